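# Pairwise-group subnetwork extraction and the topology metrics used to
# compare them: components, density, Freeman degree centralization,
# diameter, mean degree, normalized betweenness, exclusion strength, and a
# Welch two-sample test on exclusion scores.

#' Extract the bipartite subnetwork between two groups
#'
#' Retains exactly the inter-group edge records joining `focal` and
#' `partner` (intra-group edges excluded) and their endpoints; nodes not
#' incident to a retained edge are dropped, so the result has no isolated
#' nodes. Symmetric in (focal, partner).
#'
#' @param net `interaction_network`.
#' @param focal,partner distinct group labels.
#' @param sign_filter optional `"copresence"` or `"exclusion"` to keep one
#'   sign only.
#' @return object of class `subnetwork` (also an `interaction_network`)
#'   with fields `focal_group`, `partner_group`, `sign_filter`.
#' @export
extract_pair_subnetwork <- function(net, focal, partner, sign_filter = NULL) {
  check_group(net, focal)
  check_group(net, partner)
  if (focal == partner) abort("focal and partner groups must differ")
  if (!is.null(sign_filter) &&
      !sign_filter %in% c("copresence", "exclusion")) {
    abort("sign_filter must be \"copresence\" or \"exclusion\"")
  }
  gl <- group_lookup(net)
  ga <- unname(gl[net$edges$node_a])
  gb <- unname(gl[net$edges$node_b])
  sel <- (ga == focal & gb == partner) | (ga == partner & gb == focal)
  if (!is.null(sign_filter)) sel <- sel & net$edges$sign == sign_filter
  ed <- net$edges[sel, , drop = FALSE]
  keep <- net$annotations$barcode_id %in% unique(c(ed$node_a, ed$node_b))
  ann <- net$annotations[keep, , drop = FALSE]
  rownames(ed) <- rownames(ann) <- NULL
  structure(list(annotations = ann, edges = ed,
                 focal_group = focal, partner_group = partner,
                 sign_filter = sign_filter),
            class = c("subnetwork", "interaction_network"))
}

# coerce network-like objects to a simple igraph for topology metrics
topo_graph <- function(x) {
  if (inherits(x, "igraph")) {
    return(igraph::simplify(x, edge.attr.comb = "first"))
  }
  as_igraph(x, simplify = TRUE)
}

#' Number of connected components
#'
#' Counted over non-isolated nodes (a subnetwork carries none by
#' construction); the empty graph has 0 components. Fewer components in a
#' pairwise subnetwork suggest less specialist, more interconnected
#' association structure.
#'
#' @param x `subnetwork`, `interaction_network`, or `igraph`.
#' @return integer count.
#' @export
count_components <- function(x) {
  g <- topo_graph(x)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  if (igraph::vcount(g) == 0) return(0L)
  igraph::components(g)$no
}

#' Graph density
#'
#' Realized over possible edges, 2m / (n (n - 1)), on the simple graph
#' (parallel stratum records collapse to one pair).
#'
#' @param x network-like object (>= 2 nodes).
#' @param ... unused.
#' @return real in \[0,1\].
#' @export
density.subnetwork <- function(x, ...) graph_density(x)

#' @rdname density.subnetwork
#' @export
density.interaction_network <- function(x, ...) graph_density(x)

#' @rdname density.subnetwork
#' @export
graph_density <- function(x) {
  g <- topo_graph(x)
  n <- igraph::vcount(g)
  if (n < 2) abort("density needs at least 2 nodes")
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' Freeman degree centralization
#'
#' Sum of (max degree - degree) over nodes, normalized by the star graph's
#' value (n - 1)(n - 2): 1 for a star ("starlike", dependent on few hub
#' species), 0 for any regular graph.
#'
#' @param x network-like object (>= 3 nodes).
#' @return real in \[0,1\].
#' @export
degree_centralization <- function(x) {
  g <- topo_graph(x)
  n <- igraph::vcount(g)
  if (n < 3) abort("centralization needs at least 3 nodes")
  d <- igraph::degree(g)
  sum(max(d) - d) / ((n - 1) * (n - 2))
}

#' Normalized betweenness centrality
#'
#' Fraction of all-pairs shortest paths passing through each node, with
#' equal split across equal-length geodesics, normalized by
#' (n - 1)(n - 2)/2 so values lie in \[0,1\] (1 = the center of a star).
#'
#' @param x network-like object.
#' @return named numeric vector, one value in \[0,1\] per node.
#' @export
node_betweenness <- function(x) {
  g <- topo_graph(x)
  n <- igraph::vcount(g)
  if (n == 0) return(setNames(numeric(0), character(0)))
  if (n <= 2) return(setNames(rep(0, n), igraph::V(g)$name))
  b <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  setNames(as.numeric(b), igraph::V(g)$name)
}

#' Graph diameter on the largest component
#'
#' Longest shortest path, in edges, within the largest connected
#' component (pairwise subnetworks are typically disconnected).
#'
#' @param x network-like object.
#' @return integer; 0 for an empty or single-node graph.
#' @export
graph_diameter <- function(x) {
  g <- topo_graph(x)
  if (igraph::vcount(g) == 0) return(0L)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  as.integer(igraph::diameter(sub, directed = FALSE, unconnected = FALSE))
}

#' Mean and standard deviation of exclusion scores
#'
#' Arithmetic mean and sample (n - 1) standard deviation of the
#' negative-correlation edge scores of a subnetwork; the "exclusion
#' strength" compared across pairwise subnetworks. A single exclusion
#' yields sd 0 with a warning rather than an error so report generation
#' never aborts on tiny subnetworks.
#'
#' @param subnet `subnetwork` (or any network-like object with edges).
#' @return named numeric vector `c(mean = , sd = )`.
#' @export
exclusion_strength <- function(subnet) {
  sc <- subnet$edges$score[subnet$edges$sign == "exclusion"]
  if (length(sc) == 0) abort("subnetwork has no exclusion edges")
  s <- if (length(sc) == 1) {
    warning("single exclusion score; sd reported as 0", call. = FALSE)
    0
  } else {
    stats::sd(sc)
  }
  c(mean = mean(sc), sd = s)
}

#' Welch two-sample t test on score lists
#'
#' Compares the strength of (typically exclusion) scores between two
#' subnetworks or groups: Welch t statistic, Welch-Satterthwaite degrees
#' of freedom, two-sided p value from the t distribution.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list `t_statistic`, `df`, `p_value`.
#' @export
compare_strengths <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("both samples need at least 2 observations")
  }
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  if (vx + vy == 0) abort("degenerate (zero) variance in both samples")
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t_statistic = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df))
}

#' Full topology report for a subnetwork
#'
#' Bundles the metrics compared across pairwise-group subnetworks:
#' node/edge counts (edges as distinct pairs of the simple graph; the raw
#' record count is reported separately), density, degree centralization
#' (NA below 3 nodes), diameter of the largest component, mean degree,
#' per-sign component counts, exclusion score mean/sd (NA when the
#' subnetwork has no exclusions), and the betweenness map.
#'
#' @param subnet `subnetwork`.
#' @return object of class `topology_report`.
#' @export
topology_report <- function(subnet) {
  if (nrow(subnet$edges) == 0) abort("empty subnetwork")
  g <- topo_graph(subnet)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  sign_components <- function(s) {
    ed <- subnet$edges[subnet$edges$sign == s, , drop = FALSE]
    if (nrow(ed) == 0) return(0L)
    sub <- subnet
    sub$edges <- ed
    keep <- sub$annotations$barcode_id %in% unique(c(ed$node_a, ed$node_b))
    sub$annotations <- sub$annotations[keep, , drop = FALSE]
    count_components(sub)
  }
  exc <- subnet$edges$score[subnet$edges$sign == "exclusion"]
  strength <- if (length(exc) == 0) {
    c(mean = NA_real_, sd = NA_real_)
  } else {
    suppressWarnings(exclusion_strength(subnet))
  }
  structure(list(
    focal_group = subnet$focal_group %||% NA_character_,
    partner_group = subnet$partner_group %||% NA_character_,
    n_nodes = n,
    n_edges = m,
    n_edge_records = nrow(subnet$edges),
    density = graph_density(subnet),
    centralization = if (n >= 3) degree_centralization(subnet) else NA_real_,
    diameter = graph_diameter(subnet),
    avg_neighbors = 2 * m / n,
    n_components = count_components(subnet),
    n_components_copresence = sign_components("copresence"),
    n_components_exclusion = sign_components("exclusion"),
    mean_exclusion_score = unname(strength["mean"]),
    sd_exclusion_score = unname(strength["sd"]),
    betweenness = node_betweenness(subnet)
  ), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("subnetwork %s ~ %s: %d nodes, %d edges (%d records)\n",
              x$focal_group, x$partner_group, x$n_nodes, x$n_edges,
              x$n_edge_records))
  cat(sprintf("  density %.3f, centralization %s, diameter %d, avg neighbors %.2f\n",
              x$density,
              if (is.na(x$centralization)) "NA"
              else sprintf("%.3f", x$centralization),
              x$diameter, x$avg_neighbors))
  cat(sprintf("  components: %d total (%d copresence / %d exclusion)\n",
              x$n_components, x$n_components_copresence,
              x$n_components_exclusion))
  if (!is.na(x$mean_exclusion_score)) {
    cat(sprintf("  exclusion score: %.3f +/- %.3f\n",
                x$mean_exclusion_score, x$sd_exclusion_score))
  }
  invisible(x)
}

# flatten a topology report to a one-row data.frame (betweenness dropped)
topology_row <- function(rep) {
  fields <- rep[setdiff(names(rep), "betweenness")]
  as.data.frame(fields, stringsAsFactors = FALSE)
}
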