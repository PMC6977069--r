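#' @importFrom stats setNames
NULL

EDGE_COLS <- c("node_a", "node_b", "score", "sign", "size_fraction",
               "depth_layer", "driver", "driver_parameter")
ANNOT_COLS <- c("barcode_id", "lineage", "group", "genus", "species",
                "trophic_mode")
TROPHIC_LEVELS <- c("autotroph", "heterotroph", "unknown")

empty_edges <- function() {
  data.frame(node_a = character(), node_b = character(), score = numeric(),
             sign = character(), size_fraction = character(),
             depth_layer = character(), driver = character(),
             driver_parameter = character(), stringsAsFactors = FALSE)
}

empty_annotations <- function() {
  data.frame(barcode_id = character(), lineage = character(),
             group = character(), genus = character(), species = character(),
             trophic_mode = character(), stringsAsFactors = FALSE)
}

#' Construct an annotated co-occurrence network
#'
#' The central container of the package: a simple undirected graph of
#' barcodes (OTUs identified by opaque md5-style ids) whose edges are
#' statistically significant pairwise correlations ("copresences" when
#' positive, "exclusions" when negative), each carrying its correlation
#' score, the sampling stratum (size fraction, depth layer) it was inferred
#' in, and whether the correlation is best explained by the two organisms'
#' abundances alone (biotic) or by a shared environmental driver (abiotic).
#' The same unordered barcode pair may appear once per distinct
#' (size_fraction, depth_layer) stratum; all counting operations downstream
#' count each retained edge record once.
#'
#' @param annotations data.frame with columns `barcode_id`, `lineage`
#'   (semicolon-separated ranks, root to leaf), `group`, `genus`, `species`,
#'   `trophic_mode`. Missing optional columns are filled with defaults.
#' @param edges data.frame with columns `node_a`, `node_b`, `score`,
#'   `sign`, `size_fraction`, `depth_layer`, `driver`, `driver_parameter`.
#'   `sign` is recomputed from `score` if absent.
#' @return an object of class `interaction_network`.
#' @export
interaction_network <- function(annotations = empty_annotations(),
                                edges = empty_edges()) {
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  for (col in setdiff(ANNOT_COLS, names(annotations))) {
    annotations[[col]] <- if (col == "group") "unassigned"
                          else if (col == "trophic_mode") "unknown"
                          else ""
  }
  annotations <- annotations[ANNOT_COLS]
  if (nrow(edges) > 0 && !"sign" %in% names(edges)) {
    edges$sign <- ifelse(edges$score > 0, "copresence", "exclusion")
  }
  for (col in setdiff(EDGE_COLS, names(edges))) {
    edges[[col]] <- if (col == "driver") "biotic" else ""
  }
  edges <- edges[EDGE_COLS]
  net <- structure(list(annotations = annotations, edges = edges),
                   class = "interaction_network")
  validate_network(net)
  net
}

#' Validate an interaction network against its invariants
#'
#' Checks barcode uniqueness, edge endpoints, the score range (-1,1\] minus
#' zero, the sign/score correspondence, self-loops, per-stratum duplicate
#' pairs, and the driver/parameter pairing. Called by every construction
#' path; exported so user pipelines can re-assert after manual edits.
#'
#' @param net `interaction_network`.
#' @return `net`, invisibly; errors describe the first violation found.
#' @export
validate_network <- function(net) {
  ann <- net$annotations
  ed <- net$edges
  if (anyDuplicated(ann$barcode_id)) {
    abort("duplicate barcode_id in annotations: ",
          paste(unique(ann$barcode_id[duplicated(ann$barcode_id)]),
                collapse = ", "))
  }
  if (nrow(ed) == 0) return(invisible(net))
  missing <- setdiff(unique(c(ed$node_a, ed$node_b)), ann$barcode_id)
  if (length(missing) > 0) {
    abort("edge endpoints without annotation: ",
          paste(sort(missing), collapse = ", "))
  }
  if (any(ed$node_a == ed$node_b)) abort("self-loop edges are not allowed")
  if (any(!is.finite(ed$score)) || any(abs(ed$score) > 1)) {
    abort("edge score outside [-1,1]")
  }
  if (any(ed$score == 0)) {
    abort("edge score of exactly 0 is invalid (no sign can be assigned)")
  }
  ok <- (ed$score > 0) == (ed$sign == "copresence") &
    ed$sign %in% c("copresence", "exclusion")
  if (!all(ok)) abort("sign/score mismatch for ", sum(!ok), " edge(s)")
  key <- paste(pair_key(ed$node_a, ed$node_b), ed$size_fraction,
               ed$depth_layer, sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicate edge for the same pair and (size_fraction, depth_layer)")
  }
  abi <- ed$driver == "abiotic"
  if (any(abi & ed$driver_parameter == "")) {
    abort("abiotic edges must carry a driver_parameter")
  }
  if (any(!abi & ed$driver_parameter != "")) {
    abort("biotic edges must not carry a driver_parameter")
  }
  invisible(net)
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", nrow(x$annotations), "barcodes,",
      nrow(x$edges), "edge records\n")
  if (nrow(x$edges) > 0) {
    cat("  copresences:", sum(x$edges$sign == "copresence"),
        " exclusions:", sum(x$edges$sign == "exclusion"), "\n")
  }
  grp <- table(x$annotations$group)
  if (length(grp) > 0) {
    cat("  groups:", paste(names(grp), grp, sep = ":", collapse = ", "), "\n")
  }
  invisible(x)
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(NULL)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    quote = "", comment.char = "")
}

#' Read an annotated network from TSV files
#'
#' The edge file is a TSV with header columns `node_a`, `node_b`, `score`,
#' `size_fraction`, `depth_layer`, `driver`, `driver_parameter` and an
#' optional `sign` column; the sign is always recomputed from the score and,
#' when a sign column is present, cross-checked row by row. The annotation
#' file is a TSV with `barcode_id`, `lineage` (semicolon-separated ranks),
#' `genus`, `species`, `trophic_mode` and an optional `group` column.
#' Files that are empty (zero lines) denote an empty network.
#'
#' @param edge_path path to the edge TSV.
#' @param annotation_path path to the annotation TSV.
#' @return `interaction_network`.
#' @export
read_network <- function(edge_path, annotation_path) {
  ann_raw <- read_tsv_checked(annotation_path)
  if (is.null(ann_raw)) {
    ann <- empty_annotations()
  } else {
    need <- c("barcode_id", "lineage")
    miss <- setdiff(need, names(ann_raw))
    if (length(miss) > 0) {
      abort("annotation file missing column(s): ", paste(miss, collapse = ", "))
    }
    ann <- ann_raw
  }
  ed_raw <- read_tsv_checked(edge_path)
  if (is.null(ed_raw)) {
    return(interaction_network(ann, empty_edges()))
  }
  need <- c("node_a", "node_b", "score")
  miss <- setdiff(need, names(ed_raw))
  if (length(miss) > 0) {
    abort("edge file missing column(s): ", paste(miss, collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(ed_raw$score))
  bad <- which(!is.finite(score) | ed_raw$node_a == "" | ed_raw$node_b == "")
  if (length(bad) > 0) {
    # +1 for the header line
    abort("malformed edge row at line ", bad[1] + 1L, " of ", edge_path)
  }
  if (any(abs(score) > 1)) {
    abort("edge score outside [-1,1] at line ",
          which(abs(score) > 1)[1] + 1L, " of ", edge_path)
  }
  if (any(score == 0)) {
    abort("edge score of exactly 0 at line ",
          which(score == 0)[1] + 1L, " of ", edge_path)
  }
  sign <- ifelse(score > 0, "copresence", "exclusion")
  if ("sign" %in% names(ed_raw)) {
    mism <- which(ed_raw$sign != sign)
    if (length(mism) > 0) {
      abort("sign/score mismatch at line ", mism[1] + 1L, " of ", edge_path)
    }
  }
  missing <- setdiff(unique(c(ed_raw$node_a, ed_raw$node_b)), ann$barcode_id)
  if (length(missing) > 0) {
    abort("unknown barcode(s) in edge file: ",
          paste(sort(missing), collapse = ", "))
  }
  ed <- data.frame(node_a = ed_raw$node_a, node_b = ed_raw$node_b,
                   score = score, sign = sign,
                   size_fraction = ed_raw$size_fraction %||% "",
                   depth_layer = ed_raw$depth_layer %||% "",
                   driver = ed_raw$driver %||% "biotic",
                   driver_parameter = ed_raw$driver_parameter %||% "",
                   stringsAsFactors = FALSE)
  ed$driver[ed$driver == ""] <- "biotic"
  interaction_network(ann, ed)
}

#' Write a network to the TSV interchange format
#'
#' Inverse of [read_network()]: `read_network()` after `write_network()` is
#' the identity, field for field.
#'
#' @param net `interaction_network`.
#' @param edge_path,annotation_path output paths.
#' @return invisibly, the two paths.
#' @export
write_network <- function(net, edge_path, annotation_path) {
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$annotations, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(edge_path, annotation_path))
}

#' Convert a network to an igraph object
#'
#' Node attributes carry the annotation columns; edge attributes carry
#' score, sign, stratum and driver fields. Multi-records for the same pair
#' in different strata become parallel edges (igraph multigraph).
#'
#' @param net `interaction_network` or `subnetwork`.
#' @param simplify collapse parallel edges (keeping the first record's
#'   attributes)? Topology metrics are defined on the simple graph.
#' @return `igraph` object.
#' @export
as_igraph <- function(net, simplify = FALSE) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$annotations)
  if (simplify) {
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                          edge.attr.comb = "first")
  }
  g
}

#' Export a network as GraphML
#'
#' @param net `interaction_network`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Assign taxonomic groups from lineages
#'
#' Every annotation's `group` is set to the label of the FIRST entry of
#' `group_config` any of whose tokens matches (case-insensitive, exact
#' token) any rank of the barcode's lineage; barcodes matching no entry get
#' `"unassigned"`. The config is ordered so that nested taxa (e.g.
#' Syndiniales inside Dinophyceae lineage strings) resolve predictably:
#' list the more specific group first. Idempotent.
#'
#' @param net `interaction_network`.
#' @param group_config named list: group label -> character vector of
#'   lineage tokens. See [default_group_config()].
#' @return the network with groups reassigned.
#' @export
assign_groups <- function(net, group_config = default_group_config()) {
  if (length(group_config) == 0) abort("group_config must be non-empty")
  labels <- names(group_config)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels)) {
    abort("group_config labels must be unique and non-empty")
  }
  ranks <- strsplit(tolower(net$annotations$lineage), ";", fixed = TRUE)
  ranks <- lapply(ranks, trimws)
  group <- rep("unassigned", nrow(net$annotations))
  for (lab in labels) {
    tokens <- tolower(group_config[[lab]])
    hit <- vapply(ranks, function(r) any(r %in% tokens), logical(1))
    group[group == "unassigned" & hit] <- lab
  }
  net$annotations$group <- group
  net
}

#' Default taxonomic group configuration
#'
#' The canonical plankton groups used throughout: diatoms
#' (Bacillariophyta), the parasitic marine alveolates (Syndiniales, listed
#' before their parent Dinophyceae so the nested order wins), dinophytes,
#' copepods, radiolarians with silica skeletons (Polycystinea), marine
#' stramenopiles (MAST), and two photosynthetic control classes.
#'
#' @return ordered named list of lineage tokens per group label.
#' @export
default_group_config <- function() {
  list(
    Bacillariophyta = c("Bacillariophyta", "Bacillariophyceae"),
    Syndiniales = c("Syndiniales", "MALV", "MALV-I", "MALV-II"),
    Dinophyceae = c("Dinophyceae"),
    Copepoda = c("Copepoda", "Maxillopoda"),
    Polycystinea = c("Polycystinea", "Polycystina"),
    MAST = c("MAST", "MAST-1", "MAST-2", "MAST-3", "MAST-4", "MAST-7"),
    Chlorophyceae = c("Chlorophyceae"),
    Dictyochophyceae = c("Dictyochophyceae"),
    Prymnesiophyceae = c("Prymnesiophyceae", "Haptophyta"),
    Bacteria = c("Bacteria", "Proteobacteria", "Cyanobacteria")
  )
}

#' Merge several networks into one
#'
#' Union of annotations and edges, e.g. pooling per-size-fraction networks
#' into the global interactome. A pair occurring in several input networks
#' is kept once per distinct (size_fraction, depth_layer); byte-identical
#' duplicate edge records are collapsed. Conflicting annotations (same
#' barcode, different fields) or conflicting scores for the same pair and
#' stratum are errors.
#'
#' @param networks list of `interaction_network`.
#' @return merged `interaction_network`.
#' @export
merge_networks <- function(networks) {
  if (length(networks) == 0) return(interaction_network())
  ann <- unique(do.call(rbind, lapply(networks, `[[`, "annotations")))
  if (anyDuplicated(ann$barcode_id)) {
    bad <- unique(ann$barcode_id[duplicated(ann$barcode_id)])
    abort("conflicting annotations for barcode(s): ",
          paste(sort(bad), collapse = ", "))
  }
  ed <- unique(do.call(rbind, lapply(networks, `[[`, "edges")))
  rownames(ann) <- rownames(ed) <- NULL
  interaction_network(ann, ed)
}
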