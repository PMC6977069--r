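# Toy fixtures built in code. Annotation/edge builders keep tests terse.

make_annotations <- function(ids, group = "unassigned", genus = "",
                             lineage = NULL, trophic = "unknown") {
  data.frame(barcode_id = ids,
             lineage = lineage %||% rep("", length(ids)),
             group = rep_len(group, length(ids)),
             genus = rep_len(genus, length(ids)),
             species = "",
             trophic_mode = rep_len(trophic, length(ids)),
             stringsAsFactors = FALSE)
}

make_edges <- function(a, b, score, size_fraction = "20-180",
                       depth_layer = "SRF", driver = "biotic",
                       driver_parameter = "") {
  data.frame(node_a = a, node_b = b, score = score,
             sign = ifelse(score > 0, "copresence", "exclusion"),
             size_fraction = rep_len(size_fraction, length(a)),
             depth_layer = rep_len(depth_layer, length(a)),
             driver = rep_len(driver, length(a)),
             driver_parameter = rep_len(driver_parameter, length(a)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 3 diatoms, 2 copepods, 1 dinophyte; mixed signs
toy_network <- function() {
  ann <- rbind(
    make_annotations(c("d1", "d2", "d3"), "Bacillariophyta",
                     genus = c("Chaetoceros", "Chaetoceros", "Thalassiosira"),
                     trophic = "autotroph"),
    make_annotations(c("c1", "c2"), "Copepoda", genus = "Calanus",
                     trophic = "heterotroph"),
    make_annotations("x1", "Dinophyceae", genus = "Gymnodinium",
                     trophic = "heterotroph")
  )
  ed <- make_edges(
    a = c("d1", "d1", "d2", "d1", "c1", "d3"),
    b = c("c1", "c2", "c1", "d2", "c2", "x1"),
    score = c(-0.5, -0.7, 0.6, 0.8, 0.4, -0.6)
  )
  interaction_network(ann, ed)
}

# undirected random simple graph as an igraph, n nodes, edge prob p
random_igraph <- function(n, p) {
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  el <- pairs[, keep, drop = FALSE]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  if (ncol(el) > 0) {
    g <- igraph::add_edges(g, as.vector(el))
  }
  g
}

# tiny generator spec (fast): two groups, one pair
small_spec <- function(n_edges = 200, p_ex = 0.25, seed = 1,
                       abiotic_fraction = 0.13, n_barcodes = 25) {
  generator_spec(
    groups = list(
      list(label = "A", n_barcodes = n_barcodes,
           lineage = "Eukaryota;GroupA",
           genus_pool = c("Aga", "Agb", "Agc"), trophic_mode = "autotroph"),
      list(label = "B", n_barcodes = n_barcodes,
           lineage = "Eukaryota;GroupB",
           genus_pool = c("Bga", "Bgb"), trophic_mode = "heterotroph"),
      # edge-free group supplying "potential but not recovered" genus
      # pairs for the planted literature overlap
      list(label = "C", n_barcodes = 8,
           lineage = "Eukaryota;GroupC",
           genus_pool = paste0("Cg", letters[1:8]),
           trophic_mode = "heterotroph")
    ),
    pair_params = data.frame(group_a = "A", group_b = "B",
                             n_edges = n_edges, p_exclusion = p_ex,
                             stringsAsFactors = FALSE),
    abiotic_fraction = abiotic_fraction,
    n_stations = 10,
    endemic_barcodes = data.frame(barcode_index = 1, station = 3,
                                  reads = 1e4),
    litdb = list(n_records = 20, fraction_potential = 0.5,
                 fraction_recovered = 0.2),
    seed = seed
  )
}
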