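# Genus- and barcode-level profiling: connectivity vs read abundance,
# rank correlation with exact small-sample p values, per-barcode partner
# profiles, top-excluder ranking and station distributions.

#' Starter genus synonym map
#'
#' Named character vector mapping synonym -> canonical genus, applied
#' case-insensitively before any genus aggregation or literature matching.
#' Ships only the homotypic pair Rhizosolenia -> Proboscia (nonuniversal
#' taxonomic denominations otherwise split one genus across two names);
#' users extend or replace it.
#'
#' @return named character vector.
#' @export
default_synonym_map <- function() {
  path <- system.file("extdata", "genus_synonyms.csv", package = "segnet")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  setNames(tab$canonical, tab$synonym)
}

# canonicalize genus names through a synonym map, case-insensitively;
# returns input with synonyms replaced (original case of canonical name)
apply_synonyms <- function(genus, synonym_map = NULL) {
  if (is.null(synonym_map) || length(synonym_map) == 0) return(genus)
  idx <- match(tolower(genus), tolower(names(synonym_map)))
  out <- genus
  out[!is.na(idx)] <- unname(synonym_map[idx[!is.na(idx)]])
  out
}

#' Read / write a barcode-by-station abundance table
#'
#' TSV with a `barcode_id` column and one column of non-negative integer
#' read counts per station.
#'
#' @param path file path.
#' @return numeric matrix, rows = barcodes, columns = stations.
#' @export
read_abundance <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"barcode_id" %in% names(tab)) {
    abort("abundance file missing barcode_id column")
  }
  m <- as.matrix(tab[setdiff(names(tab), "barcode_id")])
  rownames(m) <- tab$barcode_id
  suppressWarnings(storage.mode(m) <- "double")
  if (any(!is.finite(m)) || any(m < 0)) {
    abort("abundance values must be non-negative numbers")
  }
  m
}

#' @rdname read_abundance
#' @param abundance matrix as returned by `read_abundance`.
#' @export
write_abundance <- function(abundance, path) {
  df <- data.frame(barcode_id = rownames(abundance), abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genus-level connectivity versus abundance
#'
#' For every genus annotated within a group: total reads summed over its
#' barcodes, the number of edge records touching them (an intra-genus edge
#' counts once; an edge joining two genera of the group is counted by
#' both), the number of distinct partner barcodes outside the genus, and
#' the sign split. Used to ask whether globally abundant genera are also
#' the connected ones (in the open-ocean interactome they are not).
#'
#' @param net `interaction_network`.
#' @param abundance barcode-by-station matrix (rows may cover a superset
#'   or subset of the network's barcodes).
#' @param group group label.
#' @param synonym_map optional named vector, synonym -> canonical genus.
#' @return data.frame of class rows: `genus`, `total_reads`, `n_edges`,
#'   `n_partner_nodes`, `n_copresence`, `n_exclusion`, sorted by
#'   decreasing `total_reads`.
#' @export
genus_connectivity <- function(net, abundance, group, synonym_map = NULL) {
  check_group(net, group)
  ann <- net$annotations[net$annotations$group == group, , drop = FALSE]
  genus <- apply_synonyms(ann$genus, synonym_map)
  if (all(genus == "")) abort("group ", group, " has no genus annotations")
  ann$genus_canon <- genus
  ann <- ann[ann$genus_canon != "", , drop = FALSE]
  ed <- net$edges
  rows <- lapply(split(ann$barcode_id, ann$genus_canon), function(bc) {
    touch <- ed$node_a %in% bc | ed$node_b %in% bc
    e <- ed[touch, , drop = FALSE]
    partners <- setdiff(unique(c(e$node_a, e$node_b)), bc)
    reads <- sum(abundance[rownames(abundance) %in% bc, , drop = FALSE])
    data.frame(total_reads = reads, n_edges = nrow(e),
               n_partner_nodes = length(partners),
               n_copresence = sum(e$sign == "copresence"),
               n_exclusion = sum(e$sign == "exclusion"))
  })
  out <- do.call(rbind, rows)
  out <- data.frame(genus = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$total_reads, out$genus), , drop = FALSE]
}

# all permutations of 1..n as an n! x n matrix (n <= 8 in practice)
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank correlation with exact small-sample p value
#'
#' rho is the Pearson correlation of average ranks (ties handled by
#' midranks). The two-sided p value is exact for n <= 8 — the proportion
#' of all n! permutations of one vector whose |rho| reaches the observed
#' |rho| — and a t approximation (t = rho sqrt((n-2)/(1-rho^2)) on n - 2
#' df) above.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list `rho`, `p_value`, `method` ("exact" or "t-approximation").
#' @export
rank_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) abort("x and y must have equal length >= 3")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("rank correlation undefined for a constant vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- permutations(n)
    rho_perm <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else if (abs(rho) >= 1 - 1e-12) {
    p <- 0
    method <- "t-approximation"
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p_value = p, method = method)
}

#' Per-barcode partner profile
#'
#' Sign-split association counts of one barcode with every partner group
#' it touches (the tabular equivalent of a chord diagram ribbon set).
#'
#' @param net `interaction_network`.
#' @param barcode_id barcode present in the annotations.
#' @return object of class `barcode_profile`: `barcode_id`, `profile`
#'   (data.frame partner_group / n_copresence / n_exclusion, zero rows for
#'   an isolated barcode), `total_exclusions`.
#' @export
barcode_profile <- function(net, barcode_id) {
  if (!barcode_id %in% net$annotations$barcode_id) {
    abort("unknown barcode: ", barcode_id)
  }
  ed <- net$edges
  touch <- ed$node_a == barcode_id | ed$node_b == barcode_id
  e <- ed[touch, , drop = FALSE]
  other <- ifelse(e$node_a == barcode_id, e$node_b, e$node_a)
  gl <- group_lookup(net)
  pg <- unname(gl[other])
  groups <- sort(unique(pg))
  prof <- data.frame(
    partner_group = groups,
    n_copresence = vapply(groups, function(g)
      sum(pg == g & e$sign == "copresence"), integer(1)),
    n_exclusion = vapply(groups, function(g)
      sum(pg == g & e$sign == "exclusion"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(barcode_id = barcode_id, profile = prof,
                 total_exclusions = sum(prof$n_exclusion)),
            class = "barcode_profile")
}

#' @export
print.barcode_profile <- function(x, ...) {
  cat("barcode", x$barcode_id, "-", x$total_exclusions, "exclusions\n")
  if (nrow(x$profile) > 0) print(x$profile)
  invisible(x)
}

#' Top excluding barcodes of a group
#'
#' Ranks the group's barcodes by their exclusion-record count, descending,
#' ties broken lexicographically by barcode id; barcodes with no
#' exclusions are dropped.
#'
#' @param net `interaction_network`.
#' @param group group label.
#' @param n number of barcodes to return (default 6).
#' @return data.frame `barcode_id`, `n_exclusions`.
#' @export
top_excluders <- function(net, group, n = 6) {
  check_group(net, group)
  bc <- net$annotations$barcode_id[net$annotations$group == group]
  ed <- net$edges[net$edges$sign == "exclusion", , drop = FALSE]
  counts <- vapply(bc, function(b)
    sum(ed$node_a == b | ed$node_b == b), integer(1))
  keep <- counts > 0
  out <- data.frame(barcode_id = bc[keep], n_exclusions = counts[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$n_exclusions, out$barcode_id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n)
}

#' Station distribution and endemicity of a barcode
#'
#' Relative abundance of the barcode at each station (its reads over the
#' station's total reads) and an endemicity index: the maximum share of
#' the barcode's own reads found at a single station (1 = fully endemic,
#' 1/k = uniform over k stations). The index is this package's scalar
#' summary of the "endemic and blooming" distribution pattern of top
#' excluding diatoms; it is not a published statistic.
#'
#' @param abundance barcode-by-station matrix.
#' @param barcode_id row name present in `abundance`.
#' @return list `table` (data.frame station / reads /
#'   relative_abundance) and `endemicity_index`.
#' @export
station_distribution <- function(abundance, barcode_id) {
  if (!barcode_id %in% rownames(abundance)) {
    abort("barcode ", barcode_id, " absent from abundance table")
  }
  reads <- abundance[barcode_id, ]
  totals <- colSums(abundance)
  rel <- ifelse(totals > 0, reads / totals, NaN)
  idx <- if (sum(reads) > 0) max(reads) / sum(reads) else NaN
  list(table = data.frame(station = colnames(abundance),
                          reads = as.numeric(reads),
                          relative_abundance = as.numeric(rel),
                          stringsAsFactors = FALSE),
       endemicity_index = idx)
}
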