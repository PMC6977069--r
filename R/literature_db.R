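# Literature interaction database: parsing with label normalization,
# hierarchical aggregation, habitat summaries, and quantification of the
# database's overlap with the co-occurrence network at genus resolution.

LIT_COLS <- c("interaction_type", "raw_label", "diatom_genus",
              "diatom_species", "partner_class", "partner_genus",
              "partner_species", "habitat", "source_ref",
              "genus_unresolved")
INTERACTION_VOCAB <- c("predation", "parasitism", "symbiosis", "epibiosis",
                       "allelopathy", "competition", "mutualism")

#' Default interaction-label normalization table
#'
#' Maps raw literature/GloBI-style labels (e.g. "eatenBy") onto the
#' controlled interaction vocabulary (predation, parasitism, symbiosis,
#' epibiosis, allelopathy, competition, mutualism). Labels mapped to
#' "nonliving" mark records describing attachment to sand or mud
#' (epipsammic/epipelic), which are dropped at read time.
#'
#' @return named character vector raw_label -> interaction_type.
#' @export
default_label_map <- function() {
  path <- system.file("extdata", "globi_label_map.csv", package = "segnet")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  setNames(tab$interaction_type, tab$raw_label)
}

#' Read a literature interaction database
#'
#' CSV with columns `interaction_raw_label`, `diatom_genus`,
#' `diatom_species`, `partner_class`, `partner_genus`, `partner_species`,
#' `habitat`, `source_ref`. Raw labels are normalized through `label_map`
#' (unknown labels are an error naming the label); habitats are lowered
#' and mapped to marine/freshwater/both/unknown (empty -> unknown).
#' Records describing interactions with nonliving surfaces
#' (epipsammic/epipelic) are dropped with a warning. Records without a
#' diatom genus are kept but flagged `genus_unresolved`.
#'
#' @param path CSV path.
#' @param label_map named vector raw_label -> interaction_type; see
#'   [default_label_map()].
#' @return data.frame of class `literature_db`.
#' @export
read_litdb <- function(path, label_map = default_label_map()) {
  if (!file.exists(path)) abort("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines[nzchar(lines)]) == 0) {
    return(empty_litdb())
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("interaction_raw_label", "diatom_genus", "partner_genus")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    abort("literature file missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(tab) == 0) return(empty_litdb())
  bad <- which(tab$interaction_raw_label == "" | tab$partner_genus == "")
  if (length(bad) > 0) {
    abort("malformed literature row at line ", bad[1] + 1L, " of ", path)
  }
  itype <- unname(label_map[tab$interaction_raw_label])
  if (anyNA(itype)) {
    abort("unknown interaction label(s): ",
          paste(sort(unique(
            tab$interaction_raw_label[is.na(itype)])), collapse = ", "))
  }
  drop <- itype == "nonliving"
  if (any(drop)) {
    warning(sum(drop),
            " record(s) with nonliving surfaces (epipsammic/epipelic) dropped",
            call. = FALSE)
    tab <- tab[!drop, , drop = FALSE]
    itype <- itype[!drop]
  }
  habitat <- tolower(tab$habitat %||% rep("", nrow(tab)))
  habitat[habitat == ""] <- "unknown"
  bad_hab <- setdiff(unique(habitat),
                     c("marine", "freshwater", "both", "unknown"))
  if (length(bad_hab) > 0) {
    abort("unknown habitat value(s): ", paste(bad_hab, collapse = ", "))
  }
  out <- data.frame(
    interaction_type = itype,
    raw_label = tab$interaction_raw_label,
    diatom_genus = tab$diatom_genus,
    diatom_species = tab$diatom_species %||% rep("", nrow(tab)),
    partner_class = tab$partner_class %||% rep("", nrow(tab)),
    partner_genus = tab$partner_genus,
    partner_species = tab$partner_species %||% rep("", nrow(tab)),
    habitat = habitat,
    source_ref = tab$source_ref %||% rep("", nrow(tab)),
    genus_unresolved = tab$diatom_genus == "",
    stringsAsFactors = FALSE
  )
  class(out) <- c("literature_db", "data.frame")
  out
}

empty_litdb <- function() {
  out <- data.frame(matrix(character(), 0, length(LIT_COLS),
                           dimnames = list(NULL, LIT_COLS)),
                    stringsAsFactors = FALSE)
  out$genus_unresolved <- logical(0)
  class(out) <- c("literature_db", "data.frame")
  out
}

#' Write a literature database in the interchange CSV layout
#'
#' @param records `literature_db`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_litdb <- function(records, path) {
  out <- data.frame(interaction_raw_label = records$raw_label,
                    diatom_genus = records$diatom_genus,
                    diatom_species = records$diatom_species,
                    partner_class = records$partner_class,
                    partner_genus = records$partner_genus,
                    partner_species = records$partner_species,
                    habitat = records$habitat,
                    source_ref = records$source_ref,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Hierarchical aggregation of literature records
#'
#' Counts records at every prefix of `levels` (e.g. interaction type, then
#' partner class within type) — the tabular equivalent of a KRONA plot.
#' At each depth, `share` is the count over the parent's count (over the
#' total at depth 1); leaf counts always sum to the number of records.
#'
#' @param records `literature_db`.
#' @param levels character vector of record fields, outer to inner.
#' @return object of class `hierarchy_counts`: list with `levels`,
#'   `n_total` and `tables` (one data.frame per depth, with `n` and
#'   `share` in percent).
#' @export
aggregate_hierarchy <- function(records,
                                levels = c("interaction_type",
                                           "partner_class")) {
  miss <- setdiff(levels, names(records))
  if (length(miss) > 0) abort("unknown field(s): ", paste(miss, collapse = ", "))
  n_total <- nrow(records)
  tables <- vector("list", length(levels))
  names(tables) <- vapply(seq_along(levels), function(d)
    paste(levels[seq_len(d)], collapse = "/"), character(1))
  for (d in seq_along(levels)) {
    key_cols <- levels[seq_len(d)]
    agg <- stats::aggregate(list(n = rep(1L, n_total)),
                            by = records[key_cols], FUN = sum)
    if (d == 1) {
      parent_n <- rep(n_total, nrow(agg))
    } else {
      parent <- tables[[d - 1]]
      pk <- do.call(paste, c(parent[levels[seq_len(d - 1)]], sep = "\r"))
      ak <- do.call(paste, c(agg[levels[seq_len(d - 1)]], sep = "\r"))
      parent_n <- parent$n[match(ak, pk)]
    }
    agg$share <- 100 * agg$n / parent_n
    ord <- do.call(order, c(agg[key_cols], list(method = "radix")))
    tables[[d]] <- agg[ord, , drop = FALSE]
    rownames(tables[[d]]) <- NULL
  }
  structure(list(levels = levels, n_total = n_total, tables = tables),
            class = "hierarchy_counts")
}

#' @export
print.hierarchy_counts <- function(x, ...) {
  cat("hierarchy over", paste(x$levels, collapse = " / "),
      "-", x$n_total, "records\n")
  print(utils::head(x$tables[[length(x$tables)]], 20))
  invisible(x)
}

#' Habitat summary of the literature database
#'
#' @param records `literature_db`.
#' @return data.frame `habitat`, `n_records`, `n_genera` (distinct
#'   resolved diatom genera).
#' @export
habitat_summary <- function(records) {
  habs <- sort(unique(records$habitat))
  data.frame(
    habitat = habs,
    n_records = vapply(habs, function(h)
      sum(records$habitat == h), integer(1)),
    n_genera = vapply(habs, function(h)
      length(unique(records$diatom_genus[
        records$habitat == h & records$diatom_genus != ""])), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Overlap between the literature database and the network
#'
#' Implements the genus-level matching protocol: a record is "potential"
#' iff its diatom genus matches at least one barcode of the focal group
#' AND its partner genus matches at least one barcode anywhere in the
#' network (case-insensitive, synonym map applied to both sides);
#' "recovered" iff at least one edge record joins a barcode of each
#' genus. Matched network edges are pooled over all recovered records and
#' deduplicated per edge record. Interaction type plays no role in
#' matching (a correlation carries no mechanism); species fields are
#' carried but unused.
#'
#' @param records `literature_db`.
#' @param net `interaction_network` with genus annotations.
#' @param group focal group label (the diatoms).
#' @param synonym_map optional named vector, synonym -> canonical genus.
#' @return object of class `overlap_report`: `n_literature`,
#'   `n_potential`, `n_recovered`, `pct_recovered_of_potential`,
#'   `n_network_edges_matched`, `pct_of_group_network_edges`,
#'   `matched_pairs` (data.frame diatom_genus / partner_genus / n_edges).
#' @export
compare_litdb_network <- function(records, net, group, synonym_map = NULL) {
  check_group(net, group)
  ann <- net$annotations
  if (all(ann$genus == "")) abort("network lacks genus annotations")
  canon <- tolower(apply_synonyms(ann$genus, synonym_map))
  focal_genera <- unique(canon[ann$group == group & canon != ""])
  all_genera <- unique(canon[canon != ""])
  genus_of <- setNames(canon, ann$barcode_id)
  dg <- tolower(apply_synonyms(records$diatom_genus, synonym_map))
  pg <- tolower(apply_synonyms(records$partner_genus, synonym_map))
  potential <- !records$genus_unresolved &
    dg %in% focal_genera & pg %in% all_genera
  ed <- net$edges
  ea <- unname(genus_of[ed$node_a])
  eb <- unname(genus_of[ed$node_b])
  edge_pair_1 <- paste(ea, eb, sep = "\r")
  edge_pair_2 <- paste(eb, ea, sep = "\r")
  rec_pair <- paste(dg, pg, sep = "\r")
  recovered <- potential &
    (rec_pair %in% edge_pair_1 | rec_pair %in% edge_pair_2)
  matched_edge <- rep(FALSE, nrow(ed))
  pairs <- unique(rec_pair[recovered])
  for (p in pairs) {
    matched_edge <- matched_edge | edge_pair_1 == p | edge_pair_2 == p
  }
  grp_total <- summarize_group(net, group)$n_total
  matched_pairs <- if (length(pairs) > 0) {
    parts <- strsplit(pairs, "\r", fixed = TRUE)
    data.frame(
      diatom_genus = vapply(parts, `[`, character(1), 1),
      partner_genus = vapply(parts, `[`, character(1), 2),
      n_edges = vapply(pairs, function(p)
        sum(edge_pair_1 == p | edge_pair_2 == p), integer(1)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else {
    data.frame(diatom_genus = character(), partner_genus = character(),
               n_edges = integer(), stringsAsFactors = FALSE)
  }
  structure(list(
    n_literature = nrow(records),
    n_potential = sum(potential),
    n_recovered = sum(recovered),
    pct_recovered_of_potential = if (sum(potential) > 0) {
      100 * sum(recovered) / sum(potential)
    } else NaN,
    n_network_edges_matched = sum(matched_edge),
    pct_of_group_network_edges = if (grp_total > 0) {
      100 * sum(matched_edge) / grp_total
    } else NaN,
    matched_pairs = matched_pairs
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("literature records: %d; potential in network: %d; recovered: %d (%s%% of potential)\n",
              x$n_literature, x$n_potential, x$n_recovered,
              if (is.nan(x$pct_recovered_of_potential)) "NA"
              else format(round_half_away(x$pct_recovered_of_potential, 1))))
  cat(sprintf("network edges matched: %d (%s%% of the group's edges)\n",
              x$n_network_edges_matched,
              if (is.nan(x$pct_of_group_network_edges)) "NA"
              else format(round_half_away(x$pct_of_group_network_edges, 1))))
  invisible(x)
}

#' Genus-level disparity between literature and network
#'
#' For the union of diatom genera seen in either source: the number of
#' literature records versus the number of network edge records
#' (connectivity as in [genus_connectivity()]), flagging genera that are
#' connected in the network yet absent from the literature — candidate
#' understudied taxa.
#'
#' @inheritParams compare_litdb_network
#' @return data.frame `genus`, `n_literature`, `n_network_edges`,
#'   `absent_from_literature`.
#' @export
genus_disparity <- function(records, net, group, synonym_map = NULL) {
  check_group(net, group)
  ann <- net$annotations[net$annotations$group == group, , drop = FALSE]
  if (all(ann$genus == "")) abort("network lacks genus annotations")
  canon <- apply_synonyms(ann$genus, synonym_map)
  ann$genus_canon <- canon
  ann <- ann[ann$genus_canon != "", , drop = FALSE]
  net_counts <- vapply(split(ann$barcode_id, ann$genus_canon), function(bc)
    sum(net$edges$node_a %in% bc | net$edges$node_b %in% bc), integer(1))
  lit_genus <- apply_synonyms(
    records$diatom_genus[!records$genus_unresolved], synonym_map)
  lit_counts <- table(lit_genus)
  genera <- sort(union(names(net_counts), names(lit_counts)))
  n_lit <- as.integer(lit_counts[genera])
  n_lit[is.na(n_lit)] <- 0L
  n_net <- as.integer(net_counts[genera])
  n_net[is.na(n_net)] <- 0L
  data.frame(genus = genera, n_literature = n_lit, n_network_edges = n_net,
             absent_from_literature = n_lit == 0 & n_net > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}
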