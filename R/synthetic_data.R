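# Seeded generator of annotated networks, abundance tables and literature
# records with planted, exactly recoverable ground truth. The default spec
# is a ~30x scaled-down analogue of the global plankton interactome:
# diatom and polycystine pairs are exclusion-dominated (P:N < 1), other
# pairs copresence-dominated, 13% of edges carry an abiotic driver, and
# correlation magnitudes follow truncated normals centered at |rho| 0.66.

GEN_SIZE_FRACTION <- "20-180"
GEN_DEPTH_LAYER <- "SRF"

# One integer seed governs every stage through a fixed splitting rule:
# stage_seed = (seed * 48271 + stage) mod (2^31 - 1), stage ids
# 0 = barcode identities, 1 = network, 2 = abundance, 3 = literature.
# (48271 is the minstd multiplier; the product stays below 2^53, so the
# double-precision modulus is exact.) Stages therefore compose
# reproducibly regardless of call order.
derive_seed <- function(seed, stage) {
  as.integer(((as.double(seed) %% 2147483647) * 48271 + stage) %%
               2147483647)
}

default_groups <- function() {
  list(
    list(label = "Bacillariophyta", n_barcodes = 40,
         lineage = "Eukaryota;Stramenopiles;Ochrophyta;Bacillariophyta",
         genus_pool = c("Chaetoceros", "Thalassiosira", "Pseudo-nitzschia",
                        "Actinocyclus", "Haslea", "Proboscia", "Corethron",
                        "Fragilariopsis", "Leptocylindrus", "Synedra"),
         trophic_mode = "autotroph"),
    list(label = "Dinophyceae", n_barcodes = 40,
         lineage = "Eukaryota;Alveolata;Dinoflagellata;Dinophyceae",
         genus_pool = c("Gymnodinium", "Gyrodinium", "Prorocentrum",
                        "Alexandrium", "Karenia"),
         trophic_mode = "heterotroph"),
    list(label = "Syndiniales", n_barcodes = 40,
         lineage = "Eukaryota;Alveolata;Dinoflagellata;Syndiniales",
         genus_pool = c("Amoebophrya", "Euduboscquella", "Hematodinium"),
         trophic_mode = "heterotroph"),
    list(label = "Copepoda", n_barcodes = 30,
         lineage = "Eukaryota;Opisthokonta;Arthropoda;Copepoda",
         genus_pool = c("Calanus", "Oithona", "Acartia", "Temora"),
         trophic_mode = "heterotroph"),
    list(label = "MAST", n_barcodes = 25,
         lineage = "Eukaryota;Stramenopiles;MAST-3",
         genus_pool = c("Solenicola", "Incisomonas"),
         trophic_mode = "heterotroph"),
    list(label = "Polycystinea", n_barcodes = 25,
         lineage = "Eukaryota;Rhizaria;Radiolaria;Polycystinea",
         genus_pool = c("Collozoum", "Sphaerozoum", "Pterocorys"),
         trophic_mode = "heterotroph"),
    list(label = "Chlorophyceae", n_barcodes = 20,
         lineage = "Eukaryota;Archaeplastida;Chlorophyta;Chlorophyceae",
         genus_pool = c("Chlamydomonas", "Dunaliella"),
         trophic_mode = "autotroph"),
    # present in the dataset but sharing no edge with diatoms, so genus
    # pairs against it supply "potential but not recovered" literature
    # records
    list(label = "Acantharea", n_barcodes = 15,
         lineage = "Eukaryota;Rhizaria;Radiolaria;Acantharea",
         genus_pool = c("Acanthometra", "Lithoptera", "Amphilonche",
                        "Phyllostaurus"),
         trophic_mode = "heterotroph")
  )
}

default_pair_params <- function() {
  df <- rbind(
    c("Bacillariophyta", "Dinophyceae", 300, 0.52),
    c("Bacillariophyta", "Syndiniales", 300, 0.50),
    c("Bacillariophyta", "Copepoda", 250, 0.55),
    c("Bacillariophyta", "MAST", 150, 0.60),
    c("Bacillariophyta", "Polycystinea", 100, 0.50),
    c("Bacillariophyta", "Chlorophyceae", 80, 0.30),
    c("Dinophyceae", "Syndiniales", 300, 0.25),
    c("Dinophyceae", "Copepoda", 200, 0.20),
    c("Syndiniales", "Copepoda", 200, 0.25),
    c("Polycystinea", "Copepoda", 120, 0.55),
    c("Polycystinea", "Syndiniales", 120, 0.55),
    c("MAST", "Dinophyceae", 100, 0.25),
    c("Chlorophyceae", "Dinophyceae", 100, 0.20)
  )
  data.frame(group_a = df[, 1], group_b = df[, 2],
             n_edges = as.integer(df[, 3]),
             p_exclusion = as.numeric(df[, 4]),
             stringsAsFactors = FALSE)
}

#' Build and validate a generator specification
#'
#' The stated world of the synthetic interactome. Defaults emulate the
#' published network scaled down ~30x: seven plankton groups, diatom and
#' polycystine pairs exclusion-dominated, 13% abiotically driven edges,
#' exclusion scores ~ truncated normal(-0.66, 0.09) on \[-1, 0) and
#' copresence scores the mirror image on (0, 1\], 126 stations, and three
#' endemic blooming diatom barcodes.
#'
#' @param groups list of group descriptors (label, n_barcodes, lineage,
#'   genus_pool, trophic_mode).
#' @param pair_params data.frame group_a / group_b / n_edges /
#'   p_exclusion.
#' @param score_model list mu_co, sigma_co, mu_ex, sigma_ex.
#' @param abiotic_fraction probability an edge carries an abiotic driver.
#' @param abiotic_parameters pool of environmental parameter names.
#' @param n_stations number of stations in the abundance table.
#' @param endemic_barcodes data.frame barcode_index (within the first
#'   group) / station / reads: barcodes whose read mass is planted at one
#'   station, or NULL.
#' @param litdb list n_records, fraction_potential, fraction_recovered
#'   (defaults follow the published database's proportions at
#'   n_records = 150).
#' @param seed integer master seed; fully determines all outputs.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(groups = default_groups(),
                           pair_params = default_pair_params(),
                           score_model = list(mu_co = 0.66, sigma_co = 0.09,
                                              mu_ex = -0.66,
                                              sigma_ex = 0.09),
                           abiotic_fraction = 0.13,
                           abiotic_parameters = c("PO4", "NO3", "Si",
                                                  "Temperature", "MLD",
                                                  "Iron"),
                           n_stations = 126,
                           endemic_barcodes = data.frame(
                             barcode_index = c(1, 2, 3),
                             station = c(36, 122, 88),
                             reads = c(2e5, 15e4, 1e5)),
                           litdb = list(n_records = 150,
                                        fraction_potential = 178 / 1533,
                                        fraction_recovered = 33 / 1533),
                           seed = 1) {
  labels <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labels)) abort("duplicate group labels")
  if (!all(pair_params$group_a %in% labels) ||
      !all(pair_params$group_b %in% labels)) {
    abort("pair_params references unknown group labels")
  }
  if (any(pair_params$p_exclusion < 0 | pair_params$p_exclusion > 1)) {
    abort("exclusion probabilities must lie in [0,1]")
  }
  if (abiotic_fraction < 0 || abiotic_fraction > 1) {
    abort("abiotic_fraction must lie in [0,1]")
  }
  n_of <- setNames(vapply(groups, `[[`, numeric(1), "n_barcodes"), labels)
  max_pairs <- ifelse(pair_params$group_a == pair_params$group_b,
                      n_of[pair_params$group_a] *
                        (n_of[pair_params$group_a] - 1) / 2,
                      n_of[pair_params$group_a] * n_of[pair_params$group_b])
  if (any(pair_params$n_edges > max_pairs)) {
    abort("n_edges exceeds the number of possible pairs for a group pair")
  }
  structure(list(groups = groups, pair_params = pair_params,
                 score_model = score_model,
                 abiotic_fraction = abiotic_fraction,
                 abiotic_parameters = abiotic_parameters,
                 n_stations = n_stations,
                 endemic_barcodes = endemic_barcodes,
                 litdb = litdb, seed = as.integer(seed)),
            class = "generator_spec")
}

# deterministic annotation table shared by all stages (stage-0 seed):
# md5-style 6-hex-character barcode ids, genera cycled through each pool
spec_annotations <- function(spec) {
  set.seed(derive_seed(spec$seed, 0))
  n_total <- sum(vapply(spec$groups, `[[`, numeric(1), "n_barcodes"))
  ids <- sprintf("%06x", sample.int(16^6 - 1, n_total))
  rows <- list()
  off <- 0
  for (g in spec$groups) {
    n <- g$n_barcodes
    genus <- rep_len(g$genus_pool, n)
    rows[[g$label]] <- data.frame(
      barcode_id = ids[off + seq_len(n)],
      lineage = paste(g$lineage, genus, sep = ";"),
      group = g$label,
      genus = genus,
      species = "",
      trophic_mode = g$trophic_mode,
      stringsAsFactors = FALSE
    )
    off <- off + n
  }
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  ann
}

# truncated-normal scores via inverse-CDF sampling on (lo, hi)
rtrunc_norm <- function(n, mu, sigma, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mu, sigma),
                    stats::pnorm(hi, mu, sigma))
  q <- stats::qnorm(p, mu, sigma)
  pmin(pmax(q, lo + 1e-12), hi - 1e-12)
}

#' Generate a synthetic annotated network with ground truth
#'
#' Draws, for every configured group pair, `n_edges` distinct cross-group
#' barcode pairs without replacement; each edge is an exclusion with the
#' pair's planted probability, its score sampled from the sign-matched
#' truncated normal (bounded away from 0 so the sign/score invariant
#' holds), and abiotic with probability `abiotic_fraction`. Fully
#' reproducible from the spec's seed.
#'
#' @param spec `generator_spec`.
#' @return list `network` (`interaction_network`) and `truth` (planted
#'   per-pair exclusion probabilities, expected group counts, abiotic
#'   fraction).
#' @export
generate_network <- function(spec) {
  ann <- spec_annotations(spec)
  set.seed(derive_seed(spec$seed, 1))
  sm <- spec$score_model
  by_group <- split(ann$barcode_id, ann$group)
  edges <- list()
  for (i in seq_len(nrow(spec$pair_params))) {
    pp <- spec$pair_params[i, ]
    a_ids <- by_group[[pp$group_a]]
    b_ids <- by_group[[pp$group_b]]
    if (pp$group_a == pp$group_b) {
      idx <- utils::combn(length(a_ids), 2)
      pool_a <- a_ids[idx[1, ]]
      pool_b <- a_ids[idx[2, ]]
    } else {
      grid <- expand.grid(a = seq_along(a_ids), b = seq_along(b_ids))
      pool_a <- a_ids[grid$a]
      pool_b <- b_ids[grid$b]
    }
    take <- sample.int(length(pool_a), pp$n_edges)
    excl <- stats::runif(pp$n_edges) < pp$p_exclusion
    score <- numeric(pp$n_edges)
    score[excl] <- rtrunc_norm(sum(excl), sm$mu_ex, sm$sigma_ex, -1, 0)
    score[!excl] <- rtrunc_norm(sum(!excl), sm$mu_co, sm$sigma_co, 0, 1)
    abiotic <- stats::runif(pp$n_edges) < spec$abiotic_fraction
    param <- ifelse(abiotic,
                    sample(spec$abiotic_parameters, pp$n_edges,
                           replace = TRUE), "")
    edges[[i]] <- data.frame(
      node_a = pool_a[take], node_b = pool_b[take],
      score = score,
      sign = ifelse(excl, "exclusion", "copresence"),
      size_fraction = GEN_SIZE_FRACTION,
      depth_layer = GEN_DEPTH_LAYER,
      driver = ifelse(abiotic, "abiotic", "biotic"),
      driver_parameter = param,
      stringsAsFactors = FALSE
    )
  }
  ed <- do.call(rbind, edges)
  rownames(ed) <- NULL
  net <- interaction_network(ann, ed)
  truth <- list(
    pair_params = spec$pair_params,
    abiotic_fraction = spec$abiotic_fraction,
    n_edges = nrow(ed),
    n_exclusions = sum(ed$sign == "exclusion"),
    seed = spec$seed
  )
  list(network = net, truth = truth)
}

#' Generate a synthetic abundance table
#'
#' Background per-barcode read totals are log-uniform between 1e2 and 1e6
#' and spread over stations with squared-uniform station weights (a few
#' stations dominate, as in real metabarcoding surveys). Endemic barcodes
#' from the spec receive their whole planted read mass at the designated
#' station, giving them endemicity index 1 by construction.
#'
#' @param spec `generator_spec`.
#' @return barcode-by-station numeric matrix with `TARA_`-style station
#'   names.
#' @export
generate_abundance <- function(spec) {
  ann <- spec_annotations(spec)
  set.seed(derive_seed(spec$seed, 2))
  n <- nrow(ann)
  k <- spec$n_stations
  stations <- sprintf("TARA_%03d", seq_len(k))
  totals <- round(exp(stats::runif(n, log(1e2), log(1e6))))
  m <- matrix(0, n, k, dimnames = list(ann$barcode_id, stations))
  for (i in seq_len(n)) {
    w <- stats::runif(k)^2
    m[i, ] <- stats::rmultinom(1, totals[i], w / sum(w))[, 1]
  }
  em <- spec$endemic_barcodes
  if (!is.null(em) && nrow(em) > 0) {
    first_group <- spec$groups[[1]]$label
    bc <- ann$barcode_id[ann$group == first_group]
    for (j in seq_len(nrow(em))) {
      id <- bc[em$barcode_index[j]]
      m[id, ] <- 0
      m[id, sprintf("TARA_%03d", em$station[j])] <- em$reads[j]
    }
  }
  m
}

#' Generate a synthetic literature database with a planted overlap
#'
#' Emits `n_records` records whose genus pairs are constructed against the
#' supplied network so that exactly `round(n_records *
#' fraction_recovered)` are recovered (their genus pair is joined by at
#' least one network edge), exactly `round(n_records *
#' fraction_potential)` are potential (both genera have barcodes), and
#' the rest name an absent partner genus. Genus pairs are distinct across
#' records, so the planted counts are recovered exactly by
#' [compare_litdb_network()]. Raw interaction labels are drawn
#' predation-heavy (58% "eatenBy"), mirroring the skew of the curated
#' literature.
#'
#' @param spec `generator_spec`.
#' @param network the `interaction_network` from [generate_network()].
#' @return list `records` (`literature_db`) and `truth` (n_records,
#'   n_potential, n_recovered, n_network_edges_matched).
#' @export
generate_litdb <- function(spec, network) {
  set.seed(derive_seed(spec$seed, 3))
  lt <- spec$litdb
  n_rec <- lt$n_records
  n_pot <- round(n_rec * lt$fraction_potential)
  n_recov <- round(n_rec * lt$fraction_recovered)
  if (n_recov > n_pot || n_pot > n_rec) {
    abort("infeasible literature fractions: need recovered <= potential <= total")
  }
  ann <- network$annotations
  focal <- spec$groups[[1]]$label
  genus_of <- setNames(ann$genus, ann$barcode_id)
  focal_genera <- unique(ann$genus[ann$group == focal])
  partner_genera <- unique(ann$genus[ann$group != focal])
  ga <- unname(genus_of[network$edges$node_a])
  gb <- unname(genus_of[network$edges$node_b])
  grp_a <- unname(setNames(ann$group, ann$barcode_id)[network$edges$node_a])
  is_focal_a <- grp_a == focal
  pair_tab <- unique(data.frame(
    dg = ifelse(is_focal_a, ga, gb),
    pg = ifelse(is_focal_a, gb, ga),
    stringsAsFactors = FALSE))
  pair_tab <- pair_tab[pair_tab$dg %in% focal_genera &
                         pair_tab$pg %in% partner_genera, , drop = FALSE]
  adjacent <- paste(pair_tab$dg, pair_tab$pg, sep = "\r")
  all_pairs <- expand.grid(dg = focal_genera, pg = partner_genera,
                           stringsAsFactors = FALSE)
  all_keys <- paste(all_pairs$dg, all_pairs$pg, sep = "\r")
  non_adjacent <- all_keys[!all_keys %in% adjacent]
  if (n_recov > length(adjacent)) {
    abort("fraction_recovered infeasible: only ", length(adjacent),
          " adjacent genus pairs in the network")
  }
  if (n_pot - n_recov > length(non_adjacent)) {
    abort("fraction_potential infeasible for this network")
  }
  rec_keys <- sample(adjacent, n_recov)
  pot_keys <- sample(non_adjacent, n_pot - n_recov)
  n_abs <- n_rec - n_pot
  abs_dg <- sample(focal_genera, n_abs, replace = TRUE)
  abs_pg <- sprintf("Absentium%03d", seq_len(n_abs))
  split_key <- function(k, i) vapply(strsplit(k, "\r", fixed = TRUE),
                                     `[`, character(1), i)
  dg <- c(split_key(rec_keys, 1), split_key(pot_keys, 1), abs_dg)
  pg <- c(split_key(rec_keys, 2), split_key(pot_keys, 2), abs_pg)
  labels <- sample(c("eatenBy", "parasiteOf", "symbiontOf", "epibiontOf",
                     "competesWith", "allelopathOf", "mutualistOf"),
                   n_rec, replace = TRUE,
                   prob = c(0.58, 0.10, 0.10, 0.10, 0.05, 0.04, 0.03))
  records <- data.frame(
    interaction_type = unname(default_label_map()[labels]),
    raw_label = labels,
    diatom_genus = dg,
    diatom_species = "",
    partner_class = "synthetic",
    partner_genus = pg,
    partner_species = "",
    habitat = "marine",
    source_ref = sprintf("synthetic:%03d", seq_len(n_rec)),
    genus_unresolved = FALSE,
    stringsAsFactors = FALSE
  )
  class(records) <- c("literature_db", "data.frame")
  matched <- sum(paste(ifelse(is_focal_a, ga, gb),
                       ifelse(is_focal_a, gb, ga),
                       sep = "\r") %in% rec_keys)
  list(records = records,
       truth = list(n_records = n_rec, n_potential = n_pot,
                    n_recovered = n_recov,
                    n_network_edges_matched = matched))
}

#' Generate and write the full synthetic input bundle
#'
#' Runs all three generators and writes `edges.tsv`, `annotations.tsv`,
#' `abundance.tsv`, `litdb.csv` and `truth.json` into a directory; the
#' on-disk bundle is byte-identical across runs with the same spec.
#'
#' @param spec `generator_spec`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of paths written.
#' @export
write_generator_outputs <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_network(spec)
  abund <- generate_abundance(spec)
  lit <- generate_litdb(spec, gen$network)
  paths <- file.path(out_dir, c("edges.tsv", "annotations.tsv",
                                "abundance.tsv", "litdb.csv", "truth.json"))
  write_network(gen$network, paths[1], paths[2])
  write_abundance(abund, paths[3])
  write_litdb(lit$records, paths[4])
  truth <- c(gen$truth, list(litdb = lit$truth))
  jsonlite::write_json(truth, paths[5], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}
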