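# Group-level tallies, segregator classification, binomial
# exclusion-enrichment tests and biotic/abiotic driver partitioning.

group_lookup <- function(net) {
  setNames(net$annotations$group, net$annotations$barcode_id)
}

check_group <- function(net, group) {
  if (!group %in% net$annotations$group) abort("unknown group: ", group)
}

# logical index of edge records with >= 1 endpoint in `group`
# (an intra-group edge is indexed once, like any other record)
edges_touching <- function(net, group) {
  gl <- group_lookup(net)
  unname(gl[net$edges$node_a] == group | gl[net$edges$node_b] == group)
}

#' Summarize a taxonomic group's associations
#'
#' Counts the copresence (positive-correlation) and exclusion
#' (negative-correlation) edge records with at least one endpoint in the
#' group — an intra-group edge counts once — and expresses them as shares
#' of the network-wide totals of each sign. The positive-to-negative ratio
#' (`pn_ratio`) measures the group's global role: groups with more
#' exclusions than copresences (ratio < 1) are classified as
#' "segregators", a label that describes an abundance pattern, not an
#' active mechanism.
#'
#' @param net `interaction_network`.
#' @param group group label present in the annotations.
#' @return object of class `group_association_summary` with fields
#'   `group`, `n_copresence`, `n_exclusion`, `n_total`,
#'   `share_of_network_copresences`, `share_of_network_exclusions`
#'   (fractions), `pn_ratio` (`Inf` if no exclusions, `NaN` if no edges)
#'   and `is_segregator`.
#' @export
summarize_group <- function(net, group) {
  check_group(net, group)
  touch <- edges_touching(net, group)
  sgn <- net$edges$sign
  n_co <- sum(touch & sgn == "copresence")
  n_ex <- sum(touch & sgn == "exclusion")
  tot_co <- sum(sgn == "copresence")
  tot_ex <- sum(sgn == "exclusion")
  ratio <- if (n_ex > 0) n_co / n_ex else if (n_co > 0) Inf else NaN
  structure(list(
    group = group,
    n_copresence = n_co,
    n_exclusion = n_ex,
    n_total = n_co + n_ex,
    share_of_network_copresences = if (tot_co > 0) n_co / tot_co else NaN,
    share_of_network_exclusions = if (tot_ex > 0) n_ex / tot_ex else NaN,
    pn_ratio = ratio,
    is_segregator = is.finite(ratio) && ratio < 1
  ), class = "group_association_summary")
}

#' @export
print.group_association_summary <- function(x, ...) {
  cat(sprintf("%s: %d copresences (%s%% of network), %d exclusions (%s%%), P:N = %s%s\n",
              x$group, x$n_copresence,
              format(format_share(x$share_of_network_copresences)),
              x$n_exclusion,
              format(format_share(x$share_of_network_exclusions)),
              format(round_half_away(x$pn_ratio, 2)),
              if (x$is_segregator) "  [segregator]" else ""))
  invisible(x)
}

#' Positive-to-negative association ratio
#'
#' Copresences divided by exclusions for a group summary. `Inf` when the
#' group has copresences but no exclusions, `NaN` when it has no edges.
#'
#' @param summary `group_association_summary`.
#' @return non-negative real, `Inf`, or `NaN`.
#' @export
pn_ratio <- function(summary) {
  if (summary$n_exclusion > 0) summary$n_copresence / summary$n_exclusion
  else if (summary$n_copresence > 0) Inf
  else NaN
}

#' Partner breakdown of a group's associations
#'
#' Attributes every edge record touching the group to a partner label: for
#' inter-group edges, the grouping label of the other endpoint; for
#' intra-group edges, the group itself (under `"group"` mode) or the
#' `node_b` endpoint's label (under `"trophic_mode"`). Percentages are
#' taken over the group's own sign-specific totals, so each `pct` column
#' sums to 100 whenever the group has edges of that sign.
#'
#' @param net `interaction_network`.
#' @param group focal group label.
#' @param partner_grouping `"group"` (taxonomic group of the partner) or
#'   `"trophic_mode"` (e.g. autotroph vs heterotroph, for
#'   bacterial-partner breakdowns).
#' @return data.frame with columns `partner`, `n_copresence`,
#'   `n_exclusion`, `pct_of_group_copresences`, `pct_of_group_exclusions`
#'   (unrounded, 0-100 scale; `NaN` when the group has no edge of a sign).
#' @export
partner_breakdown <- function(net, group,
                              partner_grouping = c("group", "trophic_mode")) {
  partner_grouping <- match.arg(partner_grouping)
  check_group(net, group)
  touch <- edges_touching(net, group)
  ed <- net$edges[touch, , drop = FALSE]
  gl <- group_lookup(net)
  lab <- setNames(net$annotations[[partner_grouping]],
                  net$annotations$barcode_id)
  a_in <- unname(gl[ed$node_a] == group)
  partner <- ifelse(a_in, unname(lab[ed$node_b]), unname(lab[ed$node_a]))
  tot_co <- sum(ed$sign == "copresence")
  tot_ex <- sum(ed$sign == "exclusion")
  if (nrow(ed) == 0) {
    return(data.frame(partner = character(), n_copresence = integer(),
                      n_exclusion = integer(),
                      pct_of_group_copresences = numeric(),
                      pct_of_group_exclusions = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- sort(unique(partner))
  n_co <- vapply(parts, function(p)
    sum(partner == p & ed$sign == "copresence"), integer(1))
  n_ex <- vapply(parts, function(p)
    sum(partner == p & ed$sign == "exclusion"), integer(1))
  data.frame(
    partner = parts,
    n_copresence = n_co,
    n_exclusion = n_ex,
    pct_of_group_copresences = if (tot_co > 0) 100 * n_co / tot_co else NaN,
    pct_of_group_exclusions = if (tot_ex > 0) 100 * n_ex / tot_ex else NaN,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Exact binomial tail probability P(X >= k)
#'
#' Upper-tail binomial probability by explicit summation of density terms,
#' the primitive behind [binomial_exclusion_enrichment()].
#'
#' @param k observed count (0..n).
#' @param n number of trials.
#' @param p0 success probability in (0,1).
#' @return P(X >= k) for X ~ Binomial(n, p0).
#' @export
binom_upper_tail <- function(k, n, p0) {
  if (k <= 0) return(1)
  sum(stats::dbinom(k:n, n, p0))
}

#' Binomial exclusion-enrichment test for a group pair
#'
#' Tests whether the focal group shows more exclusions with a partner
#' group than expected at random. Among the n focal-partner association
#' records, the number of exclusions k is compared against
#' X ~ Binomial(n, p0) with a one-sided upper-tail p value P(X >= k)
#' computed by exact summation. The default null `p0` is the focal group's
#' own network-wide exclusion fraction ("focal_global"), i.e. the test
#' asks for partner-specific excess over the group's baseline; pass
#' `p0_mode = "explicit"` to supply any null. No multiple-testing
#' correction is applied here; see [enrichment_scan()] for an optional
#' Benjamini-Hochberg adjustment across partners.
#'
#' @param net `interaction_network`.
#' @param focal,partner group labels. `focal == partner` tests the
#'   intra-group edges.
#' @param p0_mode `"focal_global"` or `"explicit"`.
#' @param p0 null exclusion probability in (0,1); required for
#'   `"explicit"`.
#' @param alpha significance level (default 0.05).
#' @return object of class `enrichment_result`: `focal_group`,
#'   `partner_group`, `k`, `n`, `p0`, `p_value`, `significant`.
#' @export
binomial_exclusion_enrichment <- function(net, focal, partner,
                                          p0_mode = c("focal_global",
                                                      "explicit"),
                                          p0 = NULL, alpha = 0.05) {
  p0_mode <- match.arg(p0_mode)
  check_group(net, focal)
  check_group(net, partner)
  gl <- group_lookup(net)
  ga <- unname(gl[net$edges$node_a])
  gb <- unname(gl[net$edges$node_b])
  sel <- (ga == focal & gb == partner) | (ga == partner & gb == focal)
  if (focal == partner) sel <- ga == focal & gb == focal
  n <- sum(sel)
  if (n == 0) abort("no associations between ", focal, " and ", partner)
  k <- sum(net$edges$sign[sel] == "exclusion")
  if (p0_mode == "focal_global") {
    s <- summarize_group(net, focal)
    p0 <- s$n_exclusion / s$n_total
  }
  if (is.null(p0) || !is.finite(p0) || p0 <= 0 || p0 >= 1) {
    abort("p0 outside (0,1)")
  }
  p <- binom_upper_tail(k, n, p0)
  structure(list(focal_group = focal, partner_group = partner,
                 k = k, n = n, p0 = p0, p_value = p,
                 significant = p < alpha, alpha = alpha),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s ~ %s: %d exclusions of %d associations (p0 = %.4g), P(X >= k) = %.4g%s\n",
              x$focal_group, x$partner_group, x$k, x$n, x$p0, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Enrichment scan over several partner groups
#'
#' Runs [binomial_exclusion_enrichment()] for one focal group against each
#' partner, optionally adjusting p values with Benjamini-Hochberg (off by
#' default).
#'
#' @param net `interaction_network`.
#' @param focal focal group label.
#' @param partners character vector of partner group labels.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @inheritParams binomial_exclusion_enrichment
#' @return data.frame, one row per partner, columns as in
#'   `enrichment_result` plus `p_adjusted` and the final `significant`
#'   call on the adjusted values.
#' @export
enrichment_scan <- function(net, focal, partners,
                            p0_mode = c("focal_global", "explicit"),
                            p0 = NULL, alpha = 0.05,
                            p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  p0_mode <- match.arg(p0_mode)
  res <- lapply(partners, function(p)
    binomial_exclusion_enrichment(net, focal, p, p0_mode, p0, alpha))
  out <- data.frame(
    focal_group = focal,
    partner_group = partners,
    k = vapply(res, `[[`, numeric(1), "k"),
    n = vapply(res, `[[`, numeric(1), "n"),
    p0 = vapply(res, `[[`, numeric(1), "p0"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  out$p_adjusted <- if (p_adjust == "BH") {
    stats::p.adjust(out$p_value, method = "BH")
  } else {
    out$p_value
  }
  out$significant <- out$p_adjusted < alpha
  out
}

#' Partition a group's associations by driver
#'
#' Splits the edge records touching a group into those best explained by
#' the two organisms' abundances alone (biotic) and those attributed
#' upstream, via interaction information, to a shared environmental
#' parameter (abiotic), with per-parameter counts. `pct_abiotic` follows
#' the share-rounding convention of [format_share()] and `pct_biotic` is
#' its complement, so the two always sum to 100.
#'
#' @param net `interaction_network`.
#' @param group group label.
#' @return object of class `driver_partition`: `group`, `n_biotic`,
#'   `n_abiotic`, `per_parameter` (named count vector), `pct_biotic`,
#'   `pct_abiotic`.
#' @export
partition_drivers <- function(net, group) {
  check_group(net, group)
  ed <- net$edges[edges_touching(net, group), , drop = FALSE]
  n_abi <- sum(ed$driver == "abiotic")
  n_bio <- nrow(ed) - n_abi
  per <- table(ed$driver_parameter[ed$driver == "abiotic"])
  per <- setNames(as.integer(per), names(per))
  pct_abi <- if (nrow(ed) > 0) format_share(n_abi / nrow(ed)) else NaN
  structure(list(group = group, n_biotic = n_bio, n_abiotic = n_abi,
                 per_parameter = per,
                 pct_biotic = 100 - pct_abi, pct_abiotic = pct_abi),
            class = "driver_partition")
}

#' @export
print.driver_partition <- function(x, ...) {
  cat(sprintf("%s: %d biotic (%s%%), %d abiotic (%s%%)\n", x$group,
              x$n_biotic, format(x$pct_biotic), x$n_abiotic,
              format(x$pct_abiotic)))
  if (length(x$per_parameter) > 0) {
    cat("  parameters:",
        paste(names(x$per_parameter), x$per_parameter, sep = ":",
              collapse = ", "), "\n")
  }
  invisible(x)
}
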