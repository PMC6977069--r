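---
title: "Methods: segregation analysis of co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segregation analysis of co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segnet)
```

## The object of study

`segnet` analyzes *co-occurrence networks* ("interactomes") inferred
upstream from ocean metabarcoding surveys. Nodes are OTU barcodes; an
edge records a statistically significant correlation between two
barcodes' read abundances across stations: a **copresence** when
positive, an **exclusion** when negative. Neither term implies a
mechanism — an exclusion is an abundance pattern that may reflect
grazing, parasitism, allelopathy, competition, or simply divergent
niches. Some edges are additionally labeled **abiotic** upstream (via
interaction information) when a shared environmental parameter explains
the correlation better than the two abundances alone; this package
consumes those labels and never recomputes them (inference of the
network itself is likewise out of scope).

The same unordered barcode pair may occur once per sampling stratum
(size fraction × depth layer). We keep these as distinct edge records
and **count records, not deduplicated pairs**, in every tally: pooled
group counts in the source data are pooled over strata, and the record
convention reproduces them. This is a documented choice — the
alternative (deduplicating pairs across strata) changes denominators by
a few percent and nothing else in the machinery.

## Group assignment

Groups are assigned from lineages by a **first-match ordered
configuration**: each config entry maps a group label to lineage tokens,
and the first entry matching any rank (case-insensitive, exact token)
wins. The order matters because some taxa nest (Syndiniales lineages
contain "Dinophyceae" in some reference taxonomies); listing the more
specific group first resolves them predictably. The assignment is
idempotent and derived only from the lineage, so re-running it is safe.

## Segregator classification

For group $G$, let $n_+$ and $n_-$ be the copresence and exclusion
records with at least one endpoint in $G$ (an intra-group edge counts
once). The positive-to-negative ratio $P\!:\!N = n_+ / n_-$ classifies
$G$ as a **segregator** when $P\!:\!N < 1$. Sentinels: a group with
exclusions but no copresences has ratio 0 (a segregator); with
copresences but no exclusions, $\infty$; with no edges, `NaN` — the last
two are never segregators. Shares of the network are taken over the
network-wide per-sign record totals, so shares of different groups may
sum above 1 (an inter-group edge is claimed by both its groups), while
the network-wide denominators count each record exactly once.

### Percent formatting

Printed shares in the source literature mix precisions. The package
convention (`format_share()`): round half away from zero, to integer for
shares ≥ 10%, one decimal below. The convention is a default, not a
straitjacket — `digits` overrides it, and raw fractions are always
exposed unrounded. In driver partitions `pct_abiotic` follows the
convention and `pct_biotic` is defined as its complement so the pair
always sums to 100.

## Exclusion enrichment

Whether a focal group "excludes a partner more than expected" is tested
with an exact binomial tail: among the $n$ focal–partner association
records, $k$ exclusions, and

$$p = P(X \ge k), \qquad X \sim \mathrm{Binomial}(n, p_0),$$

computed by explicit summation of density terms (no normal
approximation). The null $p_0$ is not fixed by the source analysis; the
default, `focal_global`, uses the focal group's own network-wide
exclusion fraction, so the test asks for *partner-specific excess over
the group's baseline*. An explicit $p_0$ is accepted for other nulls.
Conventions: upper tail includes $k$ itself ($\ge$, not $>$); one-sided;
no multiple-testing correction by default (matching practice in the
field for these few planned comparisons), with Benjamini–Hochberg
available in `enrichment_scan(p_adjust = "BH")`.

## Subnetwork topology

A pairwise subnetwork retains exactly the inter-group edges between a
focal and a partner group (never intra-group edges) and their incident
nodes; it is bipartite and has no isolated nodes by construction. All
topology metrics are computed on the **simple graph** (parallel stratum
records collapsed); the record count is reported alongside.

- *Components* are counted over non-isolated nodes; the empty graph has
  0. Sign-split component counts are computed on separately extracted
  sign-filtered subnetworks.
- *Density* is $2m/(n(n-1))$.
- *Centralization* is Freeman degree centralization
  $\sum_i (d_{\max} - d_i) / ((n-1)(n-2))$: 1 for a star, 0 for any
  regular graph. The star-normalized family is fixed by the "starlike"
  interpretation; degree (rather than betweenness or closeness)
  centralization matches the NetworkAnalyzer convention of the upstream
  tooling.
- *Betweenness* is shortest-path betweenness with equal split over
  equal-length geodesics, normalized by $(n-1)(n-2)/2$; it is computed
  on the pairwise subnetwork under analysis (computing it on the global
  network instead is a defensible alternative; we expose the primitive
  so users can).
- *Diameter* is taken over the **largest component**, since pairwise
  subnetworks are typically disconnected and the all-pairs diameter
  would be infinite.
- *Exclusion strength* is the mean and sample ($n-1$) sd of exclusion
  scores; a single exclusion reports sd 0 with a warning instead of an
  error so batch reports never abort. Comparisons between score sets use
  the Welch two-sample $t$ test (unequal variances,
  Welch–Satterthwaite df, two-sided).

Components, diameter and betweenness are delegated to `igraph`; the test
suite checks all metrics against independent brute-force oracles
(adjacency-matrix powers and geodesic-count dependency sums) on hundreds
of small random graphs, so the library is verified, not trusted.

## Genus and barcode level

Genus aggregation uses the annotation's genus field only (never re-parsed
from lineage strings at run time), after folding through a configurable
synonym map applied case-insensitively; the shipped starter list contains
the homotypic pair Rhizosolenia → Proboscia. Per-genus edge counts count
each record once per genus; an edge joining two genera of the same group
is counted by both, so per-genus sums can exceed the group total — this
is deliberate and documented, matching per-genus subnetwork extraction.

Rank correlations (abundance vs connectivity) are Spearman's $\rho$ via
average ranks. The two-sided $p$ is **exact for $n \le 8$** — the share
of all $n!$ permutations with $|\rho|$ at least the observed (a $10^{-12}$
slack absorbs float noise; rank-based $\rho$ values are spaced far more
coarsely) — and the usual $t$ approximation above.

`station_distribution()` reports per-station relative abundances and an
**endemicity index**: the maximum single-station share of the barcode's
own reads (1 = fully endemic, $1/k$ = uniform over $k$ stations). The
index is this package's addition, introduced to make the qualitative
"endemic and blooming" character of top excluding barcodes testable; it
is labeled non-published wherever it appears.

Top-excluder ranking is by exclusion-record count, descending, with
lexicographic barcode-id tie-breaks for determinism.

## Literature database

Records arrive as CSV with GloBI-style raw labels, normalized through a
shipped mapping table (`eatenBy` → predation, etc.; unknown labels are
an error naming the label). Habitats normalize to
marine/freshwater/both/unknown. Records describing attachment to
nonliving surfaces (epipsammic/epipelic) are dropped at read time with a
warning — they are not biotic interactions. Records without a diatom
genus are kept but flagged unresolved and excluded from matching.

Matching against the network is at **genus resolution only** (species
fields are carried but unused): a record is *potential* if its diatom
genus matches a barcode of the focal group and its partner genus matches
any barcode in the network (both after synonym folding,
case-insensitive); *recovered* if at least one edge record joins
barcodes of the two genera. Matched network edges are pooled over
recovered records and deduplicated per record. Interaction type plays no
role in matching — a correlation carries no mechanism — and is reported
only for interpretation.

## The synthetic world

The generator's defaults state a scaled-down (~30×) analogue of the
published open-ocean interactome: eight plankton groups (diatoms,
dinophytes, Syndiniales, copepods, MAST, polycystines, a green-algal
control, and an edge-free radiolarian group whose genera supply
"potential but not recovered" literature pairs), 2,320 edges with
diatom and polycystine pairs exclusion-dominated and the rest
copresence-dominated, a 13% abiotic fraction with six parameter names,
copresence scores ~ truncated normal(0.66, 0.09) on (0, 1] and exclusion
scores the mirror image (both bounded away from 0 so the sign/score
invariant holds by construction), 126 stations (the full station set of
the emulated survey), three endemic diatom barcodes planted at single
stations, and a literature database of 150 records following the
published proportions of potential (178/1533) and recovered (33/1533)
interactions. These defaults were chosen once from the stated properties
of the emulated data and are not tuned to test outcomes.

One integer seed governs everything through a documented splitting rule
(`stage_seed = (seed × 48271 + stage) mod (2³¹ − 1)`, stages: barcode
identities, network, abundance, literature), so stages compose
reproducibly regardless of call order and equal seeds give byte-identical
output bundles.

What the generator does **not** emulate: compositionality and sparsity
of real read counts, spatial autocorrelation between stations, lineage
misannotation, stratum-correlated duplicate edges, or literature records
with unresolved genera. A green test on synthetic data therefore
establishes the correctness of the accounting and the statistics under
the stated model — not robustness to those real-data pathologies.

## Numerical choices and degenerate inputs

- Scores of exactly 0 are rejected (the upstream network contains only
  significant nonzero correlations); accepting them would create a
  silent third sign class.
- Binomial tails are exact sums; the suite requires agreement with an
  independent Bernoulli-convolution oracle to $10^{-12}$ for $n \le 20$.
- Welch test: degenerate (both-samples-constant) input is an error;
  identical samples with positive variance give $t = 0$, $p = 1$.
- Zero-edge groups report `NaN` ratios rather than erroring, so
  whole-network scans do not abort.
- In trophic-mode partner breakdowns an intra-group edge is attributed
  to the `node_b` endpoint's trophic mode (under taxonomic grouping both
  endpoints give the same label, so the choice is inert there).

## Known limitations

- Betweenness on networks of ~10⁵ edges is delegated to igraph's exact
  algorithm; no approximation is provided.
- The abiotic/biotic partition is only as good as the upstream edge
  labels; the package cannot detect mislabeled drivers.
- Genus matching cannot recover interactions recorded above genus level
  (family-level literature records are simply never potential).
- The CLI is a thin layer over the R API; it does not stream, and very
  large GraphML exports are memory-bound.
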