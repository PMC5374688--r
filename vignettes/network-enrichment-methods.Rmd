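---
title: "Network enrichment with a parametric binomial null: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network enrichment methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netenrich)
```

## The model

Network enrichment analysis (NEA) scores the functional association
between an *altered gene set* (AGS) and a *functional gene set* (FGS)
by the number of edges of a global functional-coupling network that
connect the two sets. The null model is the configuration model: edges
are formed by pairing degree "stubs" at random, so the chance that a
stub lands in a set is proportional to the set's degree sum. With
`N_AGS` and `N_FGS` the degree sums of the two sets and `N_total` the
number of network edges, the expected connecting-edge count is

$$\hat n = \frac{N_{AGS}\, N_{FGS}}{2\, N_{total}}.$$

The observed count $n$ excludes edges lying entirely within either set;
only edges between $AGS \setminus FGS$ and $FGS \setminus AGS$ are
counted. The pair is scored by a 1-df chi-squared on the partition of
all `N_total` edges into connecting and non-connecting
($!n = N_{total} - n$):

$$\chi^2 = \frac{(n-\hat n)^2}{\hat n} + \frac{(!n-\,!\hat n)^2}{!\hat n},$$

with $p$ the upper tail of $\chi^2_1$ and the direction restored as
$z = \mathrm{sign}(n-\hat n)\sqrt{\chi^2}$ — chi-squared lives on the
non-negative axis, so depletion is coerced to negative z. Q-values are
Benjamini–Hochberg over all cells of the AGS × FGS matrix jointly; the
adjustment is only meaningful with a few hundred or more tests, and
`nea_render()` warns below 200.

Assumptions worth keeping in mind:

* **Unweighted edges.** Confidence columns in network files are parsed
  (`keep_weights = TRUE`) but never scored; the model counts edges.
* **Scale-free topology.** The parametric null is unbiased on networks
  with power-law degree distributions, the usual case for full-scale
  functional-coupling networks but not for, e.g., networks assembled
  from binding-site predictions. `connectivity()` (degree histogram and
  log–log fit) and `topology2nd()` (mean neighbor degree per degree
  class, degree–degree assortativity) exist to check this before
  trusting the parametric score; when in doubt, `nrz()` provides the
  randomization-based estimate on the same statistic.
* **Direct edges only.** The expectation is first-order; higher-order
  topological structure (e.g. hubs avoiding hubs) is visible in
  `topology2nd()` but deliberately not corrected for.

## Overlap accounting

The two denominator conventions and the overlap treatment were the two
genuinely open design points.

**Chi-squared denominators.** The historical formula divides the squared
deviations by the *observed* counts $n$ and $!n$, which is undefined at
$n = 0$ — a common situation for small sets. The package therefore
defaults to the Pearson convention (expected-count denominators,
`variant = "pearson"`), which is defined everywhere and asymptotically
equivalent; the observed-denominator form remains available as
`variant = "printed"` and falls back to Pearson (with a warning) for
cells it cannot score.

**Shared genes.** Genes in $AGS \cap FGS$ contribute no countable edges
(any edge touching them inside either set is "within-set"), so an
expectation built from full-set degree sums systematically overshoots
whenever sets overlap. The mismatch is not cosmetic: on a 2000-node
synthetic network with 30 random sets of 10–300 nodes, full-set
accounting produces artifactual depletion z-scores beyond −6 for
strongly overlapping pairs, pushes the null fraction of p < 0.05 to
about 0.15–0.18, and caps the rank agreement with the randomization
test at Spearman r ≈ 0.51. Removing shared genes from both degree sums
(`strict_overlap = TRUE`, the default) restores calibration (null
fraction ≈ 0.04) and r ≈ 0.99 — the behavior a correct implementation
of the model must show, since the randomization test measures the same
excluded-edge statistic. The full-set accounting is kept as
`strict_overlap = FALSE` for comparability. A corollary users should
know: an AGS entirely contained in an FGS has no countable edges and no
signal — containment is GSEA's territory (`gsea_render()`), not the
edge statistic's.

## The randomization comparator

`rewire_network()` performs degree-preserving double-edge swaps: two
edges $(i,j), (k,l)$ are replaced by $(i,l), (k,j)$ (or $(i,k), (j,l)$)
unless that would create a self-loop or duplicate edge. One call makes
`round(swaps_per_edge * N_total)` attempts; the default
`swaps_per_edge = 10` is a standard mixing heuristic — enough that the
edge set is thoroughly shuffled (Jaccard overlap with the original well
below 1) while every node keeps its exact degree. `nrz()` scores each
pair as $z = (n_{obs} - \bar n)/s$ with $\bar n, s$ the mean and
sample (n−1) standard deviation over `n_permutations` rewired
instances, and a two-sided Gaussian p-value (the chi-squared p of the
parametric test is likewise two-directional). Pairs whose count never
varies are flagged (`sd_zero`), with p = 1 when the observation equals
the permutation mean. Permutation $k$ is seeded `seed + k`, so runs
with different `n_permutations` share a common prefix stream and
parallel or incremental execution cannot change results.

`convergence_experiment()` packages the validation design: one
collection scored all-vs-all with both methods, Spearman correlation of
log10 p-values per randomization count, and a per-pair table carrying
the three factors that bias the randomization test — total set size in
nodes, total degree sum, and observed edge count — each cut into
exhaustive disjoint strata. Pairs with undefined NRZ z or zero observed
edges are excluded from the correlation but counted (never silently
dropped); zero-edge pairs carry no rank information for a log-p
comparison. The expected pattern, and what the test suite asserts, is a
monotone increase of r with the randomization count, r ≥ 0.99 at 300
randomizations, and — on collections containing very small sets — a
higher median randomization p than parametric p for pairs of ≤ 10 total
nodes: between-set counts cannot go negative, so the randomization
standard deviation is compressed and small sets lose sensitivity.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `variant` | scoring | `"pearson"` | chi-squared denominator convention |
| `strict_overlap` | scoring | `TRUE` | remove shared genes from degree sums |
| `jobs` | `nea_render` | 1 | forked workers for edge counting; never changes values |
| `swaps_per_edge` | rewiring | 10 | swap attempts per edge and randomization |
| `n_permutations` | `nrz` | 100 | rewired instances (≥ 2; ≥ 100 for stable sd) |
| `negatives_per_positive` | benchmark | 1 | degree-matched impostors per held-out member |
| `degree_tolerance` | benchmark | 0.25 | relative degree window for matching |
| `cutoff`, `alpha` | `ags_significant` | — | strict \|score\| threshold; non-strict adjusted-p bound |
| `boost` | `make_planted_fgs` | 10 | module density as multiple of background |

## Numerical choices and degenerate inputs

* **z cap at 38.** Beyond |z| = 38 the Gaussian tail underflows double
  precision, so cells with $\hat n = 0, n > 0$ (possible only in
  degenerate user-supplied networks) and any overflow are capped at
  $\chi^2 = 38^2$; the randomization p is floored at `2*pnorm(-38)`
  symmetrically.
* **0/0 cells score 0**; only a zero denominator with a nonzero
  numerator triggers the cap.
* **Ties.** `ags_top()` breaks boundary ties by gene id in C-locale
  lexicographic order; ROC thresholds group tied scores, making the
  trapezoidal AUC equal to the Mann–Whitney pairwise-ordering
  probability.
* **Missing scores** are excluded from AGS building with a per-column
  count message; p-values entering `bh_adjust()` must be complete.
* **Degenerate networks.** Single-edge networks cannot be rewired and
  are returned with a warning; edgeless networks error in scoring and
  second-order topology; fewer than 3 distinct degrees flag the
  power-law fit as absent rather than fabricating a slope.
* **Benchmark matching.** If no out-of-set gene lies within the degree
  window, the window doubles (warning) up to 4 times, then the case is
  skipped and counted — silently dropping cases would bias the ROC.
* The held-out gene is removed from its FGS before scoring in the
  benchmark: scoring `{g}` against a set still containing g would
  exclude exactly the edges that carry the signal.

## What the synthetic generators emulate — and what they do not

`make_scalefree_network()` grows a preferential-attachment graph (m
distinct targets per new node, attachment weight degree + 1), giving
exactly `m * (n_nodes - m)` edges and a heavy-tailed degree
distribution with a log–log slope around −2. `make_planted_fgs()`
densifies disjoint node sets to `boost` times the background edge
density, both among members and toward a per-set shared neighbor pool,
so that module structure is visible to both the enrichment statistic
and the member-recovery benchmark; the default boost of 10 reflects the
order of internal-density enrichment typical of curated pathways over
interactome background. `make_expression_matrix()` produces log2-scale
two-group expression with a planted fraction of shifted genes
(default effect 4 log2 units, replicate noise sd 0.5, 3 + 3 samples)
and a ground-truth table for recall checks.

Real data differ in ways these generators deliberately do not imitate:
real interactomes have cliquishness, disassortativity and ascertainment
bias (well-studied genes have more edges) beyond what preferential
attachment produces; real pathway collections overlap heavily and have
skewed size distributions; real expression has correlated genes and
heteroscedastic noise. Passing tests therefore demonstrate correctness
of the statistics and calibration under the stated null — not that any
particular biological network is adequate, which is exactly what the
benchmark and topology diagnostics are for on real inputs.

## Validation problem sizes

The shipped validation uses sizes chosen to exercise the asymptotics
while staying comfortable on a laptop: exact brute-force equivalence on
200 random graphs of ≤ 50 nodes; degree conservation over 50 rewirings
of a 2000-node network; the convergence experiment on a 2000-node,
~10,000-edge network with 30 sets (10–300 nodes) at 3–300
randomizations; null calibration on 900 random set pairs; and ROC
benchmarks with ~500–1000 cases. `scripts/acceptance.R` re-runs the
N = 300 convergence from scratch for any seed.

## Known limitations

* Directed, weighted, and multi-layer networks are out of scope; so is
  merging alternative networks under confidence cutoffs.
* The second-order-preserving ("over-randomization") null is not
  implemented; `topology2nd()` only diagnoses such structure.
* The Fisher comparator is the overlap (binomial) form of GSEA, not the
  rank-based form, and uses one-sided enrichment tails with the network
  nodes (when available) as universe.
* Differential-expression estimation itself is upstream: AGS builders
  consume score matrices (e.g. log2 fold changes) as given, without
  internal normalization.
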