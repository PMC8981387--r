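---
title: "Differential metabolites and pathway signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential metabolites and pathway signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsig)
```

## The analysis problem

Untargeted metabolomics platforms quantify hundreds of metabolites as raw
chromatographic peak areas per tissue sample. In a two-group design —
here sham controls (D0) versus animals exposed to five days of controlled
mechanical ventilation (D5), across diaphragm, intercostal muscle and lung —
the questions are: which metabolites change (differential metabolites, DMs),
which metabolic sub-pathways change coherently (pathway signatures), and
which DMs sit at the center of the metabolite–metabolite interaction
network (hubs). `metsig` implements that pipeline end to end, plus a
synthetic generator with planted ground truth so every stage can be
validated without access to the original animal data.

## Preprocessing model

Raw peak areas are strictly positive, roughly log-normal, and carry
multiplicative instrument-batch effects and left-censored missingness
(values below a detection limit are simply absent). The chain in
`normalize_study()` is:

1. **Batch median scaling** (`median_scale()`): each metabolite's values
   within each batch are divided by the within-batch median of the observed
   values, giving every batch — and hence the metabolite — median 1. A
   multiplicative batch factor shared by all samples in a batch is removed
   *exactly* by this step; a property test verifies bit-level agreement
   between scaled data simulated with and without batch effects.
2. **Minimum imputation** (`impute_minimum()`): missing cells are replaced
   by the metabolite's minimum observed scaled value. This is the right
   imputation under left-censoring — the unobserved value was at most as
   small as the smallest observed one — and is meaningless under
   missing-at-random dropouts, which is why the generator censors at a
   detection limit rather than dropping cells at random.
3. **Natural-log transformation** (`log_transform()`). The log base only
   rescales test statistics by a constant and leaves p-values and DM calls
   unchanged; fold changes are computed on the pre-log scale, so the base
   never reaches any reported number.

Metabolites observed in fewer than 2 samples have no usable variance and
are dropped with a logged message before imputation. The even-count median
is the conventional midpoint of the two central values.

## Differential metabolites

Per metabolite, the two-sided p-value comes from a two-group fixed-effect
linear model on the logged data — with one observation per animal per
tissue there is no random-effect structure, so this is the pooled-variance
t-test, and `fit_differential()` computes it vectorized across metabolites
(a test pins it to `stats::t.test` / `lm` to 1e-12). The fold change is the
ratio of D5 to D0 arithmetic group means on the median-scaled imputed
scale (`fc_method = "log_mean"` switches to the anti-log of the mean log
difference); the absolute fold change is `max(FC, 1/FC)`, symmetric in
direction.

A metabolite is a DM when `p < 0.05` (strict) **and** `|FC| >= 1.5`
(inclusive). No multiple-testing correction enters the call — the
published procedure uses raw p-values — but a Benjamini–Hochberg column is
emitted for information. Degenerate rows: both groups constant and equal
gives p = 1 (conservative); constant but unequal gives p = 0 flagged as
degenerate. An exact FC tie is labelled "up" but can never pass the cutoff.

Two consequences worth knowing:

* **Calibration**: dividing by a within-batch median estimated from ~5
  samples perturbs the t-test slightly; over 200 null replicates we measure
  a false-positive rate of ~0.054 with two 5-sample batches versus 0.050
  with a single batch. This is a property of the published preprocessing,
  not of the test; the calibration check in the test suite therefore runs
  on the single-batch null.
* **False-discovery proportion is prevalence-dependent**: with raw-p
  calling, the FDP among DMs depends on how many metabolites truly change.
  The recovery scenario in the test suite plants ~36% of metabolites as
  differential, matching the 29.6–42% DM percentages the study design
  anticipates; at much lower prevalence the same thresholds yield a higher
  FDP.

Overviews mirror the standard figure products: `pca_overview()` (centered
SVD scores, components sign-fixed so the largest-magnitude loading is
positive), `hierarchical_clustering()` (average linkage on Euclidean
distances of row-standardized logged values; inputs are id-sorted first so
leaf order is deterministic), `venn_counts()` for the 7 regions of the
three-tissue detected/DM overlaps, and volcano-plot tables
(log2 FC, −log10 p).

## Pathway signatures: zscore and enrichment value

Two statistics score each sub-pathway over the DMs it contains:

* **Direction zscore** `(up − down) / sqrt(up + down)`, where `up` and
  `down` count increased and decreased DMs in the pathway. Under a
  fair-coin null on directions, `up − down` has standard deviation
  `sqrt(count)`, making this an actual z statistic; it is bounded by
  `±sqrt(k)` with equality exactly when all DMs move one way. The
  plain-count denominator (which rescales into [−1, 1]) is available via
  `denominator = "count"` for comparison, but the square-root form is the
  default: it is the standard form of the statistic and the one consistent
  with all published worked examples (15 all-up → 3.87, 11 all-down →
  −3.32, and so on).
* **Enrichment value** `EV = (k/m) / ((n − k)/(N − m))`: the odds-style
  ratio of the DM proportion inside the pathway (k of m detected named
  members) to the DM proportion outside it (n − k of N − m), on the
  *named-metabolite* background. Unnamed "X-#####" compounds stay DMs for
  volcano/Venn purposes but are excluded from every EV margin, including
  `n` (kept consistent with `N`; counting unnamed DMs in `n` alone would
  mix backgrounds). `EV = 1` exactly when the in- and out-of-pathway DM
  proportions match, and `EV > 1` iff one-sided hypergeometric enrichment
  is more extreme than depletion on the same margins (property-tested).
  `n = k` (every background DM in this pathway) yields an `Inf` sentinel.

A pathway is a **signature** when `|zscore| >= 2.5`, `EV >= 1.5` and
`k >= 5`. Pathways failing `k >= 5` remain listed with
`is_signature = FALSE` so sub-threshold pathways (e.g. a TCA-cycle set
with 4 DMs) stay reportable. zscore and EV are rounded to 2 decimals only
at reporting time; internal comparisons are unrounded.

## MSEA

`msea()` is a GSEA-style weighted Kolmogorov–Smirnov running sum:
metabolites are ranked by `sign(log FC) · (−log10 p)` (the assumed ranking
statistic; p floored at 1e-300), hits contribute `|stat|^w` (w = 1,
normalized over the set) and misses subtract `1/(n − n_hits)`; the
enrichment score is the running sum at its largest absolute excursion.
The null is **set-label permutation**: `n_perm` (default 1000) random
same-size sets drawn from the per-tissue background of named detected
metabolites. `NES = ES / mean(|permuted ES| of matching sign)` and the
p-value is add-one corrected over matching-sign permutations, so p is
never exactly 0 and results are deterministic given the seed. Sets with
fewer than 2 detected members are skipped with a warning. A set spanning
the whole background has no misses, so its running sum climbs to ES = 1 by
construction; such rows are flagged `degenerate` and their permutation p
saturates at 1 — "no contrast", rather than a meaningless score.
`compare_tissues()` assembles the union of pathways with ≥ 5 DMs in any
tissue and distinguishes "not detected" (no background members in that
tissue) from detected-but-non-significant.

## Interaction network hubs

`build_subnetwork()` induces the DM subgraph of a user-supplied
chemical–chemical edge list (STITCH-convention confidence scores 0–1000),
keeping edges with score ≥ 700 — the conventional "high confidence" tier;
the threshold is an argument. Duplicate pairs collapse to their maximum
score, self-loops are dropped, and isolated DMs are reported rather than
kept as degree-0 vertices. `rank_hubs()` computes exact unweighted
shortest-path betweenness (scores filter, they do not weight), normalized
within each connected component by `(nc − 1)(nc − 2)/2` so disconnected
components are ranked jointly on a comparable scale; ties break by degree
(descending) then id (ascending). A brute-force oracle — shortest-path
counts from adjacency-matrix powers — verifies the betweenness on 100
random graphs of up to 15 nodes in the test suite.

## The synthetic generator

`simulate_study()` draws
`area = exp(base + effect · [D5] + batch + noise)` with
`base ~ N(base_log_mean, base_log_sd)` per metabolite, batch factors shared
across metabolites, iid residual noise, planted effects `±log(fold)` on
designated sub-pathway sets, and left-censoring below the metabolite's
`dropout_quantile` detection limit. Defaults (chosen once, as the study
conditions the pipeline should be validated under):

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 5 per group | the study design (4 after the lung exclusion) |
| `n_metabolites` | 200 (817/786/941 at study scale) | detected-panel sizes |
| `n_batches` | 2 | smallest configuration that exercises batch scaling |
| `batch_effect_sd` | 0.5 | visible multiplicative shifts (≈ ±65%) that scaling must remove |
| `base_log_mean`, `base_log_sd` | 13, 1.5 | peak areas ~ 4e5 spanning ~3 orders of magnitude |
| `noise_log_sd` | 0.4 | within-group CV ≈ 40%, typical for untargeted tissue panels; gives fold-3 effects ~94% single-test power at n = 5 |
| `dropout_quantile` | 0.1 | ~10% left-censored cells, enough to exercise imputation |
| planted folds | 3 | comfortably above the 1.5 cutoff, as signature-pathway members are |

All draws are standard normals scaled by the config, so RNG consumption —
and therefore every other simulated number — is invariant to changes in
the SD parameters; each tissue gets its own stream derived from
`(seed, tissue)`, so adding a tissue never perturbs another tissue's data.
`simulate_multi_tissue()` shares a core panel across tissues (sized by
`tissue_overlap_fraction` or an explicit `n_core`, e.g. 680 of 817/786/941)
with disjoint tissue-private remainders, and plants the differential sets
inside the core. `simulate_edge_list()` overlays designated high-degree
hubs (high-confidence scores) on an Erdős–Rényi background.

What the generator deliberately does **not** emulate: chromatography,
adducts/isotopes, correlated metabolite blocks, heavy-tailed or
heteroscedastic noise, and batch effects that vary by metabolite. Passing
tests therefore demonstrate that the pipeline's statistics behave as
specified under the stated model — not that real tissue data satisfy that
model.

## Numerical choices and degenerate inputs

* Strict `<` on p, inclusive `≥` on |FC|, per the published cutoff wording.
* Even-count medians: midpoint convention.
* Metabolite missing in one batch but observed in another: scaled cells in
  the all-missing batch stay missing and are filled by minimum imputation;
  missing in *all* batches: dropped with a warning.
* `pathway_zscore(0, 0)` and `EV` with `m = 0` or `N = m` are errors, not
  NaNs.
* Report-level rounding is 2 decimals for zscore/EV and 1 for DM
  percentages; all TSV outputs carry full precision (15 significant
  digits), and write/read round-trips are tested to 1e-12.

## Problem sizes in the shipped checks

The test suite validates calibration and recovery on 200-replicate
simulations of 100-metabolite panels at n = 5 per group (seconds on one
core), the betweenness oracle on 100 random graphs of ≤ 15 nodes, and one
study-scale three-tissue run (817/786/941 metabolites, core 680). The
`analysis/` scripts run the same study-scale configuration with 1000 MSEA
permutations. These sizes were chosen so the full suite exercises every
stage, including end-to-end determinism, at desk scale.

## Known limitations

* The linear model is group-only; covariates or repeated measures are out
  of scope.
* MSEA's ranking statistic and permutation scheme are reasonable defaults,
  not a reimplementation of any specific web tool; NES values are
  comparable within a run, not across tools.
* Hub selection uses betweenness with a degree tie-break; composite
  centralities are not implemented.
* Pathway membership comes solely from the annotation table; there is no
  pathway-database retrieval or topology-aware scoring.
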