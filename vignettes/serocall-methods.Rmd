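---
title: "Methods: normalization, reactivity calling and association analysis for antigen arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalization, reactivity calling and association analysis for antigen arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serocall)
```

## The analysis problem

Affinity-proteomics antigen arrays measure IgG binding of plasma samples to
large collections of recombinant protein fragments. A typical autoantibody
discovery study runs in two phases. First, an *untargeted* screen tests a
small number of pooled samples against a nearly proteome-wide planar array
(tens of thousands of antigens) to nominate candidate targets. Second, a
*targeted* bead array carrying a few hundred antigens — the planar
candidates plus literature-reported targets — screens the full case-control
cohort, and the resulting median-fluorescence-intensity (MFI) matrix is
turned into binary reactivity calls, per-sample autoantibody loads,
prevalence statistics, biomarker panels and patient clusters.

serocall implements that full analysis path, together with a synthetic-data
generator that emulates both phases with known ground truth, so that every
stage can be validated end to end without access to patient data.

## Normalization

Two robust transforms are provided.

**Array-wise nSD** (planar phase). Each antigen's raw intensity on one
array is expressed as the number of standard deviations from the array
mean: `nSD = (x - mean(x)) / sd(x)`. The standard deviation uses the
population convention (divide by `n`) by default; at proteome-wide array
sizes the difference from the sample convention is far below any decision
threshold, but the choice is fixed and configurable (`sd_type`) so results
are exactly reproducible.

**Sample-wise nMAD** (bead phase). Bead-array samples differ in overall
background level (sample quality, total IgG, dilution). Each sample row is
centered on its median and scaled by its median absolute deviation:
`nMAD = (x - median(x)) / MAD(x)`. The MAD is used *raw*, without the
1.4826 normal-consistency factor: the statistic is a unit of spread in its
own right, not an estimate of a Gaussian sigma. After the transform every
row has median 0 and MAD 1 (checked to 1e-9 in the tests), and the
transform is exactly invariant to any per-sample affine background
`a*x + b` (a > 0) — which is precisely the distortion it exists to remove.
The median of an even-length vector is the mean of the two central order
statistics. Rows with zero MAD (more than half of the values identical) are
rejected with the sample named; an `exclude` argument removes designated
columns (e.g. control beads) from the row statistics while still
transforming them.

## Planar candidate selection

Antigens are selected from the two-pool planar screen when their nSD in the
diffuse-disease (dcSSc-like) pool reaches a cutoff — 4 SD by default — and
exceeds the limited-disease pool by more than `min_difference` (default 0:
any excess counts, since no margin is defensible a priori). Ranking uses a
composite of two orderings, by descending dcSSc nSD and by descending pool
difference, averaged and tie-broken by antigen id. The composite was chosen
because it yields a reproducible total order without inventing weights for
the two criteria; both single-key orderings remain available via `rank_by`.

A practical caveat, verified on the generator: because the array mean and
SD are not robust statistics, selection recall degrades when elevated
antigens stop being a tiny minority. At 59 hits among 42,000 antigens
(0.14% contamination) recall of +8 SD hits exceeds 0.9; at 59 among 2,000
(3%) the inflated SD depresses hit nSD values by almost half and recall
drops to roughly 0.85. The method assumes proteome-wide sparsity.

## Reactivity calling

The bead phase thresholds each antigen independently, based on the
distribution of its normalized signals across all samples. The default
`antigen_mad` rule sets `cutoff = max(floor, median + c * MAD)` per antigen
column, with `c = 5` and `floor = 5` nMAD. The rule mirrors the
robust-statistics style of the rest of the workflow, is monotone in both
parameters (raising `c` or `floor` never adds positive calls), and is
reproducible from its parameters plus the data. A sample is called reactive
(1) when its value strictly exceeds the cutoff; ties are negative. Antigen
columns with zero MAD fall back to the floor-only cutoff, with a message. A
`fixed` single-threshold strategy supports sensitivity analysis, and
`allow_unnormalized` permits calling on raw intensities, without
endorsement.

Several antigens (80–100-residue protein fragments) may represent one
protein; `protein_level_calls()` ORs the fragments of each protein, and
downstream statistics are intended to run at whichever level the question
requires (the package does not force one).

## Association statistics

All group comparisons are nonparametric, matching the binary/count nature
of the data:

* **Autoantibody load** (binary row sum per sample) is compared between two
  groups by the two-sided Mann–Whitney–Wilcoxon test (exact for small
  tie-free samples, normal approximation with tie correction otherwise)
  and across three or more groups by Kruskal–Wallis with tie correction.
* **Load–age correlation** is Spearman by default, consistent with the
  rank-based toolkit; Pearson is available because the choice between the
  two is genuinely open for this quantity.
* **Prevalence** uses the two-sided Fisher exact test. Two-sided exact
  conventions differ between software packages, so the package pins one:
  the point-probability rule — the sum of probabilities of all tables with
  the observed margins whose probability does not exceed the observed
  table's (relative tolerance 1e-7) — computed by direct enumeration of the
  hypergeometric support. The test suite verifies equality with a
  brute-force log-binomial enumeration oracle on every 2x2 table with total
  n ≤ 40 (tolerance 1e-12) and cross-checks `stats::fisher.test`.
* **Selection rule** for panel candidates: a target is selected when its
  case prevalence significantly exceeds the control prevalence (raw
  p < 0.05 with a strict case excess), or when it shows any strict case
  excess while binding a fibrosis-related protein. Raw p-values are the
  default because the screening context treats the rule as a candidate
  filter, not a confirmatory claim; Benjamini–Hochberg adjustment is
  available and labeled.
* **Panel augmentation** reports the percent of cases positive on the
  clinical antibody panel before and after OR-ing in an array marker.

Percentages are reported as whole numbers rounded half-up
(`round_half_up()`), the convention that reproduces the cohort arithmetic
41/55 → 75%, 3/8 → 38%, 4/9 → 44%. Note that under this (or any
consistent) rule 9/13 is 69%, and the underlying fraction is always
reported alongside.

Fisher's exact test is conservative on discrete tables: at 55 cases / 52
controls its attained size is strictly below the nominal 0.05 and
approaches it only as table margins grow rich. The calibration test in the
suite therefore runs at a per-antigen positivity of 0.3 — the top of the
realistic range, where discreteness is mildest — and even there the true
rejection rate sits near 0.04, so a single 1,000-antigen calibration draw
can fall a little more than 3 Monte-Carlo SE below 0.05 without indicating
any defect.

## Count classifier and clustering

The panel classifier is deliberately the count rule, not a continuous
score: a sample is positive when its panel load is at least `k`. The ROC
curve is built from the discrete family `k = 0 .. k_max + 1`, anchored at
(0,0) and (1,1), and the AUC is the trapezoid area over that step curve.
When `k_max` covers the maximum load this equals the Mann–Whitney
probability-of-correct-ordering with half-credit ties, an identity the
tests assert to 1e-12.

Clustering operates on binary profiles with simple-matching (Hamming
proportion) distances — chosen over Jaccard because entirely seronegative
patients are a real and interesting group, and Jaccard is undefined between
zero vectors — and complete linkage, cut at `k = 4` by default; distance
and linkage are configurable, and a mean silhouette width is reported as a
diagnostic but never used to auto-select `k`. Two determinism measures are
built in: rows are put in canonical sample-id order before linkage (the
agglomeration order under tied binary distances otherwise depends on input
order), and clusters are renumbered by decreasing mean within-cluster
positivity, so the least-reactive cluster always receives the highest
label. Per-cluster summaries report the percent of members positive for
each clinical feature among non-missing values only — missingness is a
distinct state throughout the package and is excluded, never imputed —
and `cluster_membership()` answers cross-cluster questions such as "what
fraction of the high-skin-score patients sit in clusters 1 or 2".

## The synthetic cohort generator

`simulate_bead_cohort()` emulates the targeted phase with known truth:

* **Background**: log-normal MFI, meanlog 6 and sdlog 0.25 by default
  (backgrounds of a few hundred MFI), times a per-sample log-normal
  multiplicative shift (sdlog 0.3). The multiplicative-shift form was
  chosen because sample-wise nMAD normalization is designed to remove
  exactly such level differences, making normalization's purpose testable:
  the tests compare shifted and shift-free simulations and require the
  shift's between-sample variance inflation to vanish after normalization.
* **Reactivity**: 132 of 246 antigens (the defaults) carry true
  reactivity; each reactive sample-antigen pair multiplies the background
  by `exp(3)` (about 20-fold, far beyond 10 nMAD). Default per-antigen
  positivity probabilities are 0.10 in cases and 0.04 in controls —
  mid-range of a sparse reactivity landscape in which each reactive
  antigen is positive in roughly one to a few tens of 107 samples, with a
  modest case excess in overall load.
* **Clinical structure**: metadata marginals follow the study-group table
  (84% female cases, median case age near 61, subtype split 42/11/2,
  14/55 lung fibrosis, 13/55 mRSS > 15 with 8/55 having both, the
  clinical-antibody counts nested inside a 41/55 clinical-panel-positive
  set). Cases with lung fibrosis or mRSS > 15 receive an additive
  positivity boost (0.05 per feature) on reactive antigens, so the load
  ordering both-features > one feature > neither is true by construction
  and recoverable.
* **Determinism**: a single seed drives one RNG stream; identical configs
  give bit-identical outputs.

`simulate_planar_pools()` emulates the untargeted phase: two pool vectors
over a shared log-normal background with a chosen number of antigens
elevated by a chosen number of background SDs in the first pool.

What the generator does *not* model — and what passing tests therefore do
not establish about real data: the true MFI distribution family (the
log-normal is a stand-in), antigen-specific background differences, bead
count/QC failures, plate and batch effects, tag-reactive antibodies,
cross-reactivity between fragments of different proteins, and any
correlation structure among autoantibodies beyond the fibrosis load boost.

## Problem sizes and numerical choices

The test suite and the reproduction script run the cohort pipeline at the
study scale (107 samples x 246 antigens), Fisher calibration on 1,000
simulated null antigens, recovery on 500 case-enriched antigens,
planar-selection recall at the proteome-wide scale (42,000 antigens), and
exhaustive Fisher-oracle checks over all 2x2 tables with n ≤ 40 — sizes at
which every stage's behavior is measurable with tight Monte-Carlo error
while the full suite stays fast. Numeric tolerances: nMAD row identities to
1e-9; exact-test oracle agreement to 1e-12; strict-inequality calling with
ties negative; half-up percentage rounding.

## Known limitations

The cohort-specific headline numbers of any real study (reactive-antigen
fraction, specific Fisher p-values, panel AUC, classification rates)
depend on the measured data and are not reproducible from simulation;
serocall reproduces the *procedures* and validates them on ground-truth
synthetic data. Fisher conservatism (above) means nominal-level calibration
is approximate for exact tests on small cohorts. The planar selection step
assumes hit sparsity. Hierarchical clustering of binary profiles with few
targets has limited resolution, and `k` is a reporting choice, not an
estimate.
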