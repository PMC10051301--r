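Package: serocall
Title: Antigen-Array Autoantibody Profiling: Normalization, Reactivity
    Calling and Case-Control Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A two-phase analysis pipeline for affinity-proteomics antigen
    arrays. Phase one screens planar-array sample pools with array-wise
    robust standardization (nSD) and a standard-deviation cutoff to select
    candidate antigens; phase two analyses a targeted bead-array cohort
    with sample-wise median/MAD normalization (nMAD), per-antigen robust
    cutoffs for binary reactivity calling, autoantibody-load statistics
    (Mann-Whitney-Wilcoxon, Kruskal-Wallis, rank correlation), exact
    case-control prevalence testing, biomarker panel selection and
    augmentation arithmetic, a count-cutoff panel classifier with ROC/AUC,
    and hierarchical clustering of binary reactivity profiles. Includes a
    synthetic-data generator emulating both array phases with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, graphics
Suggests: testthat (>= 3.0.0), cluster, mclust, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
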