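#' Per-sample autoantibody load
#'
#' The autoantibody load is the number of distinct positive reactivity
#' calls per sample (binary row sums).
#'
#' @param calls binary sample-by-target matrix.
#' @return named integer vector of loads.
#' @export
autoantibody_load <- function(calls) {
  stopifnot(is.matrix(calls), all(calls %in% c(0L, 1L)))
  out <- as.integer(rowSums(calls))
  names(out) <- rownames(calls)
  out
}

#' Compare autoantibody load between two groups
#'
#' Two-sided Mann-Whitney-Wilcoxon test: exact for small samples without
#' ties, normal approximation with tie correction otherwise (the standard
#' convention of [stats::wilcox.test()]).
#'
#' @param load numeric vector of per-sample loads.
#' @param labels vector with exactly two non-empty groups, aligned with
#'   `load`.
#' @return list with `test`, `p_value`, `group_medians`, `group_n`.
#' @export
compare_load <- function(load, labels) {
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) != 2) stop("labels must define exactly two groups")
  x <- load[labels == groups[1]]
  y <- load[labels == groups[2]]
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  meds <- c(stats::median(x), stats::median(y))
  names(meds) <- groups
  list(test = "Mann-Whitney-Wilcoxon", p_value = unname(ht$p.value),
       group_medians = meds,
       group_n = stats::setNames(c(length(x), length(y)), groups))
}

#' Compare autoantibody load across three or more groups
#'
#' Kruskal-Wallis rank-sum test with tie correction; chi-square p-value
#' on k - 1 degrees of freedom.
#'
#' @param load numeric vector of per-sample loads.
#' @param labels vector defining k >= 3 non-empty groups.
#' @return list with `test`, `statistic` (H), `df`, `p_value`,
#'   `group_medians`, `group_n`.
#' @export
compare_load_multi <- function(load, labels) {
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 3) stop("need at least three groups (use compare_load for two)")
  n_by <- table(labels)
  if (any(n_by == 0)) stop("all groups must be non-empty")
  ht <- stats::kruskal.test(load, factor(labels))
  meds <- tapply(load, labels, stats::median)
  list(test = "Kruskal-Wallis", statistic = unname(ht$statistic),
       df = unname(ht$parameter), p_value = unname(ht$p.value),
       group_medians = meds[groups], group_n = c(n_by)[groups])
}

#' Correlation between autoantibody load and age
#'
#' Spearman rank correlation by default (consistent with the pipeline's
#' otherwise nonparametric toolkit); Pearson available.
#'
#' @param load,age paired numeric vectors (>= 3 observations after
#'   applying `mask`).
#' @param mask optional logical vector restricting to a subgroup.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `r` and `p_value` (two-sided).
#' @export
load_age_correlation <- function(load, age, mask = NULL,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!is.null(mask)) {
    load <- load[mask]
    age <- age[mask]
  }
  if (length(load) < 3) stop("need at least 3 paired observations")
  if (stats::sd(load) == 0 || stats::sd(age) == 0) {
    stop("correlation undefined: constant vector")
  }
  ht <- suppressWarnings(stats::cor.test(load, age, method = method,
                                         alternative = "two.sided"))
  list(r = unname(ht$estimate), p_value = unname(ht$p.value))
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Point-probability two-sided rule: the p-value is the sum of the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (with the conventional
#' relative tolerance of 1e-7 for ties in probability). Computed by direct
#' enumeration of the hypergeometric support.
#'
#' @param a,b case-positive and case-negative counts.
#' @param c,d control-positive and control-negative counts.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b   # cases
  n <- c + d   # controls
  k <- a + c   # total positives
  if (m == 0 || n == 0) stop("empty group margin")
  if (k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Case-control prevalence test for one target
#'
#' Builds the 2x2 contingency table of reactivity calls against group
#' labels (optionally within a subgroup mask; samples with a missing mask
#' value are dropped from this test only) and applies the two-sided Fisher
#' exact test.
#'
#' @param calls_column 0/1 vector of calls for one target.
#' @param labels vector of `"case"` / `"control"` labels aligned with
#'   `calls_column`.
#' @param mask optional logical vector; `NA` entries are dropped.
#' @param target_id identifier carried into the result.
#' @return list of class `serocall_prevalence` with the 2x2 counts
#'   (`a`, `b`, `c`, `d`), `prevalence_case`, `prevalence_control`,
#'   `pct_case`, `pct_control` (whole percents, half-up) and `p_value`.
#' @export
prevalence_test <- function(calls_column, labels, mask = NULL,
                            target_id = NA_character_) {
  labels <- as.character(labels)
  keep <- rep(TRUE, length(calls_column))
  if (!is.null(mask)) keep <- !is.na(mask) & mask
  calls_column <- calls_column[keep]
  labels <- labels[keep]
  case <- labels == "case"
  a <- sum(calls_column[case] == 1)
  b <- sum(calls_column[case] == 0)
  c_ <- sum(calls_column[!case] == 1)
  d <- sum(calls_column[!case] == 0)
  if (a + b == 0 || c_ + d == 0) stop("empty group margin after masking")
  out <- list(target_id = target_id, a = a, b = b, c = c_, d = d,
              prevalence_case = a / (a + b),
              prevalence_control = c_ / (c_ + d),
              pct_case = percent_half_up(a, a + b),
              pct_control = percent_half_up(c_, c_ + d),
              p_value = fisher_exact_2x2(a, b, c_, d))
  class(out) <- "serocall_prevalence"
  out
}

#' Prevalence tests across all targets of a call matrix
#'
#' @param calls binary sample-by-target matrix.
#' @param labels `"case"` / `"control"` labels aligned with rows.
#' @param mask optional subgroup mask as in [prevalence_test()].
#' @return data.frame with one row per target: counts, prevalences,
#'   percentages and the Fisher p-value.
#' @export
prevalence_scan <- function(calls, labels, mask = NULL) {
  rows <- lapply(colnames(calls), function(id) {
    r <- prevalence_test(calls[, id], labels, mask = mask, target_id = id)
    data.frame(target_id = id, a = r$a, b = r$b, c = r$c, d = r$d,
               prevalence_case = r$prevalence_case,
               prevalence_control = r$prevalence_control,
               pct_case = r$pct_case, pct_control = r$pct_control,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the autoantibody selection rule to prevalence results
#'
#' A target is selected when its case prevalence is significantly higher
#' than the control prevalence (two-sided Fisher p below `alpha` with a
#' strict case excess), or when it shows any strict case excess while
#' binding a fibrosis-related protein. Raw p-values are used by default
#' (Benjamini-Hochberg adjustment available).
#'
#' @param results data.frame from [prevalence_scan()] (needs columns
#'   `target_id`, `prevalence_case`, `prevalence_control`, `p_value`).
#' @param panel antigen panel; `fibrosis_related` is looked up by
#'   `target_id` against `antigen_id` first, then `protein_id` (for
#'   protein-level results).
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with columns `target_id`, `p_value`, `significant`,
#'   `fibrosis_rescued`, `selected`.
#' @export
select_candidates <- function(results, panel, alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  panel <- validate_panel(panel)
  p <- results$p_value
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  fib_by_antigen <- panel$fibrosis_related[match(results$target_id,
                                                 panel$antigen_id)]
  prot_fib <- tapply(panel$fibrosis_related, panel$protein_id, any)
  fib_by_protein <- prot_fib[results$target_id]
  fibrosis <- ifelse(!is.na(fib_by_antigen), fib_by_antigen,
                     ifelse(!is.na(fib_by_protein), fib_by_protein, FALSE))
  higher <- results$prevalence_case > results$prevalence_control
  significant <- p < alpha & higher
  rescued <- !significant & higher & fibrosis
  data.frame(target_id = results$target_id, p_value = p,
             significant = significant, fibrosis_rescued = rescued,
             selected = significant | rescued, stringsAsFactors = FALSE)
}

#' Clinical-panel augmentation arithmetic
#'
#' Measures how adding an array-derived marker to the routine clinical
#' antibody panel changes cohort positivity: the baseline is the percent of
#' cases positive on the clinical panel; the augmented value is the percent
#' positive on the clinical panel OR the marker. Percentages are whole
#' numbers, rounded half-up. Augmented is always >= baseline.
#'
#' @param clinical_positive logical vector (cases only): clinical-panel
#'   positivity.
#' @param marker_positive logical vector (same cases): marker call.
#' @return list with `n`, `baseline_n`, `augmented_n`, `baseline_pct`,
#'   `augmented_pct` and `rescued_n` (marker-positives among
#'   clinical-negatives).
#' @export
panel_augmentation <- function(clinical_positive, marker_positive) {
  stopifnot(length(clinical_positive) == length(marker_positive),
            !anyNA(clinical_positive), !anyNA(marker_positive))
  n <- length(clinical_positive)
  baseline_n <- sum(clinical_positive)
  augmented_n <- sum(clinical_positive | marker_positive)
  list(n = n, baseline_n = baseline_n, augmented_n = augmented_n,
       baseline_pct = percent_half_up(baseline_n, n),
       augmented_pct = percent_half_up(augmented_n, n),
       rescued_n = sum(!clinical_positive & marker_positive))
}
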