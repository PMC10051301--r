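test_that("autoantibody load is the binary row sum", {
  m <- rbind(S1 = c(1L, 0L, 1L, 1L), S2 = c(0L, 0L, 0L, 0L))
  colnames(m) <- paste0("A", 1:4)
  expect_equal(autoantibody_load(m), c(S1 = 3L, S2 = 0L))
})

test_that("two-group load comparison matches the enumeration oracle", {
  # frozen spec example: all 20 assignments of {1..6} into 3+3 -> p = 0.1
  r <- compare_load(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$p_value, 0.1)
  expect_equal(unname(r$group_medians), c(2, 5))

  # identical groups -> p = 1
  expect_equal(compare_load(c(1, 2, 3, 1, 2, 3),
                            rep(c("a", "b"), each = 3))$p_value, 1)
  expect_error(compare_load(1:3, rep("a", 3)), "two groups")

  # randomized tie-free fixtures, group sizes up to 8
  set.seed(61)
  for (i in 1:12) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    vals <- sample(1:60, n1 + n2)  # distinct -> tie-free, exact branch
    labels <- rep(c("g1", "g2"), c(n1, n2))
    r <- compare_load(vals, labels)
    expect_equal(r$p_value,
                 wilcox_enum_oracle(vals[labels == "g1"], vals[labels == "g2"]),
                 tolerance = 1e-12)
  }
})

test_that("multi-group comparison matches the rank-formula hand oracle", {
  # groups (1,2), (3,4), (5,6): ranks 1..6, mean rank 3.5
  # H = 12/(6*7) * [2(1.5-3.5)^2 + 2(3.5-3.5)^2 + 2(5.5-3.5)^2] = 32/7
  r <- compare_load_multi(1:6, rep(c("a", "b", "c"), each = 2))
  expect_equal(r$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, pchisq(32 / 7, 2, lower.tail = FALSE),
               tolerance = 1e-12)

  ident <- compare_load_multi(rep(c(5, 7), 6), rep(c("a", "b", "c"), each = 4))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_error(compare_load_multi(1:4, rep(c("a", "b"), 2)), "three groups")
})

test_that("load-age correlation behaves at the monotone extremes", {
  expect_equal(load_age_correlation(1:10, (1:10)^2)$r, 1)
  expect_equal(load_age_correlation(1:10, -(1:10)^3)$r, -1)
  expect_error(load_age_correlation(rep(2, 5), 1:5), "constant")
  r <- load_age_correlation(c(3, 1, 4, 1, 5, 9, 2, 6), c(2, 7, 1, 8, 2, 8, 1, 8),
                            method = "pearson")
  expect_equal(r$r, cor(c(3, 1, 4, 1, 5, 9, 2, 6), c(2, 7, 1, 8, 2, 8, 1, 8)))
})

test_that("load is uncorrelated with age under the null generator", {
  set.seed(63)
  rs <- replicate(300, {
    load <- rbinom(50, 20, 0.2)
    age <- sample(25:85, 50, replace = TRUE)
    load_age_correlation(load, age)$r
  })
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)))
})

test_that("Fisher p matches hand-enumerated extreme and symmetric tables", {
  # margins (3,3|3,3): the two extreme tables each have probability 1/20
  expect_equal(fisher_exact_2x2(3, 0, 0, 3), 0.1, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1)
  expect_error(fisher_exact_2x2(0, 0, 1, 1), "empty group margin")
})

test_that("Fisher p equals the brute-force oracle on random tables", {
  set.seed(65)
  for (i in 1:200) {
    tab <- rmultinom(1, sample(4:40, 1), prob = runif(4, 0.05, 1))
    a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
    if (a + b == 0 || c + d == 0) next
    expect_equal(fisher_exact_2x2(a, b, c, d), fisher_oracle(a, b, c, d),
                 tolerance = 1e-12)
    # independent cross-check against the standard implementation
    expect_equal(fisher_exact_2x2(a, b, c, d),
                 fisher.test(matrix(c(a, c, b, d), 2))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("prevalence test builds the 2x2 table and drops missing-mask samples", {
  calls <- c(1, 1, 0, 1, 0, 0, 1, 0)
  labels <- rep(c("case", "control"), each = 4)
  r <- prevalence_test(calls, labels, target_id = "AG1")
  expect_equal(c(r$a, r$b, r$c, r$d), c(3, 1, 1, 3))
  expect_equal(r$prevalence_case, 0.75)
  expect_equal(r$p_value, fisher_oracle(3, 1, 1, 3), tolerance = 1e-12)

  mask <- c(TRUE, TRUE, NA, TRUE, TRUE, TRUE, NA, TRUE)
  r2 <- prevalence_test(calls, labels, mask = mask)
  expect_equal(r2$a + r2$b, 3)  # the NA-mask case is excluded
  expect_equal(r2$c + r2$d, 3)
  expect_error(prevalence_test(calls, labels, mask = labels == "case"),
               "empty group margin")
})

test_that("the selection rule combines significance and fibrosis rescue", {
  results <- data.frame(
    target_id = c("sig", "rescued", "neither", "control_enriched"),
    prevalence_case = c(0.3, 0.2, 0.2, 0.1),
    prevalence_control = c(0.05, 0.1, 0.1, 0.3),
    p_value = c(0.016, 0.2, 0.2, 0.2))
  panel <- tiny_panel(results$target_id,
                      fibrosis = c(FALSE, TRUE, FALSE, TRUE))
  sel <- select_candidates(results, panel)
  expect_equal(sel$selected, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sel$fibrosis_rescued, c(FALSE, TRUE, FALSE, FALSE))
  # BH adjustment is available and labeled
  sel_bh <- select_candidates(results, panel, adjust = "BH")
  expect_equal(sel_bh$p_value, p.adjust(results$p_value, "BH"))
})

test_that("fibrosis flags resolve through the protein map for protein-level results", {
  results <- data.frame(target_id = "PROT9", prevalence_case = 0.2,
                        prevalence_control = 0.1, p_value = 0.4)
  panel <- tiny_panel(c("A1", "A2"), proteins = c("PROT9", "PROT9"),
                      fibrosis = c(FALSE, TRUE))
  expect_true(select_candidates(results, panel)$selected)
})

test_that("panel augmentation reproduces the rescue arithmetic and is monotone", {
  clinical <- rep(c(TRUE, FALSE), c(41, 14))
  marker <- rep(c(FALSE, TRUE, FALSE), c(41, 7, 7))
  r <- panel_augmentation(clinical, marker)
  expect_equal(r$baseline_pct, 75)   # 41/55
  expect_equal(r$augmented_pct, 87)  # 48/55
  expect_equal(r$rescued_n, 7)

  # marker positives only among clinical positives -> no change
  r2 <- panel_augmentation(clinical, clinical & rep(c(TRUE, FALSE), length.out = 55))
  expect_equal(r2$augmented_pct, r2$baseline_pct)
  # everyone marker-positive -> 100%
  expect_equal(panel_augmentation(clinical, rep(TRUE, 55))$augmented_pct, 100)
  # monotone on random fixtures
  set.seed(67)
  for (i in 1:20) {
    cl <- runif(30) < 0.5; mk <- runif(30) < 0.5
    r3 <- panel_augmentation(cl, mk)
    expect_gte(r3$augmented_pct, r3$baseline_pct)
  }
})

test_that("percent rounding is half-up", {
  expect_equal(percent_half_up(3, 8), 38)
  expect_equal(percent_half_up(4, 9), 44)
  expect_equal(percent_half_up(41, 55), 75)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(0.125, 2), 0.13)
})
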