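test_that("count classifier handles perfect and uninformative separation", {
  calls <- calls_with_loads(c(3, 2, 0, 1), n_targets = 3)
  labels <- c("case", "case", "control", "control")
  roc <- count_classifier_roc(calls, labels, k_max = 3)
  k2 <- roc$table[roc$table$k == 2, ]
  expect_equal(k2$pct_cases_positive, 100)
  expect_equal(k2$pct_controls_negative, 100)
  expect_equal(roc$auc, 1.0)

  same <- count_classifier_roc(calls_with_loads(c(2, 0, 2, 0)), labels)
  expect_equal(same$auc, 0.5)
  expect_error(count_classifier_roc(calls, rep("case", 4)), "non-empty")
  expect_error(count_classifier_roc(calls[, 0], labels), "empty panel")
})

test_that("ROC rates are non-increasing in k and anchored", {
  set.seed(71)
  calls <- calls_with_loads(rbinom(40, 8, 0.4), n_targets = 8)
  labels <- rep(c("case", "control"), 20)
  roc <- count_classifier_roc(calls, labels)
  expect_true(all(diff(roc$table$tpr) <= 0))
  expect_true(all(diff(roc$table$fpr) <= 0))
  expect_equal(roc$table$tpr[1], 1)  # k = 0: everyone positive
  expect_equal(roc$table$fpr[1], 1)
  expect_equal(roc$table$tpr[nrow(roc$table)], 0)  # k beyond max load
})

test_that("count-classifier AUC equals the U-statistic formulation", {
  set.seed(73)
  for (i in 1:25) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    loads <- rbinom(n1 + n2, 11, runif(1, 0.1, 0.6))
    labels <- rep(c("case", "control"), c(n1, n2))
    roc <- count_classifier_roc(calls_with_loads(loads, n_targets = 11), labels)
    expect_equal(roc$auc,
                 auc_u_oracle(loads[labels == "case"], loads[labels == "control"]),
                 tolerance = 1e-12)
  }
})

test_that("permuted labels give mean AUC near 0.5", {
  set.seed(75)
  loads <- rbinom(40, 11, 0.3)
  calls <- calls_with_loads(loads, n_targets = 11)
  aucs <- replicate(500, {
    labels <- sample(rep(c("case", "control"), 20))
    count_classifier_roc(calls, labels)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(length(aucs)))
})

test_that("identical profiles cluster together; least-reactive cluster gets label k", {
  m <- rbind(S1 = c(1, 1, 1, 0), S2 = c(1, 1, 1, 0),
             S3 = c(0, 1, 0, 0), S4 = c(1, 0, 0, 1), S5 = c(0, 0, 0, 0))
  colnames(m) <- paste0("A", 1:4)
  for (k in 2:4) {
    cl <- cluster_samples(m, k = k)
    expect_equal(cl$assignment[["S1"]], cl$assignment[["S2"]])
    # the all-zero profile sits in the last-numbered cluster
    expect_equal(unname(which.min(tapply(rowMeans(m), cl$assignment, mean))),
                 cl$assignment[["S5"]])
    expect_equal(max(cl$assignment), k)
  }
  # several all-zero profiles stay together in the last-numbered cluster
  z <- rbind(m[1:3, ], Z1 = rep(0, 4), Z2 = rep(0, 4))
  clz <- cluster_samples(z, k = 3)
  expect_equal(clz$assignment[["Z1"]], clz$assignment[["Z2"]])
  expect_equal(clz$assignment[["Z1"]], 3L)
  expect_error(cluster_samples(m, k = 6), "fewer samples")
})

test_that("well-separated binary blocks are recovered exactly", {
  block <- function(ids, cols, n_targets = 9) {
    m <- matrix(0L, length(ids), n_targets,
                dimnames = list(ids, paste0("A", 1:n_targets)))
    m[, cols] <- 1L
    m
  }
  m <- rbind(block(paste0("x", 1:5), 1:3), block(paste0("y", 1:5), 4:6),
             block(paste0("z", 1:5), 7:9))
  truth <- rep(1:3, each = 5)
  cl <- cluster_samples(m, k = 3)
  expect_equal(mclust::adjustedRandIndex(cl$assignment, truth), 1)
})

test_that("cluster assignment is invariant to input row order", {
  set.seed(77)
  m <- matrix(rbinom(30 * 8, 1, 0.3), 30, 8,
              dimnames = list(sprintf("S%02d", 1:30), paste0("A", 1:8)))
  cl <- cluster_samples(m, k = 3)
  perm <- sample(30)
  cl_perm <- cluster_samples(m[perm, ], k = 3)
  expect_equal(mclust::adjustedRandIndex(cl$assignment[rownames(m)],
                                         cl_perm$assignment[rownames(m)]), 1)
})

test_that("feature summaries report percent positive among non-missing", {
  assignment <- c(S1 = 1L, S2 = 1L, S3 = 2L, S4 = 2L, S5 = 2L)
  result <- list(assignment = assignment, k = 2)
  class(result) <- "serocall_clusters"
  meta <- data.frame(
    sample_id = names(assignment),
    digital_ulcers = c(TRUE, FALSE, NA, NA, NA),
    pah = c(TRUE, TRUE, FALSE, TRUE, NA),
    stringsAsFactors = FALSE)
  s <- cluster_feature_summary(result, meta,
                               features = c("digital_ulcers", "pah"))
  expect_equal(s$digital_ulcers, c(50, NA))       # all-missing -> NA
  expect_equal(s$pah, c(100, 50))                 # 2/2 and 1/2 non-missing
  expect_equal(s$n, c(2, 3))

  single <- list(assignment = c(S1 = 1L), k = 1)
  class(single) <- "serocall_clusters"
  s1 <- cluster_feature_summary(single, meta[1, ], features = "pah")
  expect_equal(s1$pah, 100)
})

test_that("cross-cluster membership summaries count masked samples", {
  assignment <- c(rep(1L, 5), rep(2L, 4), rep(3L, 4))
  names(assignment) <- sprintf("S%02d", seq_along(assignment))
  result <- list(assignment = assignment, k = 3)
  class(result) <- "serocall_clusters"
  mask <- rep(TRUE, 13)  # 13 patients of interest, 9 in clusters 1 or 2
  r <- cluster_membership(result, mask, clusters = c(1, 2))
  expect_equal(r$n_in, 9)
  expect_equal(r$n_total, 13)
  expect_equal(r$pct, 69)  # 9/13 = 69.23%, half-up
  expect_error(cluster_membership(result, rep(FALSE, 13), 1), "empty subgroup")
})

test_that("heatmap export writes dendrogram-ordered, content-preserving TSV", {
  set.seed(79)
  m <- matrix(rbinom(8 * 5, 1, 0.4), 8, 5,
              dimnames = list(paste0("S", 1:8), paste0("A", 1:5)))
  cl <- cluster_samples(m, k = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  ordered <- export_heatmap(m, cl, f)
  expect_identical(rownames(ordered), cl$order)
  tab <- read.delim(f, check.names = FALSE)
  expect_identical(tab$sample_id, cl$order)
  back <- as.matrix(tab[, paste0("A", 1:5)])
  rownames(back) <- tab$sample_id
  expect_equal(back[rownames(m), ], m, ignore_attr = TRUE)
  # deterministic for fixed input
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_heatmap(m, cluster_samples(m, k = 2), f2)
  expect_identical(readLines(f), readLines(f2))
})
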