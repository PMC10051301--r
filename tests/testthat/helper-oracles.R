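# Independent oracles used across the suite. These stay independent of the
# code paths they check: the Fisher oracle enumerates table probabilities
# from log-binomial coefficients, the Wilcoxon oracle enumerates all label
# assignments, and the AUC oracle is the U-statistic formulation.

# Two-sided Fisher p by brute-force enumeration over the hypergeometric
# support, probabilities from lchoose (point-probability two-sided rule).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (k == 0 || k == m + n) return(1)
  supp <- max(0, k - n):min(k, m)
  p <- exp(lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k))
  p_obs <- exp(lchoose(m, a) + lchoose(n, c) - lchoose(m + n, k))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# label assignments (tie-free data only).
wilcox_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(length(pooled), n1), 2, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# AUC as probability of correct ordering with half-credit ties
# (Mann-Whitney U / (n1 * n2)).
auc_u_oracle <- function(score_case, score_control) {
  cmp <- outer(score_case, score_control, ">") +
    0.5 * outer(score_case, score_control, "==")
  mean(cmp)
}

# Small fixture: binary call matrix with the given per-sample loads.
calls_with_loads <- function(loads, n_targets = max(loads, 1)) {
  m <- t(vapply(loads, function(l) {
    as.integer(seq_len(n_targets) <= l)
  }, integer(n_targets)))
  rownames(m) <- sprintf("S%02d", seq_along(loads))
  colnames(m) <- sprintf("T%02d", seq_len(n_targets))
  m
}

# Case metadata + call matrix wiring for subgroup arithmetic fixtures.
tiny_panel <- function(ids, proteins = ids, fibrosis = FALSE) {
  data.frame(antigen_id = ids, protein_id = proteins,
             source = "literature",
             fibrosis_related = rep_len(fibrosis, length(ids)),
             stringsAsFactors = FALSE)
}
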