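#' Simulation configuration for the bead-array cohort generator
#'
#' Bundles and validates all generator parameters. Defaults emulate the
#' targeted bead-array study conditions: 55 cases and 52 controls over 246
#' antigens, of which 132 carry genuine sparse reactivity; log-normal MFI
#' background with a per-sample multiplicative background shift; and an
#' additive positivity boost for cases with lung fibrosis or active skin
#' fibrosis (mRSS > 15) so that the autoantibody load is ordered
#' both-features > one feature > neither.
#'
#' @param n_cases,n_controls,n_antigens cohort dimensions.
#' @param n_reactive_antigens number of antigens with true reactivity
#'   (must not exceed `n_antigens`).
#' @param background_location,background_scale meanlog/sdlog of the
#'   log-normal MFI background.
#' @param sample_shift_scale sdlog of the per-sample multiplicative
#'   background shift (0 disables shifts).
#' @param reactive_effect log-space signal elevation for a truly reactive
#'   sample-antigen pair (default 3, about a 20-fold MFI increase).
#' @param prevalence_case,prevalence_control per-reactive-antigen positivity
#'   probability in cases / controls.
#' @param load_boost_fibrosis additional positivity probability added once
#'   for lung fibrosis and once for mRSS > 15 in cases.
#' @param seed integer seed; all draws flow from one generator stream.
#' @return a validated list of class `serocall_sim_config`.
#' @export
simulation_config <- function(n_cases = 55, n_controls = 52,
                              n_antigens = 246, n_reactive_antigens = 132,
                              background_location = 6, background_scale = 0.25,
                              sample_shift_scale = 0.3, reactive_effect = 3,
                              prevalence_case = 0.10, prevalence_control = 0.04,
                              load_boost_fibrosis = 0.05, seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_antigens = as.integer(n_antigens),
              n_reactive_antigens = as.integer(n_reactive_antigens),
              background_location = background_location,
              background_scale = background_scale,
              sample_shift_scale = sample_shift_scale,
              reactive_effect = reactive_effect,
              prevalence_case = prevalence_case,
              prevalence_control = prevalence_control,
              load_boost_fibrosis = load_boost_fibrosis,
              seed = as.integer(seed))
  with(cfg, {
    if (n_cases < 1 || n_controls < 1 || n_antigens < 1) {
      stop("cohort dimensions must be positive")
    }
    if (n_reactive_antigens < 0 || n_reactive_antigens > n_antigens) {
      stop("n_reactive_antigens must lie in [0, n_antigens]")
    }
    if (background_scale <= 0) stop("background_scale must be positive")
    if (sample_shift_scale < 0) stop("sample_shift_scale must be non-negative")
    probs <- c(prevalence_case, prevalence_control, load_boost_fibrosis)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  })
  class(cfg) <- "serocall_sim_config"
  cfg
}

## Table-1-style clinical marginals (fractions of the 55-case study group);
## scaled by round() for other cohort sizes.
.case_marginals <- list(
  female = 46 / 55,
  subtype = c(limited = 42, diffuse = 11, no_sclerosis = 2) / 55,
  lf_and_high_mrss = 8 / 55,  # both lung fibrosis and mRSS > 15
  lf_only = 6 / 55,           # lung fibrosis, mRSS <= 15
  high_mrss_only = 5 / 55,    # mRSS > 15, no lung fibrosis
  flags = c(calcinosis = 16, digital_ulcers = 12, dysphagia = 29,
            pah = 20, raynaud = 47, reflux = 30, sicca = 16) / 55,
  clinical_panel_positive = 41 / 55,
  antibodies = c(scl70 = 18, centromere = 19, ssa = 4, rnp_sm = 3) / 55
)

.sim_case_metadata <- function(n) {
  sex <- rep("M", n)
  sex[seq_len(round(.case_marginals$female * n))] <- "F"
  sex <- sample(sex)
  age <- pmin(85L, pmax(25L, as.integer(round(stats::rnorm(n, 61, 13)))))
  n_sub <- round(.case_marginals$subtype * n)
  n_sub[1] <- n - sum(n_sub[-1])
  subtype <- sample(rep(names(.case_marginals$subtype), times = n_sub))

  ## joint lung-fibrosis / high-mRSS structure
  n_both <- round(.case_marginals$lf_and_high_mrss * n)
  n_lf_only <- round(.case_marginals$lf_only * n)
  n_mrss_only <- round(.case_marginals$high_mrss_only * n)
  grp <- sample(rep(c("both", "lf", "mrss", "none"),
                    times = c(n_both, n_lf_only, n_mrss_only,
                              n - n_both - n_lf_only - n_mrss_only)))
  lung_fibrosis <- grp %in% c("both", "lf")
  high_mrss <- grp %in% c("both", "mrss")
  mrss <- integer(n)
  mrss[high_mrss] <- sample(16:46, sum(high_mrss), replace = TRUE)
  mrss[!high_mrss] <- sample(0:15, sum(!high_mrss), replace = TRUE,
                             prob = stats::dpois(0:15, 8))

  flags <- lapply(.case_marginals$flags, function(p) {
    k <- round(p * n)
    sample(rep(c(TRUE, FALSE), times = c(k, n - k)))
  })

  ## clinical antibody statuses nested inside the clinical-panel-positive set
  n_pos <- round(.case_marginals$clinical_panel_positive * n)
  panel_positive <- sample(rep(c(TRUE, FALSE), times = c(n_pos, n - n_pos)))
  pos_idx <- which(panel_positive)
  anti <- lapply(.case_marginals$antibodies, function(p) {
    k <- min(round(p * n), length(pos_idx))
    out <- rep(FALSE, n)
    out[sample(pos_idx, k)] <- TRUE
    out
  })

  data.frame(group = "case", subtype = subtype, age = age, sex = sex,
             mrss = mrss,
             calcinosis = flags$calcinosis, digital_ulcers = flags$digital_ulcers,
             dysphagia = flags$dysphagia, lung_fibrosis = lung_fibrosis,
             pah = flags$pah, raynaud = flags$raynaud, reflux = flags$reflux,
             sicca = flags$sicca,
             scl70 = anti$scl70, centromere = anti$centromere,
             ssa = anti$ssa, rnp_sm = anti$rnp_sm,
             clinical_panel_positive = panel_positive,
             stringsAsFactors = FALSE)
}

.sim_control_metadata <- function(n) {
  sex <- rep("M", n)
  sex[seq_len(round(39 / 52 * n))] <- "F"
  sex <- sample(sex)
  age <- pmin(79L, pmax(21L, as.integer(round(stats::rnorm(n, 53, 13)))))
  df <- data.frame(group = "control", subtype = "not_applicable",
                   age = age, sex = sex, mrss = NA_integer_,
                   stringsAsFactors = FALSE)
  for (col in c(.flag_fields, .antibody_fields)) df[[col]] <- NA
  df$clinical_panel_positive <- NA
  df
}

.sim_panel <- function(antigen_ids, reactive_ids) {
  n <- length(antigen_ids)
  ## several antigens (protein fragments) may represent one protein:
  ## roughly 4 antigens per 5 proteins, as in a fragment-based panel
  n_proteins <- max(1L, ceiling(0.8 * n))
  protein_pool <- sprintf("PROT%04d", seq_len(n_proteins))
  assignment <- c(protein_pool,
                  sample(protein_pool, n - n_proteins, replace = TRUE))
  assignment <- sample(assignment)
  source <- rep("literature", n)
  source[sample.int(n, round(0.3 * n))] <- "planar_selected"
  fibrosis <- stats::runif(n) < 0.2
  data.frame(antigen_id = antigen_ids, protein_id = assignment,
             source = source, fibrosis_related = fibrosis,
             stringsAsFactors = FALSE)
}

#' Simulate a bead-array case-control cohort with known ground truth
#'
#' Generates raw MFI as
#' `exp(Normal(background_location, background_scale)) * sample_shift *
#' (reactive ? exp(reactive_effect) : 1)`, where `sample_shift` is a
#' per-sample log-normal multiplicative background level, together with
#' clinical metadata whose marginal frequencies follow the study group
#' (84% female cases, median case age near 61, 14/55 lung fibrosis,
#' 13/55 mRSS > 15, 8/55 with both), an antigen panel, and the truth labels
#' of every reactive sample-antigen pair. Fully deterministic given the
#' config seed.
#'
#' @param config a [simulation_config()].
#' @return a list of class `serocall_cohort` with elements `intensity`
#'   (matrix), `metadata` (data.frame), `panel` (data.frame) and `truth`
#'   (list with `reactive_pairs` logical matrix, `reactive_antigens`,
#'   `case_enriched_antigens`).
#' @export
simulate_bead_cohort <- function(config = simulation_config()) {
  if (!inherits(config, "serocall_sim_config")) {
    config <- do.call(simulation_config, as.list(config))
  }
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  m <- config$n_antigens
  sample_ids <- c(sprintf("SSC%03d", seq_len(config$n_cases)),
                  sprintf("CTRL%03d", seq_len(config$n_controls)))
  antigen_ids <- sprintf("AG%04d", seq_len(m))

  meta <- rbind(.sim_case_metadata(config$n_cases),
                .sim_control_metadata(config$n_controls))
  meta <- cbind(sample_id = sample_ids, meta, stringsAsFactors = FALSE)
  meta <- validate_metadata(meta)

  reactive_ids <- sort(sample(antigen_ids, config$n_reactive_antigens))
  panel <- .sim_panel(antigen_ids, reactive_ids)

  ## per-sample per-antigen positivity probabilities for truth labels
  prob <- matrix(0, n, m, dimnames = list(sample_ids, antigen_ids))
  is_case <- meta$group == "case"
  boost <- numeric(n)
  boost[is_case] <- config$load_boost_fibrosis *
    ((!is.na(meta$lung_fibrosis[is_case]) & meta$lung_fibrosis[is_case]) +
     (!is.na(meta$mrss[is_case]) & meta$mrss[is_case] > 15))
  base <- ifelse(is_case, config$prevalence_case, config$prevalence_control)
  reactive_cols <- antigen_ids %in% reactive_ids
  prob[, reactive_cols] <- pmin(1, base + boost)

  truth_calls <- matrix(stats::runif(n * m) < prob, n, m,
                        dimnames = list(sample_ids, antigen_ids))

  background <- matrix(exp(stats::rnorm(n * m, config$background_location,
                                        config$background_scale)),
                       n, m, dimnames = list(sample_ids, antigen_ids))
  shift <- exp(stats::rnorm(n, 0, config$sample_shift_scale))
  intensity <- background * shift
  intensity[truth_calls] <- intensity[truth_calls] * exp(config$reactive_effect)

  enriched <- if (config$prevalence_case > config$prevalence_control) {
    reactive_ids
  } else {
    character(0)
  }
  out <- list(intensity = intensity, metadata = meta, panel = panel,
              truth = list(reactive_pairs = truth_calls,
                           reactive_antigens = reactive_ids,
                           case_enriched_antigens = enriched),
              config = config)
  class(out) <- "serocall_cohort"
  out
}

#' @export
print.serocall_cohort <- function(x, ...) {
  cat(sprintf("simulated bead cohort: %d cases / %d controls x %d antigens (%d reactive), seed %d\n",
              x$config$n_cases, x$config$n_controls, x$config$n_antigens,
              x$config$n_reactive_antigens, x$config$seed))
  invisible(x)
}

#' Simulate the two planar-array screening pools
#'
#' Emulates the untargeted phase: two pooled-plasma intensity vectors (a
#' dcSSc-like and an lcSSc-like pool) over a shared log-normal background,
#' with `n_elevated` antigens in the first pool raised by
#' `elevation_sd_units` background standard deviations.
#'
#' @param n_antigens number of antigens on the array.
#' @param n_elevated number of truly elevated antigens in the dcSSc-like
#'   pool (must not exceed `n_antigens`).
#' @param elevation_sd_units elevation in units of the background standard
#'   deviation (raw-intensity scale).
#' @param seed integer seed.
#' @param background_location,background_scale meanlog/sdlog of the
#'   log-normal background.
#' @return list with `dc_pool`, `lc_pool` (named numeric vectors) and
#'   `truth` (character vector of elevated antigen ids).
#' @export
simulate_planar_pools <- function(n_antigens, n_elevated,
                                  elevation_sd_units = 8, seed = 1L,
                                  background_location = 6,
                                  background_scale = 0.25) {
  if (n_elevated < 0 || n_elevated > n_antigens) {
    stop("n_elevated must lie in [0, n_antigens]")
  }
  set.seed(as.integer(seed))
  ids <- sprintf("PA%05d", seq_len(n_antigens))
  dc <- exp(stats::rnorm(n_antigens, background_location, background_scale))
  lc <- exp(stats::rnorm(n_antigens, background_location, background_scale))
  names(dc) <- names(lc) <- ids
  truth <- character(0)
  if (n_elevated > 0) {
    truth <- sort(sample(ids, n_elevated))
    dc[truth] <- dc[truth] + elevation_sd_units * stats::sd(dc)
  }
  list(dc_pool = dc, lc_pool = lc, truth = truth)
}
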