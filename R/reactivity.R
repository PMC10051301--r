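#' Cutoff rule for binary reactivity calling
#'
#' The default `antigen_mad` strategy sets, for each antigen, the cutoff
#' `max(floor, median + c * MAD)` over that antigen's normalized values
#' across all samples (raw, unscaled MAD); a sample is called reactive when
#' its value strictly exceeds the cutoff. The `fixed` strategy applies one
#' constant threshold (`floor`) to every antigen. Both `c` and `floor` are
#' tunable; increasing either never increases the number of positive calls.
#'
#' @param strategy `"antigen_mad"` (default) or `"fixed"`.
#' @param c MAD multiplier (default 5).
#' @param floor minimum normalized-signal cutoff (default 5 nMAD).
#' @return a list of class `serocall_cutoff_rule`.
#' @export
cutoff_rule <- function(strategy = c("antigen_mad", "fixed"), c = 5, floor = 5) {
  strategy <- match.arg(strategy)
  if (!is.finite(c) || !is.finite(floor)) stop("c and floor must be finite")
  out <- list(strategy = strategy, c = c, floor = floor)
  class(out) <- "serocall_cutoff_rule"
  out
}

#' Call binary reactivity from a normalized bead-array matrix
#'
#' Thresholds each antigen's normalized signals into 0/1 reactivity calls.
#' An antigen column whose across-sample MAD is zero falls back to the
#' floor-only cutoff (logged via a message). Ties with the cutoff are
#' negative (strict inequality).
#'
#' @param normalized matrix in nMAD mode (see [nmad_transform()]).
#' @param rule a [cutoff_rule()].
#' @param allow_unnormalized set `TRUE` to threshold a plain matrix (e.g.
#'   raw intensities) with the same rule; default requires nMAD mode.
#' @return integer 0/1 matrix with the same dimnames, carrying attributes
#'   `cutoffs` (per-antigen realized cutoffs) and `rule` (provenance).
#' @export
call_reactivity <- function(normalized, rule = cutoff_rule(),
                            allow_unnormalized = FALSE) {
  stopifnot(is.matrix(normalized))
  if (!inherits(rule, "serocall_cutoff_rule")) stop("rule must be a cutoff_rule()")
  if (!allow_unnormalized && !is_nmad(normalized)) {
    stop("input is not in nMAD mode; run nmad_transform() first ",
         "(or set allow_unnormalized = TRUE)")
  }
  if (rule$strategy == "fixed") {
    cutoffs <- rep(rule$floor, ncol(normalized))
  } else {
    med <- apply(normalized, 2, stats::median)
    madv <- apply(normalized, 2, mad_raw)
    degenerate <- madv <= 0
    cutoffs <- pmax(rule$floor, med + rule$c * madv)
    cutoffs[degenerate] <- rule$floor
    if (any(degenerate)) {
      message(sum(degenerate), " antigen(s) with zero MAD fell back to the ",
              "floor-only cutoff: ",
              paste(utils::head(colnames(normalized)[degenerate], 5),
                    collapse = ", "))
    }
  }
  names(cutoffs) <- colnames(normalized)
  calls <- matrix(as.integer(sweep(normalized, 2, cutoffs, ">")),
                  nrow = nrow(normalized), dimnames = dimnames(normalized))
  attr(calls, "cutoffs") <- cutoffs
  attr(calls, "rule") <- rule
  calls
}

#' Aggregate antigen-level calls to protein-level autoantibody calls
#'
#' Several antigens (protein fragments) may represent one protein; a
#' protein-level autoantibody call is positive when any of its fragments
#' is positive (logical OR).
#'
#' @param calls binary sample-by-antigen matrix.
#' @param panel antigen panel mapping every antigen id to a protein id.
#' @return binary sample-by-protein matrix (columns ordered by first
#'   appearance of each protein in the panel).
#' @export
protein_level_calls <- function(calls, panel) {
  panel <- validate_panel(panel)
  unmapped <- setdiff(colnames(calls), panel$antigen_id)
  if (length(unmapped) > 0) {
    stop("antigen(s) without protein mapping: ",
         paste(unmapped, collapse = ", "))
  }
  prot <- panel$protein_id[match(colnames(calls), panel$antigen_id)]
  proteins <- unique(prot)
  out <- vapply(proteins, function(p) {
    as.integer(rowSums(calls[, prot == p, drop = FALSE]) > 0)
  }, integer(nrow(calls)))
  dimnames(out) <- list(rownames(calls), proteins)
  out
}

#' Summarize a binary reactivity matrix
#'
#' @param calls binary sample-by-target matrix.
#' @return list with `n_targets`, `n_reactive_targets` (>= 1 positive
#'   sample), `pct_reactive` (whole percent, half-up), `target_positive_counts`,
#'   `sample_loads` and `load_range` over samples with at least one call.
#' @export
reactivity_summary <- function(calls) {
  counts <- colSums(calls)
  loads <- rowSums(calls)
  nonzero <- loads[loads > 0]
  list(n_targets = ncol(calls),
       n_reactive_targets = sum(counts > 0),
       pct_reactive = percent_half_up(sum(counts > 0), ncol(calls)),
       target_positive_counts = counts,
       sample_loads = loads,
       load_range = if (length(nonzero) > 0) range(nonzero) else c(0L, 0L))
}
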