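#' Array-wise robust standardization (nSD) of a planar-array vector
#'
#' Expresses each antigen's raw intensity as the number of standard
#' deviations from the array mean: `(x - mean(x)) / sd(x)`. The standard
#' deviation uses the population convention (divide by n) by default; at
#' planar-array scale (tens of thousands of antigens) the choice is
#' numerically immaterial, but it is fixed and configurable for
#' reproducibility.
#'
#' @param raw numeric vector of raw intensities over one array
#'   (length >= 2).
#' @param sd_type `"population"` (divide by n, default) or `"sample"`
#'   (divide by n - 1).
#' @return numeric vector of nSD values, preserving names.
#' @export
nsd_transform <- function(raw, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(raw) < 2) stop("nSD needs at least 2 values")
  if (anyNA(raw)) stop("nSD input must not contain missing values")
  mu <- mean(raw)
  s <- stats::sd(raw)
  if (sd_type == "population") s <- s * sqrt((length(raw) - 1) / length(raw))
  if (!is.finite(s) || s <= 0) {
    stop("degenerate input: standard deviation is zero")
  }
  (raw - mu) / s
}

#' Sample-wise median/MAD normalization (nMAD) of a bead-array matrix
#'
#' Corrects for sample-specific background levels: each sample row is
#' centered on its median and scaled by its raw median absolute deviation
#' (no 1.4826 consistency factor), giving the number of MADs from the
#' sample median: `(x - median(x)) / MAD(x)` per row. After the transform
#' every row has median 0 and MAD 1, and the result is invariant to any
#' per-sample affine background `a*x + b` (a > 0).
#'
#' @param raw sample-by-antigen intensity matrix.
#' @param exclude optional character vector of antigen ids (e.g. control
#'   beads) excluded from each row's median/MAD computation; excluded
#'   columns are still transformed.
#' @return the normalized matrix with attributes `mode = "nMAD"`, `center`
#'   and `scale` (per-sample statistics used).
#' @export
nmad_transform <- function(raw, exclude = NULL) {
  stopifnot(is.matrix(raw))
  if (anyNA(raw)) stop("nMAD input must not contain missing values")
  use <- rep(TRUE, ncol(raw))
  if (!is.null(exclude)) {
    use <- !(colnames(raw) %in% exclude)
    if (!any(use)) stop("all antigens excluded from normalization")
  }
  center <- apply(raw[, use, drop = FALSE], 1, stats::median)
  scale <- apply(raw[, use, drop = FALSE], 1, mad_raw)
  zero <- which(scale <= 0)
  if (length(zero) > 0) {
    stop("MAD is zero for sample(s): ",
         paste(rownames(raw)[zero], collapse = ", "))
  }
  out <- (raw - center) / scale
  attr(out, "mode") <- "nMAD"
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Is a matrix in nMAD mode?
#' @param x a matrix.
#' @return logical.
#' @keywords internal
is_nmad <- function(x) identical(attr(x, "mode"), "nMAD")
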