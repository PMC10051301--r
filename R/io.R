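#' Read a sample-by-antigen intensity matrix
#'
#' Reads a raw median-fluorescence-intensity (MFI) matrix with samples in
#' rows and antigens in columns. The first row must hold antigen ids, the
#' first column sample ids; the body must be numeric, non-missing and
#' non-negative.
#'
#' @param path path to a TSV or CSV file.
#' @param dialect `"tsv"` or `"csv"`; guessed from the file extension when
#'   omitted.
#' @return a numeric matrix with sample ids as rownames and antigen ids as
#'   colnames.
#' @seealso [write_intensity_matrix()]
#' @export
read_intensity_matrix <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("malformed header: expected sample id column plus at least one antigen column")
  sample_ids <- raw[[1]]
  antigen_ids <- colnames(raw)[-1]
  if (anyDuplicated(antigen_ids)) {
    stop("duplicated antigen id(s): ",
         paste(unique(antigen_ids[duplicated(antigen_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(storage.mode(body) <- "double")
  bad <- which(is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-numeric or missing cell at sample '", sample_ids[bad[1, 1]],
         "', antigen '", antigen_ids[bad[1, 2]], "'")
  }
  neg <- which(body < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative MFI at sample '", sample_ids[neg[1, 1]],
         "', antigen '", antigen_ids[neg[1, 2]], "'")
  }
  dimnames(body) <- list(sample_ids, antigen_ids)
  body
}

#' Write an intensity matrix
#'
#' Writes values with 17 significant digits so that a write/read round trip
#' reproduces the numeric content bit-exactly.
#'
#' @param x numeric matrix with dimnames.
#' @param path output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @export
write_intensity_matrix <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  fmt <- matrix(sprintf("%.17g", x), nrow = nrow(x), dimnames = dimnames(x))
  df <- data.frame(sample_id = rownames(x), fmt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.group_levels    <- c("case", "control")
.subtype_levels  <- c("limited", "diffuse", "no_sclerosis", "not_applicable")
.flag_fields     <- c("calcinosis", "digital_ulcers", "dysphagia",
                      "lung_fibrosis", "pah", "raynaud", "reflux", "sicca")
.antibody_fields <- c("scl70", "centromere", "ssa", "rnp_sm")

.parse_bool <- function(x, column) {
  out <- rep(NA, length(x))
  x <- trimws(tolower(as.character(x)))
  miss <- is.na(x) | x == "" | x == "na"
  out[!miss & x %in% c("1", "true", "yes")] <- TRUE
  out[!miss & x %in% c("0", "false", "no")] <- FALSE
  bad <- !miss & is.na(out)
  if (any(bad)) {
    stop("unrecognised boolean token '", x[which(bad)[1]],
         "' in column '", column, "'")
  }
  out
}

#' Read a sample-metadata table
#'
#' Parses clinical metadata: group (case/control), SSc subtype, age, sex,
#' modified Rodnan skin score (mRSS), clinical manifestation flags and
#' clinical antibody statuses. Missing optional values stay missing (`NA`),
#' never coerced to `FALSE`.
#'
#' @param path TSV/CSV file with columns `sample_id`, `group`, `subtype`,
#'   `age`, `sex`, `mrss`, the flag columns
#'   (calcinosis, digital_ulcers, dysphagia, lung_fibrosis, pah, raynaud,
#'   reflux, sicca) and antibody columns (scl70, centromere, ssa, rnp_sm).
#'   Flag/antibody columns may be absent (treated as all-missing).
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @return a data.frame, one row per sample.
#' @export
read_metadata <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("sample_id", "group", "subtype", "age", "sex")
  missing_cols <- setdiff(required, colnames(raw))
  if (length(missing_cols) > 0) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_metadata(raw)
}

#' Validate (and type) a metadata data.frame
#'
#' @param df data.frame with metadata columns as in [read_metadata()].
#' @return the validated, typed data.frame.
#' @export
validate_metadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad_group <- setdiff(unique(df$group), .group_levels)
  if (length(bad_group) > 0) {
    stop("unknown group token(s): ", paste(bad_group, collapse = ", "))
  }
  bad_sub <- setdiff(unique(stats::na.omit(df$subtype)), .subtype_levels)
  if (length(bad_sub) > 0) {
    stop("unknown subtype token(s): ", paste(bad_sub, collapse = ", "))
  }
  df$age <- as.integer(df$age)
  if (any(is.na(df$age) | df$age <= 0)) stop("age must be a positive integer for every sample")
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (!"mrss" %in% colnames(df)) df$mrss <- NA_integer_
  df$mrss <- suppressWarnings(as.integer(df$mrss))
  if (any(!is.na(df$mrss) & df$mrss < 0)) stop("mrss must be non-negative when present")
  ctrl <- df$group == "control"
  if (any(ctrl & df$subtype != "not_applicable")) {
    stop("controls must have subtype 'not_applicable'")
  }
  if (any(ctrl & !is.na(df$mrss))) stop("controls must have missing mrss")
  for (col in c(.flag_fields, .antibody_fields)) {
    if (!col %in% colnames(df)) {
      df[[col]] <- NA
    } else if (!is.logical(df[[col]])) {
      df[[col]] <- .parse_bool(df[[col]], col)
    }
  }
  rownames(df) <- NULL
  df
}

#' Read an antigen panel table
#'
#' @param path TSV/CSV with columns `antigen_id`, `protein_id`, `source`
#'   (`planar_selected` or `literature`) and `fibrosis_related` (boolean).
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @return a data.frame, one row per antigen.
#' @export
read_panel <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_panel(df)
}

#' Validate an antigen panel data.frame
#'
#' @param df data.frame with columns `antigen_id`, `protein_id`, `source`,
#'   `fibrosis_related`.
#' @return the validated data.frame.
#' @export
validate_panel <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("antigen_id", "protein_id", "source")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$antigen_id)) {
    stop("duplicated antigen id(s) in panel: ",
         paste(unique(df$antigen_id[duplicated(df$antigen_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$source), c("planar_selected", "literature"))
  if (length(bad) > 0) stop("unknown source token(s): ", paste(bad, collapse = ", "))
  if (!"fibrosis_related" %in% colnames(df)) df$fibrosis_related <- FALSE
  if (!is.logical(df$fibrosis_related)) {
    df$fibrosis_related <- .parse_bool(df$fibrosis_related, "fibrosis_related")
  }
  df$fibrosis_related[is.na(df$fibrosis_related)] <- FALSE
  rownames(df) <- NULL
  df
}

#' Join matrix, metadata and panel into one aligned dataset
#'
#' Aligns the rows of the intensity matrix with the metadata and its columns
#' with the antigen panel, and reports the case/control split.
#'
#' @param matrix sample-by-antigen intensity matrix.
#' @param metadata data.frame as returned by [read_metadata()].
#' @param panel data.frame as returned by [read_panel()].
#' @return an object of class `serocall_dataset`: a list with elements
#'   `intensity`, `metadata`, `panel`, `n_cases`, `n_controls`.
#' @export
join_dataset <- function(matrix, metadata, panel) {
  if (nrow(matrix) == 0) stop("no samples in intensity matrix")
  metadata <- validate_metadata(metadata)
  panel <- validate_panel(panel)
  missing_samples <- setdiff(rownames(matrix), metadata$sample_id)
  if (length(missing_samples) > 0) {
    stop("sample id(s) absent from metadata: ",
         paste(missing_samples, collapse = ", "))
  }
  missing_antigens <- setdiff(colnames(matrix), panel$antigen_id)
  if (length(missing_antigens) > 0) {
    stop("antigen id(s) absent from panel: ",
         paste(missing_antigens, collapse = ", "))
  }
  extra <- setdiff(metadata$sample_id, rownames(matrix))
  if (length(extra) > 0) {
    warning("metadata sample(s) without intensity data dropped: ",
            paste(extra, collapse = ", "))
  }
  metadata <- metadata[match(rownames(matrix), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  panel <- panel[panel$antigen_id %in% colnames(matrix), , drop = FALSE]
  panel <- panel[match(colnames(matrix), panel$antigen_id), , drop = FALSE]
  rownames(panel) <- NULL
  out <- list(intensity = matrix, metadata = metadata, panel = panel,
              n_cases = sum(metadata$group == "case"),
              n_controls = sum(metadata$group == "control"))
  class(out) <- "serocall_dataset"
  message(sprintf("joined dataset: %d cases / %d controls, %d antigens",
                  out$n_cases, out$n_controls, ncol(matrix)))
  out
}

#' @export
print.serocall_dataset <- function(x, ...) {
  cat(sprintf("serocall dataset: %d samples (%d cases / %d controls) x %d antigens\n",
              nrow(x$intensity), x$n_cases, x$n_controls, ncol(x$intensity)))
  invisible(x)
}
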