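#' Count-cutoff panel classifier with ROC/AUC
#'
#' The panel classifier labels a sample positive when its panel load (count
#' of positive calls over the panel targets) is at least `k`. For
#' `k = 0 .. k_max + 1` it reports the true- and false-positive rates, the
#' percent of cases classified positive and percent of controls classified
#' negative (whole percents, half-up), and computes the AUC by the
#' trapezoid rule over the step curve anchored at (0,0) and (1,1). When
#' `k_max` covers the maximum observed load, this AUC equals the
#' probability-of-correct-ordering (Mann-Whitney U with half-credit ties)
#' of the loads.
#'
#' @param calls binary sample-by-target matrix restricted to the panel.
#' @param labels `"case"` / `"control"` labels aligned with rows.
#' @param k_max largest cutoff to tabulate (default: maximum observed
#'   load).
#' @return list of class `serocall_roc` with `table` (one row per cutoff)
#'   and `auc`.
#' @export
count_classifier_roc <- function(calls, labels, k_max = NULL) {
  if (ncol(as.matrix(calls)) == 0) stop("empty panel")
  labels <- as.character(labels)
  load <- rowSums(as.matrix(calls))
  case <- labels == "case"
  n_case <- sum(case)
  n_ctrl <- sum(!case)
  if (n_case == 0 || n_ctrl == 0) stop("both label groups must be non-empty")
  if (is.null(k_max)) k_max <- max(load)
  ks <- 0:(k_max + 1)
  tpr <- vapply(ks, function(k) mean(load[case] >= k), numeric(1))
  fpr <- vapply(ks, function(k) mean(load[!case] >= k), numeric(1))
  tab <- data.frame(k = ks, tpr = tpr, fpr = fpr,
                    pct_cases_positive = round_half_up(100 * tpr),
                    pct_controls_negative = round_half_up(100 * (1 - fpr)))
  pts <- unique(rbind(data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                      tab[, c("fpr", "tpr")]))
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  out <- list(table = tab, auc = auc, n_case = n_case, n_control = n_ctrl)
  class(out) <- "serocall_roc"
  out
}

#' @export
print.serocall_roc <- function(x, ...) {
  cat(sprintf("count-classifier ROC: %d cases / %d controls, AUC = %.3f\n",
              x$n_case, x$n_control, x$auc))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Hierarchical clustering of binary autoantibody profiles
#'
#' Clusters samples on their binary reactivity profiles using simple
#' matching (Hamming proportion) distances by default - chosen over Jaccard
#' because all-negative profiles make Jaccard undefined between zero
#' vectors - and agglomerative linkage (complete by default), cut to `k`
#' clusters. Labels are deterministic: clusters are numbered by decreasing
#' mean within-cluster positivity, so the least-reactive cluster always
#' receives the highest label. Rows are put in a canonical (sample-id)
#' order before linkage so that the result is invariant to input row order
#' even when binary distances tie.
#'
#' @param calls binary sample-by-target matrix (typically cases only,
#'   restricted to selected targets).
#' @param k number of clusters (default 4).
#' @param distance `"simple_matching"` (default) or `"jaccard"`.
#' @param linkage `"complete"` (default), `"average"` or `"ward.D2"`.
#' @return list of class `serocall_clusters` with `assignment` (named
#'   integer vector), `hclust`, `order` (sample ids in dendrogram order), `k`,
#'   `cluster_positivity` (mean positivity per cluster),
#'   `target_prevalence` (per-cluster per-target positivity fraction) and
#'   `silhouette` (mean silhouette width, diagnostic only; `NA` if the
#'   cluster package is unavailable).
#' @export
cluster_samples <- function(calls, k = 4,
                            distance = c("simple_matching", "jaccard"),
                            linkage = c("complete", "average", "ward.D2")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  x <- as.matrix(calls)
  if (nrow(x) < k) stop("fewer samples than clusters")
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%04d", seq_len(nrow(x)))
  ## canonical row order before linkage: agglomeration order under tied
  ## binary distances depends on input order, so sort by sample id to make
  ## the assignment invariant to how rows arrive
  x <- x[order(rownames(x)), , drop = FALSE]
  d <- switch(distance,
              simple_matching = stats::dist(x, method = "manhattan") / ncol(x),
              jaccard = stats::dist(x, method = "binary"))
  hc <- stats::hclust(d, method = linkage)
  raw_labels <- stats::cutree(hc, k = k)
  ## renumber by decreasing mean within-cluster positivity (ties: first
  ## occurrence order); the all-negative-like cluster gets label k
  positivity <- tapply(rowMeans(x), raw_labels, mean)
  new_order <- order(-positivity, as.integer(names(positivity)))
  relabel <- integer(k)
  relabel[as.integer(names(positivity))[new_order]] <- seq_len(k)
  assignment <- relabel[raw_labels]
  names(assignment) <- rownames(x)
  target_prev <- do.call(rbind, lapply(seq_len(k), function(cl) {
    colMeans(x[assignment == cl, , drop = FALSE])
  }))
  rownames(target_prev) <- paste0("cluster", seq_len(k))
  sil <- NA_real_
  if (requireNamespace("cluster", quietly = TRUE) && k > 1 && nrow(x) > k) {
    sil <- mean(cluster::silhouette(assignment, d)[, "sil_width"])
  }
  out <- list(assignment = assignment, hclust = hc,
              order = rownames(x)[hc$order], k = k,
              cluster_positivity = tapply(rowMeans(x), assignment, mean),
              target_prevalence = target_prev, silhouette = sil,
              distance = distance, linkage = linkage)
  class(out) <- "serocall_clusters"
  out
}

#' @export
print.serocall_clusters <- function(x, ...) {
  cat(sprintf("binary-profile clustering: %d samples, k = %d (%s distance, %s linkage)\n",
              length(x$assignment), x$k, x$distance, x$linkage))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Per-cluster clinical-feature prevalence table
#'
#' For each cluster and each clinical flag / clinical antibody, the percent
#' of member samples positive among those with a non-missing value (whole
#' percent, half-up); `NA` when the feature is missing for every member.
#'
#' @param result a [cluster_samples()] result.
#' @param metadata metadata data.frame covering all clustered samples.
#' @param features character vector of logical metadata columns to
#'   summarize (default: all clinical flags and antibodies present).
#' @return data.frame, one row per cluster, one column per feature (plus
#'   `cluster` and `n`).
#' @export
cluster_feature_summary <- function(result, metadata, features = NULL) {
  metadata <- as.data.frame(metadata)
  missing_samples <- setdiff(names(result$assignment), metadata$sample_id)
  if (length(missing_samples) > 0) {
    stop("clustered sample(s) absent from metadata: ",
         paste(missing_samples, collapse = ", "))
  }
  meta <- metadata[match(names(result$assignment), metadata$sample_id), ,
                   drop = FALSE]
  if (is.null(features)) {
    features <- intersect(c(.flag_fields, .antibody_fields), colnames(meta))
  }
  rows <- lapply(seq_len(result$k), function(cl) {
    members <- result$assignment == cl
    vals <- vapply(features, function(f) {
      v <- meta[[f]][members]
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else percent_half_up(sum(v), length(v))
    }, numeric(1))
    data.frame(cluster = cl, n = sum(members), t(vals),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-cluster membership summary for a patient subgroup
#'
#' Answers questions of the form "what percent of the mRSS > 15 patients
#' fall in clusters 1 or 2": among samples where `mask` is `TRUE`
#' (missing-mask samples excluded), the fraction assigned to any of
#' `clusters`.
#'
#' @param result a [cluster_samples()] result.
#' @param mask logical vector aligned with `names(result$assignment)`.
#' @param clusters integer vector of cluster labels forming the union.
#' @return list with `n_in`, `n_total`, `fraction` and `pct` (whole
#'   percent, half-up).
#' @export
cluster_membership <- function(result, mask, clusters) {
  stopifnot(length(mask) == length(result$assignment))
  sel <- !is.na(mask) & mask
  n_total <- sum(sel)
  if (n_total == 0) stop("empty subgroup")
  n_in <- sum(result$assignment[sel] %in% clusters)
  list(n_in = n_in, n_total = n_total, fraction = n_in / n_total,
       pct = percent_half_up(n_in, n_total))
}

#' Export a clustered binary heatmap and its ordered table
#'
#' Writes the binary call matrix with rows in dendrogram order as a TSV
#' (a bit-exact twin of any plotted heatmap) and, optionally, a PNG image
#' with binary fill.
#'
#' @param calls binary sample-by-target matrix used for clustering.
#' @param result the matching [cluster_samples()] result.
#' @param tsv_path output TSV path.
#' @param image_path optional PNG path; skipped when `NULL`.
#' @return the row-ordered matrix, invisibly.
#' @export
export_heatmap <- function(calls, result, tsv_path, image_path = NULL) {
  x <- as.matrix(calls)[result$order, , drop = FALSE]
  df <- data.frame(sample_id = rownames(x),
                   cluster = result$assignment[rownames(x)],
                   x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(image_path)) {
    grDevices::png(image_path, width = 600, height = 800)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::image(t(x[rev(seq_len(nrow(x))), , drop = FALSE]),
                    col = c("grey95", "purple4"), axes = FALSE,
                    main = "binary autoantibody profiles (dendrogram order)")
  }
  invisible(x)
}
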