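#' Select planar-array candidate antigens from two screening pools
#'
#' The untargeted-screening selection step: antigens whose nSD in the
#' dcSSc-like pool reaches the cutoff (default 4 SD) and exceeds the
#' lcSSc-like pool by more than `min_difference` are retained and ranked.
#' The composite rank averages two orderings - by descending dcSSc nSD and
#' by descending pool difference - with ties broken by antigen id; both
#' single-key orderings are available via `rank_by`.
#'
#' @param dc_pool,lc_pool named nSD vectors over the same antigen ids (see
#'   [nsd_transform()]).
#' @param cutoff nSD threshold applied to the dcSSc pool (default 4).
#' @param min_difference minimum `nsd_dc - nsd_lc` excess (default 0: any
#'   dcSSc excess counts).
#' @param rank_by `"composite"` (default), `"intensity"` or `"difference"`.
#' @return data.frame with columns `antigen_id`, `nsd_dc`, `nsd_lc`,
#'   `difference`, `composite_rank`, ordered by rank.
#' @export
select_planar_candidates <- function(dc_pool, lc_pool, cutoff = 4,
                                     min_difference = 0,
                                     rank_by = c("composite", "intensity",
                                                 "difference")) {
  rank_by <- match.arg(rank_by)
  if (is.null(names(dc_pool)) || is.null(names(lc_pool)) ||
      !identical(sort(names(dc_pool)), sort(names(lc_pool)))) {
    stop("dc_pool and lc_pool must be named over the same antigen ids")
  }
  lc_pool <- lc_pool[names(dc_pool)]
  difference <- dc_pool - lc_pool
  keep <- dc_pool >= cutoff & difference > min_difference
  df <- data.frame(antigen_id = names(dc_pool)[keep],
                   nsd_dc = unname(dc_pool[keep]),
                   nsd_lc = unname(lc_pool[keep]),
                   difference = unname(difference[keep]),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    df$composite_rank <- integer(0)
    return(df)
  }
  r_int <- rank(-df$nsd_dc, ties.method = "average")
  r_diff <- rank(-df$difference, ties.method = "average")
  score <- switch(rank_by,
                  composite = (r_int + r_diff) / 2,
                  intensity = r_int,
                  difference = r_diff)
  ord <- order(score, df$antigen_id)
  df <- df[ord, , drop = FALSE]
  df$composite_rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Assemble the targeted panel from planar candidates and literature antigens
#'
#' Union of the planar-selected candidates and literature-reported antigens;
#' duplicates (by antigen id) collapse to a single record with the planar
#' source winning.
#'
#' @param candidates data.frame from [select_planar_candidates()], or a
#'   character vector of antigen ids.
#' @param literature data.frame of antigen records (see [read_panel()] for
#'   columns); may be empty.
#' @param protein_map optional named character vector mapping candidate
#'   antigen ids to protein ids; unmapped candidates reuse their antigen id.
#' @param fibrosis_related optional named logical vector for candidate
#'   antigens (default `FALSE`).
#' @return validated panel data.frame.
#' @export
candidates_to_panel <- function(candidates, literature = NULL,
                                protein_map = NULL, fibrosis_related = NULL) {
  ids <- if (is.data.frame(candidates)) candidates$antigen_id else as.character(candidates)
  prot <- if (!is.null(protein_map)) {
    ifelse(ids %in% names(protein_map), protein_map[ids], ids)
  } else ids
  fib <- if (!is.null(fibrosis_related)) {
    ifelse(ids %in% names(fibrosis_related), fibrosis_related[ids], FALSE)
  } else rep(FALSE, length(ids))
  planar <- data.frame(antigen_id = ids, protein_id = unname(prot),
                       source = rep("planar_selected", length(ids)),
                       fibrosis_related = unname(fib),
                       stringsAsFactors = FALSE)
  if (is.null(literature) || nrow(as.data.frame(literature)) == 0) {
    return(validate_panel(planar))
  }
  literature <- validate_panel(literature)
  literature$source <- "literature"
  lit_keep <- literature[!(literature$antigen_id %in% planar$antigen_id), ,
                         drop = FALSE]
  validate_panel(rbind(planar, lit_keep))
}
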