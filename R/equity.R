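#' Distribution of the final rank by the deciles of a grouping indicator
#'
#' Groups ranked tracts by their decile on one indicator (typically the
#' people-of-color or poverty indicator) and summarises the final
#' disparities rank within each group with the median and interquartile
#' range. Tracts whose group decile is missing land in an `"unassigned"`
#' bucket.
#'
#' @param result An `ehd_result` from [ehd_score()].
#' @param group_indicator Id of the grouping indicator; must be a column of
#'   the result's decile table.
#' @return Data frame of class `ehd_group_distribution` with columns
#'   `group` (decile label or `"unassigned"`), `n`, `median_rank`,
#'   `q25`, `q75`.
#' @export
rank_distribution_by_group <- function(result, group_indicator) {
  stopifnot(inherits(result, "ehd_result"))
  dec <- result$deciles
  if (!group_indicator %in% names(dec))
    stop("group indicator '", group_indicator,
         "' not found in the decile table", call. = FALSE)
  ranked <- !is.na(result$scores$ehd_rank)
  g <- dec[[group_indicator]][match(result$scores$GEOID, dec$GEOID)][ranked]
  r <- result$scores$ehd_rank[ranked]
  lab <- ifelse(is.na(g), "unassigned", as.character(g))
  groups <- c(as.character(1:10), if (anyNA(g)) "unassigned")
  rows <- lapply(groups, function(grp) {
    ri <- r[lab == grp]
    if (!length(ri))
      return(data.frame(group = grp, n = 0L, median_rank = NA_real_,
                        q25 = NA_real_, q75 = NA_real_,
                        stringsAsFactors = FALSE))
    q <- stats::quantile(ri, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(group = grp, n = length(ri), median_rank = q[2],
               q25 = q[1], q75 = q[3], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ehd_group_distribution", "data.frame")
  out
}

#' Flag high-impact tracts
#'
#' Tracts at or above the rank cutoff — with the default cutoff of 9, the
#' top 20% of the panel when final scores are distinct.
#'
#' @param result An `ehd_result`.
#' @param cutoff Minimum final rank to flag (default 9).
#' @return Data frame with columns `GEOID`, `ehd_rank`, `final_score` for
#'   the flagged tracts, sorted by descending rank then GEOID.
#' @export
identify_high_impact <- function(result, cutoff = 9L) {
  stopifnot(inherits(result, "ehd_result"))
  s <- result$scores
  keep <- !is.na(s$ehd_rank) & s$ehd_rank >= cutoff
  out <- s[keep, c("GEOID", "ehd_rank", "final_score"), drop = FALSE]
  out <- out[order(-out$ehd_rank, out$GEOID), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Driver indicators of selected tracts
#'
#' For each requested tract, the individual indicators whose decile meets
#' the threshold (default 9) — the indicators that push a high-impact tract
#' into the top ranks. Results are grouped by category and sorted by
#' descending decile, ties broken by indicator id.
#'
#' @param result An `ehd_result`.
#' @param tract_ids Character vector of GEOIDs; all must exist.
#' @param threshold Minimum indicator decile to count as a driver
#'   (default 9).
#' @return Named list (one element per tract, in input order) of data
#'   frames with columns `indicator`, `category`, `decile`.
#' @export
driver_indicators <- function(result, tract_ids, threshold = 9L) {
  stopifnot(inherits(result, "ehd_result"))
  dec <- result$deciles
  unknown <- setdiff(tract_ids, dec$GEOID)
  if (length(unknown))
    stop("unknown tract id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ind <- result$registry$indicators
  ids <- setdiff(names(dec), "GEOID")
  cat_of <- ind$category[match(ids, ind$id)]
  cat_order <- match(cat_of, EHD_CATEGORIES)
  out <- lapply(tract_ids, function(tid) {
    row <- dec[dec$GEOID == tid, ids, drop = FALSE]
    d <- as.integer(row[1, ])
    keep <- !is.na(d) & d >= threshold
    df <- data.frame(indicator = ids[keep], category = cat_of[keep],
                     decile = d[keep], stringsAsFactors = FALSE)
    df <- df[order(match(df$category, EHD_CATEGORIES), -df$decile,
                   df$indicator), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(out) <- tract_ids
  out
}
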