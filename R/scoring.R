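#' Decile score of a raw indicator column
#'
#' Tracts are scored by rank-order of the raw value. Ties receive average
#' ranks; the decile of a tract with average rank `r` among `m` non-missing
#' values is `ceiling(bins * r / m)`, clamped to `[1, bins]`. Missing raw
#' values yield missing deciles, never imputed ones. A direction of -1
#' flips the column before ranking so the top decile always marks the
#' greatest burden.
#'
#' @param x Numeric vector of raw values; `NA` allowed.
#' @param direction +1 (higher raw value = higher burden, default) or -1.
#' @param bins Number of bins (default 10).
#' @return Integer vector of the same length as `x`, values in `1:bins`
#'   where `x` is non-missing and `NA` elsewhere.
#' @examples
#' decile_score(seq(10, 100, by = 10))  # 1:10
#' decile_score(rep(5, 10))             # all ties -> 6
#' @export
decile_score <- function(x, direction = 1, bins = 10L) {
  if (!direction %in% c(-1, 1))
    stop("`direction` must be +1 or -1", call. = FALSE)
  if (bins < 2) stop("`bins` must be >= 2", call. = FALSE)
  ok <- !is.na(x)
  m <- sum(ok)
  if (m == 0L)
    stop("all values missing; cannot assign decile scores", call. = FALSE)
  r <- rank(direction * x[ok], ties.method = "average")
  d <- as.integer(ceiling(bins * r / m))
  d <- pmin(pmax(d, 1L), as.integer(bins))
  out <- rep(NA_integer_, length(x))
  out[ok] <- d
  out
}

#' Decile-score every indicator column of a panel
#'
#' Applies [decile_score()] to each active registry indicator present in the
#' table, honouring each indicator's direction.
#'
#' @param table Tract-by-indicator data frame with a `GEOID` column.
#' @param registry An `ehd_registry`.
#' @return Data frame with `GEOID` and one integer decile column per scored
#'   indicator.
#' @export
decile_table <- function(table, registry) {
  v <- validate_table(table, registry)
  if (!v$ok)
    stop("decile_table: no data for category(ies): ",
         paste(v$failed_categories, collapse = ", "), call. = FALSE)
  active <- registry$indicators[registry$indicators$active, , drop = FALSE]
  present <- active[active$id %in% names(table), , drop = FALSE]
  out <- data.frame(GEOID = as.character(table$GEOID), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(present))) {
    id <- present$id[i]
    out[[id]] <- tryCatch(
      decile_score(table[[id]], direction = present$direction[i],
                   bins = registry$scoring$decile_bins),
      error = function(e) stop("indicator '", id, "': ", conditionMessage(e),
                               call. = FALSE))
  }
  out
}

#' Per-tract category averages of decile scores
#'
#' For each tract and each of the four categories, the arithmetic mean of
#' the non-missing deciles of that category's active indicators. The average
#' is missing when no indicator is available, or when the non-missing
#' fraction falls below `min_category_coverage`.
#'
#' @param deciles Output of [decile_table()].
#' @param registry An `ehd_registry`.
#' @return Data frame with `GEOID`, one `<category>_avg` and one
#'   `<category>_n` (count of contributing indicators) per category.
#' @export
category_averages <- function(deciles, registry) {
  active <- registry$indicators[registry$indicators$active, , drop = FALSE]
  min_cov <- registry$scoring$min_category_coverage
  out <- data.frame(GEOID = deciles$GEOID, stringsAsFactors = FALSE)
  for (cat_ in EHD_CATEGORIES) {
    ids <- intersect(active$id[active$category == cat_], names(deciles))
    short <- category_short(cat_)
    if (!length(ids)) {
      out[[paste0(short, "_avg")]] <- NA_real_
      out[[paste0(short, "_n")]] <- 0L
      next
    }
    mat <- as.matrix(deciles[ids])
    n_ok <- rowSums(!is.na(mat))
    avg <- ifelse(n_ok > 0, rowMeans(mat, na.rm = TRUE), NA_real_)
    need <- max(1, min_cov * length(ids))
    avg[n_ok < need] <- NA_real_
    out[[paste0(short, "_avg")]] <- avg
    out[[paste0(short, "_n")]] <- as.integer(n_ok)
  }
  out
}

category_short <- function(category) {
  c(environmental_exposures = "exposures",
    environmental_effects = "effects",
    sensitive_populations = "sensitive",
    socioeconomic_factors = "socioeconomic")[[category]]
}

#' Pollution Burden score
#'
#' Combines the environmental exposures and environmental effects category
#' averages, with effects down-weighted by `effects_weight` (default 0.5).
#' In the default `weighted_sum` mode the denominator is `1 + w`, so the
#' score attains its maximum of 10 when both averages are 10; the
#' `literal_two` mode divides by 2 instead.
#'
#' @param exposures_avg,effects_avg Numeric vectors of category averages in
#'   `[1, 10]`; `NA` propagates.
#' @param options An [ehd_scoring_options()] object.
#' @return Numeric vector of Pollution Burden scores.
#' @export
pollution_burden <- function(exposures_avg, effects_avg,
                             options = ehd_scoring_options()) {
  if (any(exposures_avg < 0, na.rm = TRUE) || any(effects_avg < 0, na.rm = TRUE))
    stop("category averages must be nonnegative", call. = FALSE)
  w <- options$effects_weight
  denom <- switch(options$pb_denominator_mode,
                  weighted_sum = 1 + w,
                  literal_two = 2)
  (exposures_avg + w * effects_avg) / denom
}

#' Population Characteristics score
#'
#' Arithmetic mean of the sensitive-populations and socioeconomic-factors
#' category averages; attains 10 when both are 10.
#'
#' @param sensitive_avg,socioeconomic_avg Numeric vectors of category
#'   averages in `[1, 10]`; `NA` propagates.
#' @return Numeric vector of Population Characteristics scores.
#' @export
population_characteristics <- function(sensitive_avg, socioeconomic_avg) {
  if (any(sensitive_avg < 0, na.rm = TRUE) ||
      any(socioeconomic_avg < 0, na.rm = TRUE))
    stop("category averages must be nonnegative", call. = FALSE)
  (sensitive_avg + socioeconomic_avg) / 2
}

#' Final cumulative-impact score
#'
#' Risk = threat x vulnerability: the product of the Pollution Burden and
#' Population Characteristics scores, ranging from 1 to 100.
#'
#' @param pb,pc Numeric vectors (Pollution Burden, Population
#'   Characteristics); `NA` propagates.
#' @return Numeric vector of final scores.
#' @export
final_score <- function(pb, pc) pb * pc

#' Final disparities rank
#'
#' Decile rank (1-10) of the final scores across the supplied panel, with
#' 10 marking the highest cumulative impact. Uses the same average-rank tie
#' rule as [decile_score()]; tracts with missing final scores stay unranked
#' and the decile bins are formed over the scored tracts only.
#'
#' @param scores Numeric vector of final scores.
#' @param bins Number of rank bins (default 10).
#' @return Integer vector of ranks in `1:bins`, `NA` where `scores` is `NA`.
#' @export
final_rank <- function(scores, bins = 10L) {
  decile_score(scores, direction = 1, bins = bins)
}

#' Run the full cumulative-impact scoring pipeline
#'
#' Deciles each indicator by rank-order, averages deciles within the four
#' categories, combines them into Pollution Burden and Population
#' Characteristics scores, multiplies those into the final score and
#' assigns the final 1-10 disparities rank relative to the supplied panel.
#'
#' @param table Tract-by-indicator data frame with a `GEOID` column of raw
#'   indicator values.
#' @param registry An `ehd_registry` (default: the bundled 19-indicator
#'   registry).
#' @param quiet Suppress per-stage log messages.
#' @return A list of class `ehd_result` with elements `scores` (data frame:
#'   `GEOID`, four category averages and counts, `pollution_burden`,
#'   `population_characteristics`, `final_score`, `ehd_rank`), `deciles`
#'   (per-indicator decile table) and `registry`.
#' @examples
#' reg <- load_registry()
#' panel <- generate_panel(synthetic_spec(n_tracts = 200, seed = 1))
#' res <- ehd_score(panel, reg, quiet = TRUE)
#' table(res$scores$ehd_rank)
#' @export
ehd_score <- function(table, registry = load_registry(), quiet = FALSE) {
  log_stage <- function(stage, ...) if (!quiet) message("[", stage, "] ", ...)
  v <- validate_table(table, registry)
  if (!v$ok)
    stop("ehd_score: validation failed; no data for category(ies): ",
         paste(v$failed_categories, collapse = ", "), call. = FALSE)
  if (length(v$missing_indicators))
    log_stage("validate", "missing indicators: ",
              paste(v$missing_indicators, collapse = ", "))
  log_stage("validate", nrow(table), " tracts, ",
            length(setdiff(names(table), "GEOID")), " columns")
  dec <- decile_table(table, registry)
  log_stage("decile", nrow(dec), " tracts x ", ncol(dec) - 1L, " indicators, ",
            sum(is.na(dec[-1])), " missing cells")
  avg <- category_averages(dec, registry)
  scores <- avg
  scores$pollution_burden <-
    pollution_burden(avg$exposures_avg, avg$effects_avg, registry$scoring)
  scores$population_characteristics <-
    population_characteristics(avg$sensitive_avg, avg$socioeconomic_avg)
  scores$final_score <-
    final_score(scores$pollution_burden, scores$population_characteristics)
  log_stage("combine", sum(!is.na(scores$final_score)), " of ", nrow(scores),
            " tracts scored")
  if (all(is.na(scores$final_score)))
    stop("ehd_score: no tract received a final score", call. = FALSE)
  scores$ehd_rank <- final_rank(scores$final_score,
                                bins = registry$scoring$decile_bins)
  log_stage("rank", sum(!is.na(scores$ehd_rank)), " tracts ranked")
  structure(list(scores = scores, deciles = dec, registry = registry),
            class = "ehd_result")
}

#' @export
print.ehd_result <- function(x, ...) {
  s <- x$scores
  cat("<ehd_result> ", nrow(s), " tracts, ",
      sum(!is.na(s$ehd_rank)), " ranked\n", sep = "")
  if (any(!is.na(s$final_score))) {
    cat("  final_score: ",
        paste(round(stats::quantile(s$final_score, c(0, .5, 1), na.rm = TRUE), 2),
              collapse = " / "), " (min/median/max)\n", sep = "")
    cat("  rank distribution:\n")
    print(table(rank = s$ehd_rank))
  }
  invisible(x)
}
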