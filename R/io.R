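#' Read a tract-by-indicator CSV
#'
#' First column `GEOID`, read as character so leading zeros survive; the
#' remaining columns are indicator values, empty cells meaning missing.
#' Duplicate GEOIDs and non-numeric cells are rejected rather than coerced.
#'
#' @param path CSV file path.
#' @return Data frame with a character `GEOID` column and numeric
#'   indicator columns.
#' @export
read_indicator_csv <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        check.names = FALSE)
  if (!"GEOID" %in% names(df))
    stop("header must include a GEOID column: ", path, call. = FALSE)
  dup <- unique(df$GEOID[duplicated(df$GEOID)])
  if (length(dup))
    stop("duplicate GEOID(s): ", paste(dup, collapse = ", "), call. = FALSE)
  for (col in setdiff(names(df), "GEOID")) {
    raw <- trimws(df[[col]])
    raw[raw == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop("non-numeric value in column '", col, "', row ", bad[1],
           ": \"", raw[bad[1]], "\"", call. = FALSE)
    df[[col]] <- num
  }
  df
}

SCORE_COLUMNS <- c("GEOID",
                   "exposures_avg", "exposures_n", "effects_avg", "effects_n",
                   "sensitive_avg", "sensitive_n",
                   "socioeconomic_avg", "socioeconomic_n",
                   "pollution_burden", "population_characteristics",
                   "final_score", "ehd_rank")

#' Write pipeline scores (and deciles) to CSV
#'
#' Fixed column order: `GEOID`, per-indicator deciles prefixed `d_`, the
#' four category averages with their contributing counts, Pollution Burden,
#' Population Characteristics, final score and final rank. Missing values
#' become empty fields. Reading the file back with [read_indicator_csv()]
#' reproduces the numeric values.
#'
#' @param result An `ehd_result` from [ehd_score()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(result, path) {
  stopifnot(inherits(result, "ehd_result"))
  dec <- result$deciles
  ind_ids <- setdiff(names(dec), "GEOID")
  dcols <- dec[ind_ids]
  names(dcols) <- paste0("d_", ind_ids)
  out <- cbind(result$scores["GEOID"], dcols,
               result$scores[setdiff(SCORE_COLUMNS, "GEOID")])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write scores to: ", path, call. = FALSE)
  invisible(path)
}

#' Write a correlation report to CSV
#'
#' Two files: `<prefix>_matrix.csv` (the square matrix) and
#' `<prefix>_pairs.csv` (long form: pair, rho, flag).
#'
#' @param report An `ehd_correlation_report`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_correlation_csv <- function(report, prefix) {
  m_path <- paste0(prefix, "_matrix.csv")
  p_path <- paste0(prefix, "_pairs.csv")
  utils::write.csv(data.frame(id = report$ids, report$matrix,
                              check.names = FALSE),
                   m_path, row.names = FALSE, na = "")
  utils::write.csv(correlation_pairs(report, indicators_only = FALSE),
                   p_path, row.names = FALSE, na = "")
  invisible(c(m_path, p_path))
}

#' Write a PCA report to CSV
#'
#' Two files: `<prefix>_loadings.csv` and `<prefix>_shares.csv`.
#'
#' @param report An `ehd_pca_report`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_pca_csv <- function(report, prefix) {
  l_path <- paste0(prefix, "_loadings.csv")
  s_path <- paste0(prefix, "_shares.csv")
  utils::write.csv(data.frame(indicator = report$ids, report$loadings,
                              check.names = FALSE),
                   l_path, row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(report$share),
                              eigenvalue = report$eigenvalues,
                              share = report$share,
                              cumulative = report$cumulative),
                   s_path, row.names = FALSE)
  invisible(c(l_path, s_path))
}

#' Join pipeline scores onto tract geometries
#'
#' Attaches `ehd_rank`, `final_score`, the composite scores and the four
#' category averages as properties of the matching features of a GeoJSON
#' FeatureCollection (matched on the `GEOID` property) and counts the
#' unmatched records on both sides.
#'
#' @param result An `ehd_result`.
#' @param geojson_path Path to a GeoJSON FeatureCollection whose features
#'   carry a `GEOID` property.
#' @return A list of class `ehd_geojoin`: `features` (the joined
#'   FeatureCollection as a list), `matched`, `unmatched_scores`,
#'   `unmatched_geometries`.
#' @export
join_geometry <- function(result, geojson_path) {
  stopifnot(inherits(result, "ehd_result"))
  gj <- tryCatch(jsonlite::read_json(geojson_path),
                 error = function(e) stop("invalid GeoJSON: ",
                                          conditionMessage(e), call. = FALSE))
  if (!identical(gj$type, "FeatureCollection") || is.null(gj$features))
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  s <- result$scores
  attach_cols <- c("ehd_rank", "final_score", "pollution_burden",
                   "population_characteristics", "exposures_avg",
                   "effects_avg", "sensitive_avg", "socioeconomic_avg")
  geo_ids <- character(length(gj$features))
  for (i in seq_along(gj$features)) {
    gid <- gj$features[[i]]$properties$GEOID
    if (is.null(gid))
      stop("feature ", i, " has no GEOID property", call. = FALSE)
    geo_ids[i] <- as.character(gid)
    row <- match(geo_ids[i], s$GEOID)
    if (!is.na(row))
      for (col in attach_cols) {
        val <- s[[col]][row]
        gj$features[[i]]$properties[[col]] <- if (is.na(val)) NULL else val
      }
  }
  matched <- sum(geo_ids %in% s$GEOID)
  structure(list(features = gj,
                 matched = matched,
                 unmatched_scores = sum(!s$GEOID %in% geo_ids),
                 unmatched_geometries = length(geo_ids) - matched),
            class = "ehd_geojoin")
}

#' Write a joined FeatureCollection to GeoJSON
#'
#' @param join An `ehd_geojoin` from [join_geometry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(join, path) {
  stopifnot(inherits(join, "ehd_geojoin"))
  jsonlite::write_json(join$features, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
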