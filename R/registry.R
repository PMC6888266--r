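#' @keywords internal
"_PACKAGE"

EHD_CATEGORIES <- c("environmental_exposures", "environmental_effects",
                    "sensitive_populations", "socioeconomic_factors")

#' Scoring options
#'
#' Parameters controlling how decile scores are aggregated into the final
#' cumulative-impact score.
#'
#' @param effects_weight Nonnegative weight applied to the environmental
#'   effects category average inside the Pollution Burden score. Effects
#'   indicators are proximity-based proxies for exposure and are down-weighted
#'   (default 0.5) to reflect that uncertainty.
#' @param pb_denominator_mode Either `"weighted_sum"` (default; divide by
#'   `1 + effects_weight`, so a tract in the top decile on every indicator
#'   attains the maximum Pollution Burden score of 10) or `"literal_two"`
#'   (divide by 2, capping the score at 7.5 when `effects_weight = 0.5`).
#' @param min_category_coverage Minimum fraction of a category's active
#'   indicators that must be non-missing for the category average to be
#'   computed. The default 0 means any non-missing indicator suffices; a
#'   tract with an entirely missing category always gets a missing average.
#' @param decile_bins Number of rank bins (default 10 for deciles).
#'
#' @return A list of class `ehd_scoring_options`.
#' @export
ehd_scoring_options <- function(effects_weight = 0.5,
                                pb_denominator_mode = c("weighted_sum", "literal_two"),
                                min_category_coverage = 0,
                                decile_bins = 10L) {
  pb_denominator_mode <- match.arg(pb_denominator_mode)
  if (!is.numeric(effects_weight) || length(effects_weight) != 1L || effects_weight < 0)
    stop("`effects_weight` must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(decile_bins) || length(decile_bins) != 1L || decile_bins < 2)
    stop("`decile_bins` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(min_category_coverage) || min_category_coverage < 0 ||
      min_category_coverage > 1)
    stop("`min_category_coverage` must lie in [0, 1]", call. = FALSE)
  structure(list(effects_weight = effects_weight,
                 pb_denominator_mode = pb_denominator_mode,
                 min_category_coverage = min_category_coverage,
                 decile_bins = as.integer(decile_bins)),
            class = "ehd_scoring_options")
}

#' Construct an indicator registry
#'
#' A registry is the schema for a tract-by-indicator panel: one row per
#' indicator with its id, display name, category, direction, provenance and
#' an `active` flag controlling whether it participates in scoring.
#'
#' @param indicators A data frame with columns `id`, `name`, `category`,
#'   `direction`, `source`, `years`, `active`. `category` must be one of
#'   `"environmental_exposures"`, `"environmental_effects"`,
#'   `"sensitive_populations"`, `"socioeconomic_factors"`; `direction` must
#'   be +1 or -1 (-1 indicators are sign-flipped before ranking so that a
#'   higher decile always means greater burden).
#' @param scoring An [ehd_scoring_options()] object.
#'
#' @return An object of class `ehd_registry`.
#' @export
ehd_registry <- function(indicators, scoring = ehd_scoring_options()) {
  indicators <- as.data.frame(indicators, stringsAsFactors = FALSE)
  required <- c("id", "name", "category", "direction", "source", "years", "active")
  missing_cols <- setdiff(required, names(indicators))
  for (col in missing_cols) {
    indicators[[col]] <- switch(col,
      direction = 1, active = TRUE,
      name = indicators$id, "")
  }
  indicators <- indicators[required]
  if (nrow(indicators) == 0L)
    stop("registry has an empty indicator list", call. = FALSE)
  if (any(!nzchar(indicators$id)) || anyNA(indicators$id))
    stop("registry has empty indicator ids", call. = FALSE)
  dup <- unique(indicators$id[duplicated(indicators$id)])
  if (length(dup))
    stop("duplicate indicator id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  bad <- !indicators$category %in% EHD_CATEGORIES
  if (any(bad))
    stop("unknown category for indicator(s) ",
         paste(indicators$id[bad], collapse = ", "), ": ",
         paste(unique(indicators$category[bad]), collapse = ", "),
         " (expected one of ", paste(EHD_CATEGORIES, collapse = ", "), ")",
         call. = FALSE)
  if (!all(indicators$direction %in% c(-1, 1)))
    stop("`direction` must be +1 or -1 for every indicator", call. = FALSE)
  indicators$direction <- as.numeric(indicators$direction)
  indicators$active <- as.logical(indicators$active)
  if (!inherits(scoring, "ehd_scoring_options"))
    scoring <- do.call(ehd_scoring_options, as.list(scoring))
  structure(list(indicators = indicators, scoring = scoring),
            class = "ehd_registry")
}

#' @export
print.ehd_registry <- function(x, ...) {
  counts <- table(factor(x$indicators$category, levels = EHD_CATEGORIES))
  cat("<ehd_registry> ", nrow(x$indicators), " indicators (",
      sum(x$indicators$active), " active)\n", sep = "")
  for (cat_ in EHD_CATEGORIES)
    cat("  ", format(cat_, width = 24), counts[[cat_]], "\n", sep = " ")
  cat("  effects_weight =", x$scoring$effects_weight,
      "| pb_denominator_mode =", x$scoring$pb_denominator_mode, "\n")
  invisible(x)
}

#' Indicator ids of a registry, optionally filtered
#'
#' @param registry An `ehd_registry`.
#' @param category Optional category name to filter on.
#' @param active_only Keep only indicators flagged active (default TRUE).
#' @return Character vector of indicator ids.
#' @export
registry_ids <- function(registry, category = NULL, active_only = TRUE) {
  ind <- registry$indicators
  if (active_only) ind <- ind[ind$active, , drop = FALSE]
  if (!is.null(category)) ind <- ind[ind$category == category, , drop = FALSE]
  ind$id
}

#' Load an indicator registry
#'
#' Reads a registry from YAML (keys `indicators` and optionally `scoring`)
#' or from CSV with the same columns. With `path = NULL` the bundled default
#' registry of 19 indicators — 5 environmental exposures, 5 environmental
#' effects, 2 sensitive-population and 7 socioeconomic indicators — is
#' returned.
#'
#' @param path Path to a `.yaml`/`.yml` or `.csv` registry file, or `NULL`
#'   for the bundled default.
#' @return An `ehd_registry`.
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "registry.yaml", package = "ehdscreen",
                        mustWork = TRUE)
  if (!file.exists(path))
    stop("registry file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    doc <- yaml::read_yaml(path)
    if (is.null(doc$indicators) || !length(doc$indicators))
      stop("registry file has no `indicators` entries: ", path, call. = FALSE)
    ind <- do.call(rbind, lapply(doc$indicators, function(r)
      data.frame(id = as.character(r$id %||% ""),
                 name = as.character(r$name %||% r$id %||% ""),
                 category = as.character(r$category %||% ""),
                 direction = as.numeric(r$direction %||% 1),
                 source = as.character(r$source %||% ""),
                 years = as.character(r$years %||% ""),
                 active = isTRUE(r$active %||% TRUE),
                 stringsAsFactors = FALSE)))
    scoring <- if (is.null(doc$scoring)) ehd_scoring_options()
               else do.call(ehd_scoring_options, doc$scoring)
  } else {
    ind <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(id = "character"))
    scoring <- ehd_scoring_options()
  }
  ehd_registry(ind, scoring)
}

#' Write a registry to YAML
#'
#' Round-trips with [load_registry()]: writing and re-reading yields an
#' equal registry.
#'
#' @param registry An `ehd_registry`.
#' @param path Output file path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "ehd_registry"))
  ind <- registry$indicators
  doc <- list(
    indicators = lapply(seq_len(nrow(ind)), function(i)
      list(id = ind$id[i], name = ind$name[i], category = ind$category[i],
           direction = ind$direction[i], source = ind$source[i],
           years = ind$years[i], active = ind$active[i])),
    scoring = unclass(registry$scoring))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Validate an indicator table against a registry
#'
#' Report-returning check: lists registry indicators missing from the table,
#' extra (unregistered) columns, and the per-indicator missing-value
#' fraction. The check fails only when an active category has no present
#' indicator at all, since that category's average would be undefined for
#' every tract.
#'
#' @param table A tract-by-indicator data frame with a `GEOID` column.
#' @param registry An `ehd_registry`.
#' @return A list of class `ehd_validation` with elements `ok`,
#'   `missing_indicators`, `extra_columns`, `missing_fraction` and
#'   `failed_categories`.
#' @export
validate_table <- function(table, registry) {
  stopifnot(inherits(registry, "ehd_registry"))
  if (!"GEOID" %in% names(table))
    stop("indicator table must have a GEOID column", call. = FALSE)
  active <- registry$indicators[registry$indicators$active, , drop = FALSE]
  cols <- setdiff(names(table), "GEOID")
  missing_ind <- setdiff(active$id, cols)
  extra <- setdiff(cols, registry$indicators$id)
  present <- intersect(active$id, cols)
  miss_frac <- vapply(present, function(id) mean(is.na(table[[id]])), numeric(1))
  failed <- vapply(EHD_CATEGORIES, function(cat_) {
    in_cat <- active$id[active$category == cat_]
    length(in_cat) > 0L && !any(in_cat %in% cols)
  }, logical(1))
  structure(list(ok = !any(failed),
                 missing_indicators = missing_ind,
                 extra_columns = extra,
                 missing_fraction = miss_frac,
                 failed_categories = EHD_CATEGORIES[failed]),
            class = "ehd_validation")
}

#' @export
print.ehd_validation <- function(x, ...) {
  cat("<ehd_validation> ", if (x$ok) "OK" else "FAILED", "\n", sep = "")
  if (length(x$missing_indicators))
    cat("  missing indicators:", paste(x$missing_indicators, collapse = ", "), "\n")
  if (length(x$extra_columns))
    cat("  extra columns (ignored):", paste(x$extra_columns, collapse = ", "), "\n")
  if (length(x$failed_categories))
    cat("  categories with no data:", paste(x$failed_categories, collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
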