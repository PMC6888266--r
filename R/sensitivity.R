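#' Spearman rank correlation of two vectors
#'
#' Pairwise deletion of missing values, average ranks for ties. When either
#' input is constant after deletion the correlation is undefined and `NA`
#' is returned with a warning rather than a number.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single correlation in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' spearman_cor(1:3, c(1, 4, 9))        # 1: monotone
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))  # 0.8
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L)
    stop("need at least 3 paired non-missing observations", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant input: Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Flag a correlation as none / moderate / high
#'
#' Moderate means `0.5 <= |rho| <= 0.8` (closed at 0.5, and 0.8 itself
#' counts as moderate); high means `|rho| > 0.8`. Undefined correlations
#' are flagged `"undefined"`.
#'
#' @param rho Numeric vector of correlations.
#' @return Character vector of flags.
#' @export
correlation_flag <- function(rho) {
  out <- rep("none", length(rho))
  a <- abs(rho)
  out[!is.na(a) & a >= 0.5] <- "moderate"
  out[!is.na(a) & a > 0.8] <- "high"
  out[is.na(rho)] <- "undefined"
  out
}

#' Pairwise Spearman redundancy screen
#'
#' Computes the full pairwise Spearman correlation matrix over the active
#' indicators of a panel and flags each pair as none / moderate / high
#' (see [correlation_flag()]) to surface duplicative indicators. When an
#' `ehd_result` is supplied, the four category averages, the two composite
#' scores and the final rank are appended as extra rows/columns.
#'
#' @param table Tract-by-indicator data frame with a `GEOID` column.
#' @param registry An `ehd_registry`.
#' @param result Optional `ehd_result` from [ehd_score()] whose composite
#'   scores are appended to the matrix.
#' @return A list of class `ehd_correlation_report`: `ids`, `matrix`
#'   (symmetric, unit diagonal), `flags` (character matrix), and
#'   `indicator_ids` (the subset that are raw indicators, excluding
#'   appended composites).
#' @export
correlation_screen <- function(table, registry = load_registry(),
                               result = NULL) {
  active <- registry$indicators[registry$indicators$active, , drop = FALSE]
  ids <- intersect(active$id, names(table))
  if (length(ids) < 2L)
    stop("need at least 2 active indicators present in the table", call. = FALSE)
  cols <- lapply(ids, function(id) table[[id]])
  names(cols) <- ids
  if (!is.null(result)) {
    stopifnot(inherits(result, "ehd_result"))
    s <- result$scores[match(table$GEOID, result$scores$GEOID), , drop = FALSE]
    extras <- list(exposures_avg = s$exposures_avg,
                   effects_avg = s$effects_avg,
                   sensitive_avg = s$sensitive_avg,
                   socioeconomic_avg = s$socioeconomic_avg,
                   pollution_burden = s$pollution_burden,
                   population_characteristics = s$population_characteristics,
                   final_rank = as.numeric(s$ehd_rank))
    cols <- c(cols, extras)
  }
  p <- length(cols)
  m <- diag(1, p)
  dimnames(m) <- list(names(cols), names(cols))
  for (i in seq_len(p - 1L)) for (j in seq(i + 1L, p)) {
    rho <- tryCatch(suppressWarnings(spearman_cor(cols[[i]], cols[[j]])),
                    error = function(e) NA_real_)
    m[i, j] <- m[j, i] <- rho
  }
  flags <- matrix(correlation_flag(m), p, p, dimnames = dimnames(m))
  diag(flags) <- ""
  structure(list(ids = names(cols), matrix = m, flags = flags,
                 indicator_ids = ids),
            class = "ehd_correlation_report")
}

#' @export
print.ehd_correlation_report <- function(x, ...) {
  cat("<ehd_correlation_report> ", length(x$ids), " variables\n", sep = "")
  pairs <- correlation_pairs(x)
  n_high <- sum(pairs$flag == "high")
  n_mod <- sum(pairs$flag == "moderate")
  cat("  ", n_high, " high, ", n_mod, " moderate pair(s)\n", sep = "")
  if (n_high) {
    hi <- pairs[pairs$flag == "high", , drop = FALSE]
    for (i in seq_len(nrow(hi)))
      cat("  high: ", hi$a[i], " ~ ", hi$b[i], " (rho = ",
          round(hi$rho[i], 2), ")\n", sep = "")
  }
  invisible(x)
}

#' Long-form pair listing of a correlation report
#'
#' @param report An `ehd_correlation_report`.
#' @param indicators_only Restrict to raw indicator pairs, dropping appended
#'   composite rows (default TRUE).
#' @return Data frame with columns `a`, `b`, `rho`, `flag`, one row per
#'   unordered pair.
#' @export
correlation_pairs <- function(report, indicators_only = TRUE) {
  ids <- if (indicators_only) report$indicator_ids else report$ids
  m <- report$matrix[ids, ids, drop = FALSE]
  f <- report$flags[ids, ids, drop = FALSE]
  idx <- which(upper.tri(m), arr.ind = TRUE)
  data.frame(a = ids[idx[, 1]], b = ids[idx[, 2]],
             rho = m[idx], flag = f[idx], stringsAsFactors = FALSE)
}

#' Variance explained by principal components of a correlation matrix
#'
#' Eigendecomposes a symmetric (Spearman) correlation matrix and reports
#' each component's share of the trace, sorted descending. Negative
#' eigenvalues — possible for matrices transcribed at 2 decimal places —
#' are retained in both the shares and the trace.
#'
#' @param corr Square symmetric matrix.
#' @param k Number of leading components to summarise (default: all).
#' @param tol Symmetry tolerance.
#' @return A list: `eigenvalues`, `share` (fractions of the trace),
#'   `cumulative` (cumulative shares), `k`, `cumulative_k` (cumulative
#'   share of the first `k`).
#' @export
variance_explained <- function(corr, k = ncol(corr), tol = 1e-8) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || max(abs(corr - t(corr))) > tol)
    stop("`corr` must be square and symmetric", call. = FALSE)
  if (k < 1 || k > ncol(corr))
    stop("`k` must lie in 1..ncol(corr)", call. = FALSE)
  ev <- eigen((corr + t(corr)) / 2, symmetric = TRUE, only.values = TRUE)$values
  share <- ev / sum(diag(corr))
  list(eigenvalues = ev, share = share, cumulative = cumsum(share),
       k = as.integer(k), cumulative_k = sum(share[seq_len(k)]))
}

#' Principal component analysis on rank-transformed indicators
#'
#' Replaces each indicator column by its average ranks (so units drop out),
#' standardises, and runs PCA; this is equivalent to eigendecomposing the
#' Spearman correlation matrix of the panel. Loading-column signs are fixed
#' by making the largest-magnitude loading in each component positive.
#'
#' @param table Tract-by-indicator data frame with a `GEOID` column.
#' @param registry An `ehd_registry`.
#' @param exclude Character vector of indicator ids to drop before the
#'   decomposition (e.g. indicators that carried no weight in a preliminary
#'   pass).
#' @return A list of class `ehd_pca_report`: `ids` (included indicators),
#'   `loadings` (indicator x component), `eigenvalues`, `share`,
#'   `cumulative`, `n_obs` (complete tracts used).
#' @export
pca_ranks <- function(table, registry = load_registry(), exclude = NULL) {
  active <- registry$indicators[registry$indicators$active, , drop = FALSE]
  ids <- setdiff(intersect(active$id, names(table)), exclude)
  if (length(ids) < 2L)
    stop("need at least 2 included indicators", call. = FALSE)
  mat <- as.matrix(table[ids])
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(mat) <= length(ids))
    stop("need more complete tracts than indicators", call. = FALSE)
  const <- vapply(ids, function(id) length(unique(mat[, id])) < 2L, logical(1))
  if (any(const))
    stop("constant column(s) after exclusion: ",
         paste(ids[const], collapse = ", "), call. = FALSE)
  ranks <- apply(mat, 2, rank, ties.method = "average")
  fit <- stats::prcomp(ranks, center = TRUE, scale. = TRUE)
  loadings <- fit$rotation
  for (j in seq_len(ncol(loadings))) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) loadings[, j] <- -loadings[, j]
  }
  ev <- fit$sdev^2
  share <- ev / sum(ev)
  structure(list(ids = ids, loadings = loadings, eigenvalues = ev,
                 share = share, cumulative = cumsum(share),
                 n_obs = nrow(mat)),
            class = "ehd_pca_report")
}

#' @export
print.ehd_pca_report <- function(x, ...) {
  cat("<ehd_pca_report> ", length(x$ids), " indicators, ", x$n_obs,
      " tracts\n  share (%): ",
      paste(round(100 * x$share[seq_len(min(5, length(x$share)))], 2),
            collapse = ", "),
      if (length(x$share) > 5) ", ...", "\n", sep = "")
  invisible(x)
}

#' Flag indicators with weak loadings
#'
#' Returns indicators whose maximum absolute loading across the first
#' `n_components` components falls below `threshold` — candidates for
#' exclusion from the decomposition. Nothing is removed automatically.
#'
#' @param report An `ehd_pca_report`.
#' @param n_components Number of leading components to examine.
#' @param threshold Loading magnitude below which an indicator is flagged
#'   (default 0.2).
#' @return Character vector of flagged indicator ids (possibly empty).
#' @export
weak_loading_flags <- function(report, n_components, threshold = 0.2) {
  stopifnot(inherits(report, "ehd_pca_report"))
  if (n_components < 1 || n_components > ncol(report$loadings))
    stop("`n_components` must lie in 1..", ncol(report$loadings), call. = FALSE)
  l <- abs(report$loadings[, seq_len(n_components), drop = FALSE])
  report$ids[apply(l, 1, max) < threshold]
}

#' Kaiser rule component count
#'
#' Convenience helper: the number of eigenvalues exceeding 1 (the average
#' for a correlation matrix). Reported for orientation only; component
#' selection stays with the user.
#'
#' @param report An `ehd_pca_report` or the output of [variance_explained()].
#' @return Integer count.
#' @export
kaiser_count <- function(report) sum(report$eigenvalues > 1)
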