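#' Latent Pearson correlation matching a target Spearman correlation
#'
#' Under a Gaussian copula, latent normals with Pearson correlation
#' `2 * sin(pi * rho_s / 6)` induce exactly the Spearman correlation
#' `rho_s` on the observed (continuously-distributed) margins.
#'
#' @param rho_s Spearman correlation(s) in `[-1, 1]`; vectors and matrices
#'   are mapped elementwise.
#' @return Latent Pearson correlation(s), same shape as the input.
#' @export
spearman_to_pearson <- function(rho_s) {
  if (any(abs(rho_s) > 1, na.rm = TRUE))
    stop("|rho_s| must be <= 1", call. = FALSE)
  2 * sin(pi * rho_s / 6)
}

#' Nearest positive-semidefinite correlation matrix
#'
#' Projects a symmetric matrix onto the positive-semidefinite cone
#' (Frobenius-nearest, via Higham's alternating projections as implemented
#' in [Matrix::nearPD()]) and restores the unit diagonal. Correlation
#' matrices transcribed at 2 decimal places can be slightly indefinite;
#' already-PSD inputs are returned unchanged with a zero perturbation.
#'
#' @param m Square symmetric matrix.
#' @param tol Eigenvalue tolerance below which `m` counts as PSD already.
#' @return The repaired matrix with attribute `"perturbation"` holding the
#'   Frobenius norm of the applied change.
#' @export
nearest_psd <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("`m` must be square and symmetric", call. = FALSE)
  ev_min <- min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min >= -tol) {
    attr(m, "perturbation") <- 0
    return(m)
  }
  fixed <- as.matrix(Matrix::nearPD(m, corr = TRUE, keepDiag = TRUE)$mat)
  dimnames(fixed) <- dimnames(m)
  attr(fixed, "perturbation") <- norm(fixed - m, type = "F")
  fixed
}

#' Specification for a synthetic tract panel
#'
#' Describes a Gaussian-copula simulation: the number of tracts, the target
#' pairwise Spearman correlation matrix, one marginal distribution per
#' indicator, a missing-completely-at-random rate and a seed. Defaults
#' reproduce the study panel this package emulates: roughly 1,500 tracts on
#' the bundled 19-indicator schema with the transcribed target correlation
#' structure, concentration-like indicators lognormal and percentage-like
#' indicators beta.
#'
#' @param n_tracts Number of tracts (default 1500).
#' @param target_spearman Symmetric target Spearman matrix with unit
#'   diagonal and indicator ids as dimnames (default:
#'   [load_table2_matrix()]).
#' @param marginals Named list, one entry per indicator:
#'   `list(dist = "lognormal", meanlog=, sdlog=)`,
#'   `list(dist = "beta", shape1=, shape2=)`,
#'   `list(dist = "uniform", min=, max=)` or
#'   `list(dist = "gamma", shape=, scale=)`. Defaults chosen by indicator
#'   kind; marginals only shape the raw values, not any rank-based result.
#' @param missing_rate MCAR missingness fraction in `[0, 1)` (default 0).
#' @param seed Integer seed making the panel fully reproducible.
#' @return A list of class `ehd_synthetic_spec`.
#' @export
synthetic_spec <- function(n_tracts = 1500L,
                           target_spearman = load_table2_matrix(),
                           marginals = NULL,
                           missing_rate = 0,
                           seed = 1L) {
  target_spearman <- as.matrix(target_spearman)
  ids <- colnames(target_spearman)
  if (is.null(ids))
    stop("`target_spearman` must carry indicator ids as dimnames", call. = FALSE)
  if (nrow(target_spearman) != ncol(target_spearman) ||
      max(abs(target_spearman - t(target_spearman))) > 1e-8)
    stop("`target_spearman` must be square and symmetric", call. = FALSE)
  if (any(abs(target_spearman) > 1) ||
      any(abs(diag(target_spearman) - 1) > 1e-12))
    stop("`target_spearman` must have unit diagonal and |rho| <= 1", call. = FALSE)
  if (n_tracts < 1) stop("`n_tracts` must be positive", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  if (is.null(marginals)) marginals <- default_marginals(ids)
  missing_marg <- setdiff(ids, names(marginals))
  if (length(missing_marg))
    stop("no marginal given for: ", paste(missing_marg, collapse = ", "),
         call. = FALSE)
  structure(list(n_tracts = as.integer(n_tracts), ids = ids,
                 target_spearman = target_spearman, marginals = marginals,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "ehd_synthetic_spec")
}

# Concentration/rate-like indicators get lognormal marginals,
# percentage-like indicators beta; cosmetic only, ranks are unaffected.
default_marginals <- function(ids) {
  lognormal_ids <- c("diesel", "ozone", "pm25", "toxic_release", "haz_waste",
                     "superfund", "rmp", "wastewater", "cardio",
                     "low_birth_weight")
  out <- lapply(ids, function(id) {
    if (id %in% lognormal_ids)
      list(dist = "lognormal", meanlog = 0, sdlog = 1)
    else
      list(dist = "beta", shape1 = 2, shape2 = 5)
  })
  names(out) <- ids
  out
}

marginal_quantile <- function(u, marginal) {
  switch(marginal$dist,
    lognormal = stats::qlnorm(u, meanlog = marginal$meanlog %||% 0,
                              sdlog = marginal$sdlog %||% 1),
    beta = stats::qbeta(u, shape1 = marginal$shape1 %||% 2,
                        shape2 = marginal$shape2 %||% 2),
    uniform = stats::qunif(u, min = marginal$min %||% 0,
                           max = marginal$max %||% 1),
    gamma = stats::qgamma(u, shape = marginal$shape %||% 2,
                          scale = marginal$scale %||% 1),
    stop("unknown marginal distribution: ", marginal$dist, call. = FALSE))
}

#' Generate a synthetic tract-by-indicator panel
#'
#' Draws latent multivariate normals whose correlation is the elementwise
#' Gaussian-copula conversion of the target Spearman matrix (repaired to
#' positive-semidefinite with [nearest_psd()] if needed), maps each column
#' through its marginal quantile function, injects MCAR missingness, and
#' assigns synthetic 11-character GEOIDs. Identical specs give identical
#' panels.
#'
#' @param spec An [synthetic_spec()] object.
#' @return Data frame with a `GEOID` column and one numeric column per
#'   indicator; attribute `"psd_perturbation"` records the Frobenius norm
#'   of any PSD repair applied to the converted latent matrix.
#' @examples
#' panel <- generate_panel(synthetic_spec(n_tracts = 100, seed = 42))
#' dim(panel)
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "ehd_synthetic_spec"))
  latent <- spearman_to_pearson(spec$target_spearman)
  diag(latent) <- 1
  latent <- nearest_psd(latent)
  perturbation <- attr(latent, "perturbation")
  ch <- tryCatch(chol(latent + diag(1e-10, ncol(latent))),
                 error = function(e)
                   stop("latent correlation matrix is not factorizable ",
                        "after PSD repair", call. = FALSE))
  p <- length(spec$ids)
  set.seed(spec$seed)
  z <- matrix(stats::rnorm(spec$n_tracts * p), spec$n_tracts, p) %*% ch
  u <- stats::pnorm(z)
  out <- data.frame(GEOID = sprintf("53%03d%06d",
                                    (seq_len(spec$n_tracts) - 1L) %/% 1000L + 1L,
                                    seq_len(spec$n_tracts)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(p))
    out[[spec$ids[j]]] <- marginal_quantile(u[, j], spec$marginals[[spec$ids[j]]])
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(spec$n_tracts * p) < spec$missing_rate,
                   spec$n_tracts, p)
    for (j in seq_len(p)) out[[spec$ids[j]]][mask[, j]] <- NA_real_
  }
  attr(out, "psd_perturbation") <- perturbation
  out
}

#' Bundled target Spearman correlation matrix
#'
#' The 19-indicator pairwise Spearman correlation matrix shipped with the
#' package (values to two decimals; composite and final-ranking rows are
#' not part of it). Used as the default calibration target for
#' [synthetic_spec()] and as the worked matrix for [variance_explained()].
#'
#' @return A symmetric 19 x 19 numeric matrix with unit diagonal and
#'   indicator ids as dimnames.
#' @export
load_table2_matrix <- function() {
  path <- system.file("extdata", "table2_spearman.csv", package = "ehdscreen",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  m <- as.matrix(df[-1])
  rownames(m) <- df$id
  stopifnot(identical(rownames(m), colnames(m)))
  m
}
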