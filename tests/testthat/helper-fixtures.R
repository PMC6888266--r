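# Shared fixtures: small registries, random panels, and independent oracles
# used to cross-check the rank-based scoring primitives.

# Independent decile oracle: average rank computed by counting values
# strictly below / tied (no call to rank()), then binned by ceiling.
oracle_decile <- function(x, bins = 10) {
  ok <- !is.na(x)
  v <- x[ok]
  m <- length(v)
  d <- vapply(v, function(vi) {
    below <- sum(v < vi)
    ties <- sum(v == vi)
    avg_rank <- below + (ties + 1) / 2
    min(max(ceiling(bins * avg_rank / m), 1), bins)
  }, numeric(1))
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(d)
  out
}

# Closed-form Spearman for untied data: 1 - 6 * sum(d^2) / (n (n^2 - 1)).
oracle_spearman_untied <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

# Two-indicator registry (one category each side of the model).
mini_registry <- function() {
  ehd_registry(data.frame(
    id = c("exp1", "ses1"),
    name = c("Exposure one", "Socio one"),
    category = c("environmental_exposures", "socioeconomic_factors"),
    direction = 1, source = "synthetic", years = "n/a", active = TRUE,
    stringsAsFactors = FALSE))
}

# Four-indicator registry covering all categories, for pipeline tests
# where hand-built raw values are easier to reason about than 19 columns.
quad_registry <- function() {
  ehd_registry(data.frame(
    id = c("exp1", "eff1", "sen1", "ses1"),
    name = c("Exposure one", "Effect one", "Sensitive one", "Socio one"),
    category = c("environmental_exposures", "environmental_effects",
                 "sensitive_populations", "socioeconomic_factors"),
    direction = 1, source = "synthetic", years = "n/a", active = TRUE,
    stringsAsFactors = FALSE))
}

# Random raw panel for the quad registry.
quad_panel <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(GEOID = sprintf("53%09d", seq_len(n)),
             exp1 = stats::rlnorm(n), eff1 = stats::rlnorm(n),
             sen1 = stats::runif(n), ses1 = stats::rbeta(n, 2, 5),
             stringsAsFactors = FALSE)
}
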