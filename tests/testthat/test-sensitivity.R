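test_that("spearman correlation matches closed forms and handles edge cases", {
  expect_equal(spearman_cor(1:3, c(1, 4, 9)), 1)
  expect_equal(spearman_cor(1:3, c(9, 4, 1)), -1)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) = 1 - 24/120
  expect_equal(spearman_cor(1:5, c(2, 1, 4, 3, 5)), 0.8)
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
  expect_warning(rho <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(rho))
})

test_that("spearman is symmetric and invariant under monotone transforms", {
  set.seed(21)
  for (i in 1:20) {
    x <- stats::rlnorm(40)
    y <- x + stats::rnorm(40)
    rho <- spearman_cor(x, y)
    expect_equal(spearman_cor(y, x), rho)
    expect_equal(spearman_cor(log(x), y), rho)
    expect_equal(spearman_cor(x, exp(y / 4)), rho)
    expect_equal(rho, oracle_spearman_untied(x, y))
  }
})

test_that("correlation flags implement the moderate/high thresholds", {
  expect_equal(correlation_flag(c(0, 0.49, 0.5, 0.8, 0.81, -0.9, NA)),
               c("none", "none", "moderate", "moderate", "high", "high",
                 "undefined"))
})

test_that("the screen equals elementwise spearman and flags duplicates", {
  reg <- quad_registry()
  panel <- quad_panel(50, seed = 6)
  panel$eff1 <- panel$exp1 * 3 + 1  # duplicated information
  rep_ <- correlation_screen(panel, reg)
  expect_equal(diag(rep_$matrix), rep(1, 4), ignore_attr = TRUE)
  expect_equal(rep_$matrix, t(rep_$matrix))
  expect_equal(rep_$matrix["exp1", "eff1"], 1)
  expect_equal(rep_$flags["exp1", "eff1"], "high")
  # oracle equivalence over every pair
  for (a in rep_$ids) for (b in rep_$ids)
    if (a != b)
      expect_equal(rep_$matrix[a, b], spearman_cor(panel[[a]], panel[[b]]))
})

test_that("screen appends composite scores when a result is supplied", {
  reg <- quad_registry()
  panel <- quad_panel(80, seed = 8)
  res <- ehd_score(panel, reg, quiet = TRUE)
  rep_ <- correlation_screen(panel, reg, result = res)
  expect_true(all(c("pollution_burden", "population_characteristics",
                    "final_rank") %in% rep_$ids))
  expect_equal(rep_$indicator_ids, c("exp1", "eff1", "sen1", "ses1"))
  # composite rows do not appear among the indicator pairs
  pairs <- correlation_pairs(rep_)
  expect_false(any(pairs$a == "final_rank" | pairs$b == "final_rank"))
  expect_equal(nrow(pairs), choose(4, 2))
})

test_that("independent columns show only small sample correlations", {
  reg <- quad_registry()
  set.seed(13)
  n <- 4000
  panel <- data.frame(GEOID = sprintf("53%09d", 1:n),
                      exp1 = stats::rnorm(n), eff1 = stats::rnorm(n),
                      sen1 = stats::rnorm(n), ses1 = stats::rnorm(n))
  rep_ <- correlation_screen(panel, reg)
  off <- rep_$matrix[upper.tri(rep_$matrix)]
  expect_true(all(abs(off) < 3 / sqrt(n)))
  expect_true(all(correlation_pairs(rep_)$flag == "none"))
})

test_that("variance explained reproduces simple eigenstructures", {
  ve <- variance_explained(diag(2))
  expect_equal(ve$share, c(0.5, 0.5))
  ve1 <- variance_explained(matrix(1, 2, 2), k = 1)
  expect_equal(ve1$cumulative_k, 1)
  expect_error(variance_explained(matrix(c(1, 0.2, 0.5, 1), 2, 2)),
               "symmetric")
  # shares are nonincreasing and sum to 1 even with negative eigenvalues
  m <- load_table2_matrix()
  ve2 <- variance_explained(m)
  expect_true(all(diff(ve2$share) <= 1e-12))
  expect_equal(sum(ve2$share), 1)
})

test_that("rank PCA matches the Spearman-matrix eigendecomposition", {
  reg <- load_registry()
  panel <- generate_panel(synthetic_spec(n_tracts = 2000, seed = 17))
  pca <- pca_ranks(panel, reg)
  screen <- correlation_screen(panel, reg)
  ve <- variance_explained(screen$matrix)
  # data-space PCA on standardized ranks == eigen of the sample Spearman matrix
  expect_equal(pca$share, ve$share, tolerance = 1e-8)
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  # loading columns are orthonormal with positive dominant entries
  g <- crossprod(pca$loadings)
  expect_equal(g, diag(ncol(g)), tolerance = 1e-8, ignore_attr = TRUE)
  for (j in seq_len(ncol(pca$loadings)))
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
})

test_that("two perfectly rank-correlated indicators collapse onto one component", {
  reg <- mini_registry()
  set.seed(23)
  x <- stats::rlnorm(100)
  panel <- data.frame(GEOID = sprintf("53%09d", 1:100),
                      exp1 = x, ses1 = exp(x))
  pca <- pca_ranks(panel, reg)
  expect_equal(pca$share[1], 1)
  panel$ses1 <- 1
  expect_error(pca_ranks(panel, reg), "constant column.*ses1")
})

test_that("weak-loading flags pick out indicators outside the factor structure", {
  reg <- quad_registry()
  set.seed(31)
  n <- 500
  f <- stats::rnorm(n)
  panel <- data.frame(GEOID = sprintf("53%09d", 1:n),
                      exp1 = f + 0.1 * stats::rnorm(n),
                      eff1 = f + 0.1 * stats::rnorm(n),
                      sen1 = f + 0.1 * stats::rnorm(n),
                      ses1 = stats::rnorm(n))  # orthogonal to the factor
  pca <- pca_ranks(panel, reg)
  expect_equal(weak_loading_flags(pca, n_components = 1), "ses1")
  expect_false("exp1" %in% weak_loading_flags(pca, n_components = 1))
  expect_length(weak_loading_flags(pca, n_components = 2, threshold = 0), 0)
  expect_error(weak_loading_flags(pca, n_components = 10), "1\\.\\.4")
  expect_true(kaiser_count(pca) >= 1)
})
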