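test_that("decile scores follow the average-rank ceiling rule", {
  expect_equal(decile_score(seq(10, 100, by = 10)), 1:10)
  # full tie: average rank 5.5 of 10 -> ceiling(5.5) = 6
  expect_equal(decile_score(rep(5, 10)), rep(6L, 10))
  # direction -1 reverses the ordering
  expect_equal(decile_score(seq(10, 100, by = 10), direction = -1), 10:1)
  # missing raw values stay missing and shrink the ranked pool
  x <- c(NA, 1, 2, NA, 3)
  d <- decile_score(x)
  expect_equal(is.na(d), is.na(x))
  expect_equal(d[!is.na(d)], oracle_decile(x)[!is.na(x)])
  expect_error(decile_score(c(NA_real_, NA_real_)), "all values missing")
})

test_that("decile scores match the counting oracle on random tied columns", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(20:300, 1)
    x <- sample(round(stats::rlnorm(n), sample(0:2, 1)))
    x[sample(n, floor(n / 10))] <- NA
    expect_equal(decile_score(x), oracle_decile(x))
  }
})

test_that("deciles conserve bin counts for distinct values", {
  set.seed(7)
  for (n in c(50, 200, 1000)) {
    x <- sample(stats::rnorm(n))
    expect_equal(unname(table(decile_score(x))), rep(n / 10, 10),
                 ignore_attr = TRUE)
  }
})

test_that("category averages use available indicators and honour coverage", {
  reg <- load_registry()
  dec <- data.frame(GEOID = "t1", diesel = 10L, ozone = 10L, pm25 = 10L,
                    toxic_release = 10L, traffic = 10L,
                    lead_risk = 3L, haz_waste = NA_integer_, superfund = 5L,
                    rmp = NA_integer_, wastewater = 4L,
                    cardio = 4L, low_birth_weight = NA_integer_,
                    low_education = 2L, housing_burden = 4L, ling_iso = 6L,
                    poverty = 8L, race_eth = 10L, transport = 1L,
                    unemployment = 4L, stringsAsFactors = FALSE)
  avg <- category_averages(dec, reg)
  expect_equal(avg$exposures_avg, 10)
  expect_equal(avg$effects_avg, mean(c(3, 5, 4)))
  expect_equal(avg$effects_n, 3L)
  expect_equal(avg$sensitive_avg, 4)   # mean of the one available decile
  expect_equal(avg$sensitive_n, 1L)
  expect_equal(avg$socioeconomic_avg, 35 / 7)

  # with full coverage required, partially observed categories go missing
  reg$scoring$min_category_coverage <- 1
  avg2 <- category_averages(dec, reg)
  expect_true(is.na(avg2$effects_avg))
  expect_true(is.na(avg2$sensitive_avg))
  expect_equal(avg2$exposures_avg, 10)
})

test_that("pollution burden weighting restores the maximum of 10", {
  opts <- ehd_scoring_options()
  expect_equal(pollution_burden(10, 10, opts), 10)
  expect_equal(pollution_burden(1, 1, opts), 1)
  expect_equal(pollution_burden(10, 1, opts), 10.5 / 1.5)
  # the printed-denominator mode caps at 7.5
  lit <- ehd_scoring_options(pb_denominator_mode = "literal_two")
  expect_equal(pollution_burden(10, 10, lit), 7.5)
  expect_error(pollution_burden(-1, 5, opts), "nonnegative")
  expect_true(is.na(pollution_burden(NA, 5, opts)))
})

test_that("population characteristics is the plain category midpoint", {
  expect_equal(population_characteristics(10, 10), 10)
  expect_equal(population_characteristics(1, 1), 1)
  expect_equal(population_characteristics(4, 6), 5)
  expect_error(population_characteristics(-2, 6), "nonnegative")
})

test_that("final rank deciles final scores with the same tie rule", {
  expect_equal(final_score(7.5, 8), 60)
  set.seed(11)
  r <- final_rank(sample(stats::runif(20)))
  expect_equal(unname(table(r)), rep(2, 10), ignore_attr = TRUE)
  expect_equal(final_rank(rep(42, 15)), rep(6L, 15))
})

test_that("the pipeline produces in-range, internally consistent scores", {
  reg <- load_registry()
  panel <- generate_panel(synthetic_spec(n_tracts = 300, missing_rate = 0.05,
                                         seed = 5))
  res <- ehd_score(panel, reg, quiet = TRUE)
  s <- res$scores
  expect_equal(s$GEOID, panel$GEOID)
  ok <- !is.na(s$final_score)
  expect_true(all(s$pollution_burden[ok] >= 1 & s$pollution_burden[ok] <= 10))
  expect_true(all(s$population_characteristics[ok] >= 1 &
                  s$population_characteristics[ok] <= 10))
  expect_true(all(s$final_score[ok] >= 1 & s$final_score[ok] <= 100))
  expect_equal(s$final_score[ok],
               (s$pollution_burden * s$population_characteristics)[ok])
  expect_equal(is.na(s$ehd_rank), is.na(s$final_score))
  expect_true(all(s$ehd_rank[ok] %in% 1:10))
  # category averages bounded by their contributing deciles
  dmat <- as.matrix(res$deciles[registry_ids(reg, "environmental_exposures")])
  lo <- apply(dmat, 1, min, na.rm = TRUE)
  hi <- apply(dmat, 1, max, na.rm = TRUE)
  expect_true(all(s$exposures_avg >= lo & s$exposures_avg <= hi, na.rm = TRUE))
})

test_that("a tract dominating every indicator takes the top rank", {
  reg <- quad_registry()
  panel <- quad_panel(40, seed = 2)
  panel[1, c("exp1", "eff1", "sen1", "ses1")] <-
    apply(panel[-1, -1], 2, max) * 2
  res <- ehd_score(panel, reg, quiet = TRUE)
  expect_equal(res$scores$ehd_rank[1], 10L)
  expect_equal(max(res$scores$final_score), res$scores$final_score[1])
})

test_that("tracts with an entirely missing category drop out of the ranking", {
  reg <- quad_registry()
  panel <- quad_panel(30, seed = 4)
  panel$sen1[1:3] <- NA
  res <- ehd_score(panel, reg, quiet = TRUE)
  expect_true(all(is.na(res$scores$ehd_rank[1:3])))
  expect_equal(sum(!is.na(res$scores$ehd_rank)), 27L)
  # decile bins are formed over the 27 scored tracts only
  expect_equal(res$scores$ehd_rank[-(1:3)],
               oracle_decile(res$scores$final_score)[-(1:3)])
})

test_that("increasing one raw value never lowers a tract's final score", {
  reg <- quad_registry()
  set.seed(9)
  for (i in 1:10) {
    panel <- quad_panel(60, seed = i)
    tract <- sample(60, 1)
    col <- sample(c("exp1", "eff1", "sen1", "ses1"), 1)
    before <- ehd_score(panel, reg, quiet = TRUE)$scores$final_score[tract]
    panel[[col]][tract] <- panel[[col]][tract] + stats::rexp(1)
    after <- ehd_score(panel, reg, quiet = TRUE)$scores$final_score[tract]
    expect_gte(after, before)
  }
})
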