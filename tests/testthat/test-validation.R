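test_that("LOOCV reports both held-out and in-sample metrics coherently", {
  g <- make_sim_cohort(n = 20, noise_sd = 0.1, seed = 101)
  rep1 <- loocv(g)
  expect_equal(nrow(rep1$per_fold_predictions), 20)
  expect_gte(rep1$rmse, rep1$mae)
  expect_equal(rep1$n_folds_converged, 20)
  # held-out error can only be worse than apparent error
  expect_gte(rep1$rmse, rep1$apparent$rmse)
  # in-sample identities: RMSE = sqrt(RSS/n), calibration slope = R2,
  # intercept = (1 - R2) * mean(observed)
  expect_equal(rep1$apparent$rmse, sqrt(rep1$apparent$rss / 20),
               tolerance = 1e-12)
  expect_equal(rep1$apparent$calibration_slope, rep1$apparent$r2,
               tolerance = 1e-8)
  expect_equal(rep1$apparent$calibration_intercept,
               (1 - rep1$apparent$r2) * mean(g$vo2vent_measured),
               tolerance = 1e-8)
})

test_that("LOOCV is deterministic and exact on model-true data", {
  g <- generate_cohort(16, noise_sd = 0, seed = 111)
  r1 <- loocv(g)
  r2 <- loocv(g)
  expect_identical(r1, r2)
  expect_lt(r1$rmse, 1e-6)

  small <- generate_cohort(14, noise_sd = 0.1, seed = 112)
  expect_error(loocv(small[1:10, ]), class = "insufficient_data")
})

test_that("calibration regression satisfies its defining identities", {
  obs <- c(0.4, 0.7, 0.9, 1.2, 0.6)
  expect_equal(calibration(obs, obs), list(slope = 1, intercept = 0),
               tolerance = 1e-12)
  expect_equal(calibration(obs, 2 * obs)$slope, 2, tolerance = 1e-12)
  expect_equal(calibration(obs, 2 * obs)$intercept, 0, tolerance = 1e-12)
  expect_error(calibration(rep(1, 5), runif(5)), class = "undefined_slope")
  expect_error(calibration(1:2, 1:2), class = "insufficient_data")
})

test_that("bootstrap validation is seed-reproducible and orders its CIs", {
  g <- make_sim_cohort(n = 16, noise_sd = 0.1, seed = 121)
  b1 <- bootstrap_validation(g, n_iterations = 100, seed = 9)
  b2 <- bootstrap_validation(g, n_iterations = 100, seed = 9)
  expect_identical(b1, b2)
  b3 <- bootstrap_validation(g, n_iterations = 100, seed = 10)
  expect_false(identical(b1$raw_distributions, b3$raw_distributions))
  for (ci in c(b1$metric_cis, b1$coefficient_cis)) {
    expect_lte(ci[1], ci[2])
  }
  expect_error(bootstrap_validation(g, n_iterations = 50, seed = 1),
               class = "domain_error")
})

test_that("bootstrap metric intervals contract as the noise vanishes", {
  noisy <- generate_cohort(16, noise_sd = 0.2, seed = 131)
  quiet <- generate_cohort(16, noise_sd = 0.01, seed = 131)
  bn <- bootstrap_validation(noisy, n_iterations = 100, seed = 5)
  bq <- bootstrap_validation(quiet, n_iterations = 100, seed = 5)
  width <- function(b) diff(b$metric_cis$apparent_r2)
  expect_lt(width(bq), width(bn))
  expect_gt(min(bq$raw_distributions[, "apparent_r2"], na.rm = TRUE), 0.99)
})

test_that("bootstrap coefficient intervals cover the generating linear terms", {
  pc <- published_composite()
  g <- generate_cohort(42, noise_sd = 0.05, seed = 141)
  b <- bootstrap_validation(g, n_iterations = 150, seed = 6)
  for (term in c("age1", "vp1", "hr1")) {
    ci <- b$coefficient_cis[[term]]
    expect_gte(pc[[term]], ci[1])
    expect_lte(pc[[term]], ci[2])
  }
})

test_that("collinearity screening reproduces the printed correlation and the VIF oracle", {
  t1 <- table1_cohort()
  co <- collinearity(t1)
  expect_equal(co$pearson_matrix["vo2peak", "height"], 0.761,
               tolerance = 0.005)
  expect_equal(unname(diag(co$pearson_matrix)), rep(1, 6))
  expect_true(all(co$vif >= 1))
  expect_lt(max(co$vif), 5)
  # oracle: VIFs are the diagonal of the inverse predictor correlation matrix
  expect_equal(unname(co$vif), unname(diag(solve(co$pearson_matrix))),
               tolerance = 1e-8)
})

test_that("orthogonal predictors give unit VIFs and degeneracy is caught", {
  # mutually orthogonal columns via a designed grid, shifted into valid ranges
  d <- expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1))
  d <- rbind(d, d)
  df <- data.frame(subject_id = as.character(1:16),
                   ve_peak = 100 + 10 * d$a, age = 30 + 5 * d$b,
                   weight = 70 + 10 * d$c, height = 170 + 5 * d$a * d$b,
                   vo2peak = 4 + 0.5 * d$a * d$c, hr_max = 180 + 5 * d$b * d$c)
  co <- collinearity(cohort_table(df))
  expect_equal(unname(co$vif), rep(1, 6), tolerance = 1e-8)

  dup <- df
  dup$vo2peak <- dup$ve_peak / 25  # exact linear copy of another predictor
  expect_error(collinearity(cohort_table(dup)),
               class = "degenerate_predictor")
  const <- df
  const$age <- 30
  expect_error(collinearity(cohort_table(const)),
               class = "degenerate_predictor")
})

test_that("residual diagnostics expose constructed trends", {
  fake <- function(obs, pred) {
    structure(list(per_fold_predictions = data.frame(
      subject_id = seq_along(obs), observed = obs, predicted = pred)),
      class = "validation_report")
  }
  perfect <- residual_diagnostics(fake(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(perfect$table$residual, rep(0, 4))
  expect_equal(perfect$trend_slope, 0)

  # observed = 2 * predicted, so residual = predicted: trend slope 1
  pred <- c(0.3, 0.5, 0.8, 1.1)
  built <- suppressWarnings(residual_diagnostics(fake(2 * pred, pred)))
  expect_equal(built$trend_slope, 1, tolerance = 1e-10)
})
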