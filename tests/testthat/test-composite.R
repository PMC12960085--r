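test_that("the published composite set carries the printed constants", {
  pc <- published_composite()
  expect_equal(pc$hr1, 0.001880224895256)
  expect_equal(pc$h_rate, 0.00006302)
  expect_equal(pc$ve3, 0.000000082921)
  expect_equal(pc$provenance, "published")
  expect_length(pc$c0_list, 5)
})

test_that("composite evaluation matches hand arithmetic", {
  pc <- published_composite()
  t1 <- table1_cohort()
  # first derivation subject: VE 71.66, age 28, weight 50.8, height 168.7,
  # vo2peak 2.1681, HRmax 191 -> ~0.415 against a measured 0.42
  expect_equal(as.numeric(evaluate_composite(pc, t1[1, ])), 0.41455,
               tolerance = 1e-4)
  # all predictors zero: constants sum minus h_scale * exp(0)
  zero <- data.frame(ve_peak = 0, age = 0, weight = 0, height = 0,
                     vo2peak = 0, hr_max = 0)
  expect_equal(as.numeric(suppressWarnings(
    evaluate_composite(pc, zero, guard = FALSE))),
    sum(pc$c0_list) + pc$h_scale, tolerance = 1e-9)
  expect_equal(sum(pc$c0_list) + pc$h_scale, 3.519341, tolerance = 1e-5)
})

test_that("a coefficient set that is one constant predicts that constant", {
  k <- composite_coefficients(c(0.7, 0, 0, 0, 0), 0, 0, 0, 0, 0, 0, 0, 0,
                              0, 0, 0)
  t1 <- table1_cohort()
  expect_equal(as.numeric(evaluate_composite(k, t1)), rep(0.7, 42))
})

test_that("predictions are invariant to redistributing the additive constants", {
  pc <- published_composite()
  t1 <- table1_cohort()
  base <- as.numeric(evaluate_composite(pc, t1))
  set.seed(21)
  for (rep in 1:5) {
    shift <- rnorm(4, 0, 50)
    c0 <- pc$c0_list + c(shift, -sum(shift))
    alt <- composite_coefficients(c0, pc$ve1, pc$ve2, pc$ve3, pc$w1, pc$w2,
                                  pc$w3, pc$h_scale, pc$h_rate, pc$age1,
                                  pc$vp1, pc$hr1)
    expect_equal(as.numeric(evaluate_composite(alt, t1)), base,
                 tolerance = 1e-9)
  }
})

test_that("negative predictions are clamped with the raw value retained", {
  k <- composite_coefficients(c(-1, 0, 0, 0, 0), 0, 0, 0, 0, 0, 0, 0, 0,
                              0, 0, 0)
  t1 <- table1_cohort()
  expect_warning(p <- evaluate_composite(k, t1[1, ]),
                 class = "negative_prediction")
  expect_equal(as.numeric(p), 0)
  expect_equal(attr(p, "unclamped"), -1)
})

test_that("the derivation-cohort refit attains the published optimum", {
  t1 <- table1_cohort()
  fit <- fit_composite(t1)
  expect_true(fit$converged)
  expect_equal(fit$n, 42)
  expect_equal(fit$adjusted_r2,
               1 - (1 - fit$r2) * 41 / 35, tolerance = 1e-12)
  # the refit cannot be worse than the published member of the same family
  pub_pred <- as.numeric(evaluate_composite(published_composite(), t1))
  pub_rss <- sum((t1$vo2vent_measured - pub_pred)^2)
  expect_lte(fit$rss, pub_rss)
  # refits collapse the constant split into one effective intercept
  expect_equal(fit$coefficients$c0_list[2:5], rep(0, 4))
  expect_equal(fit$coefficients$provenance, "refit")
})

test_that("profiled fitting matches a brute-force dense grid on small cohorts", {
  g <- generate_cohort(15, noise_sd = 0.1, seed = 31)
  fit <- fit_composite(g)
  grid <- seq(-0.06, 0.06, length.out = 4001)
  y <- g$vo2vent_measured
  rs <- vapply(grid, function(h) ventcost:::.composite_rss_at(g, y, h), 0)
  expect_lt(fit$rss, min(rs) + 1e-6)
})

test_that("model-true data are fitted perfectly and constant data give R2 = 0", {
  g0 <- generate_cohort(20, noise_sd = 0, seed = 41)
  f0 <- fit_composite(g0)
  expect_lt(f0$rss, 1e-10)
  expect_gt(f0$r2, 1 - 1e-8)

  gc <- as.data.frame(generate_cohort(20, noise_sd = 0, seed = 42))
  gc$vo2vent_measured <- 0.8
  fc <- fit_composite(cohort_table(gc))
  expect_equal(fc$r2, 0)
  slopes <- unlist(fc$coefficients[c("ve1", "ve2", "ve3", "w1", "w2", "w3",
                                     "age1", "vp1", "hr1")])
  expect_equal(unname(slopes), rep(0, 9), tolerance = 1e-8)
})

test_that("refits recover the generating model at the prediction level", {
  pc <- published_composite()
  ref <- generate_cohort(50, noise_sd = 0, seed = 51)  # evaluation grid
  truth <- as.numeric(evaluate_composite(pc, ref))
  for (seed in 1:20) {
    g <- generate_cohort(200, noise_sd = 0.05, seed = 1000 + seed)
    f <- fit_composite(g)
    pred <- as.numeric(evaluate_composite(f$coefficients, ref))
    expect_lt(sqrt(mean((pred - truth)^2)), 0.03)
  }
})

test_that("fitting preconditions are enforced", {
  g <- generate_cohort(14, noise_sd = 0.1, seed = 61)
  expect_error(fit_composite(g[1:12, ]), class = "insufficient_data")
  df <- as.data.frame(g)
  df$vo2vent_measured <- NULL
  expect_error(fit_composite(cohort_table(df)), class = "schema_error")
  btps <- cohort_table(as.data.frame(g), volume_condition = "BTPS")
  expect_error(fit_composite(btps), class = "units_error")
})

test_that("goodness of fit reports both F conventions and hand values", {
  g <- goodness_of_fit(c(0, 1, 2), c(0, 1, 1), k_predictors = 1)
  expect_equal(g$rss, 1)
  expect_equal(g$r2, 0.5)

  # adjusted R2 at the derivation-cohort size
  gg <- goodness_of_fit(seq(0, 1, length.out = 42),
                        seq(0, 1, length.out = 42) + 0.01, k_predictors = 6)
  r2 <- 0.812
  expect_equal(1 - (1 - r2) * 41 / 35, 0.78, tolerance = 0.001)

  perfect <- goodness_of_fit(1:10 / 10, 1:10 / 10, k_predictors = 1)
  expect_equal(perfect$rss, 0)
  expect_equal(perfect$r2, 1)

  expect_error(goodness_of_fit(rep(1, 10), runif(10), k_predictors = 1),
               class = "undefined_r2")
  expect_error(goodness_of_fit(1:3, 1:3, k_predictors = 6),
               class = "insufficient_data")
})

test_that("composite coefficients round-trip through JSON", {
  fit <- fit_composite(generate_cohort(20, noise_sd = 0.05, seed = 71))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_composite(fit$coefficients, tmp)
  back <- read_composite(tmp)
  expect_equal(unclass(back), unclass(fit$coefficients))
})
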