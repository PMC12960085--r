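make_series <- function(n = 60, duration = 300) {
  t <- seq(0, duration, length.out = n)
  rie_series(time = t, power = 50 + t, vo2 = 1 + t / 200, ve = 20 + t / 3)
}

test_that("series invariants are enforced at construction", {
  expect_error(rie_series(c(0, 1, 1), c(0, 1, 2), c(1, 1, 1), c(20, 21, 22)),
               class = "domain_error")
  expect_error(rie_series(0:2, c(0, 1, -2), c(1, 1, 1), c(20, 21, 22)),
               class = "domain_error")
  expect_error(rie_series(0:2, 0:2, c(1, 1), c(20, 21, 22)),
               class = "shape_error")
  # fr * vt must reconstruct ve within 10%
  expect_error(rie_series(0:2, 0:2, c(1, 1, 1), c(20, 21, 22),
                          fr = c(10, 10, 10), vt = c(1, 1, 1)),
               class = "domain_error")
  ok <- rie_series(0:2, 0:2, c(1, 1, 1), c(20, 21, 22),
                   fr = c(20, 21, 22), vt = c(1, 1, 1))
  expect_s3_class(ok, "rie_series")
})

test_that("breath averaging takes block means and drops the remainder", {
  t <- cumsum(rep(2, 14))
  s <- rie_series(t, seq(50, 115, 5), rep(2, 14), rep(40, 14))
  a <- average_breaths(s, 7)
  expect_equal(nrow(a), 2)
  expect_equal(a$vo2, c(2, 2))        # mean of a constant channel
  expect_equal(a$time, c(mean(t[1:7]), mean(t[8:14])))
  expect_equal(attr(a, "averaging_width"), 7L)
  expect_identical(average_breaths(s, 1), s)
  expect_error(average_breaths(s[1:3, ], 7), class = "insufficient_data")
  # width 7 on 15 breaths still yields 2 blocks (trailing breath dropped)
  s15 <- rie_series(c(t, 30), c(seq(50, 115, 5), 120), rep(2, 15),
                    rep(40, 15))
  expect_equal(nrow(average_breaths(s15, 7)), 2)
})

test_that("the VO2vent trajectory follows the instantaneous VE", {
  pc <- published_composite()
  t1 <- table1_cohort()
  sub <- t1[1, ]
  # constant VE at the subject's peak reproduces the peak prediction
  s <- rie_series(time = 0:9, power = seq(50, 300, length.out = 10),
                  vo2 = rep(2, 10), ve = rep(sub$ve_peak, 10))
  v <- predict_vent_series(pc, s, sub)
  expect_equal(v, rep(0.41455, 10), tolerance = 1e-4)

  # monotone rising VE in the cubic's rising range gives a monotone trajectory
  s2 <- rie_series(time = 0:19, power = seq(50, 400, length.out = 20),
                   vo2 = seq(1, 4, length.out = 20),
                   ve = seq(55, 185, length.out = 20))
  v2 <- predict_vent_series(pc, s2, sub)
  expect_true(all(diff(v2) >= 0))

  # BTPS series must be converted first
  sb <- rie_series(time = 0:9, power = seq(50, 300, length.out = 10),
                   vo2 = rep(2, 10), ve = rep(100, 10),
                   volume_condition = "BTPS")
  expect_error(predict_vent_series(pc, sb, sub), class = "units_error")

  # rest-offset mode anchors the first sample at zero
  v3 <- predict_vent_series(pc, s2, sub, rest_offset = TRUE)
  expect_equal(v3[1], 0)
  # peak-anchored mode scales the peak prediction by VE(t)/VE_peak
  v4 <- predict_vent_series(pc, s, sub, mode = "peak_anchored")
  expect_equal(v4, v, tolerance = 1e-4)
})

test_that("correction conserves VO2 and summarizes the peak", {
  s <- make_series()
  vent <- rep(0.5, nrow(s))
  cr <- correct_series(s, vent)
  expect_identical(cr$samples$vo2 - cr$samples$vo2vent, cr$samples$vo2vcorr)
  expect_equal(cr$samples$vo2vent, vent, tolerance = 1e-12)
  expect_equal(cr$wpeak, max(s$power))

  z <- correct_series(s, rep(0, nrow(s)))
  expect_equal(z$samples$vo2vcorr, s$vo2)
  eq <- correct_series(s, s$vo2)
  expect_equal(eq$samples$vo2vcorr, rep(0, nrow(s)))
  expect_error(correct_series(s, 1:3), class = "shape_error")
  expect_warning(correct_series(s, rep(10, nrow(s))), class = "negative_vcorr")

  # peak-sample arithmetic as in the application table: 5.90 - 0.91 = 4.99
  expect_equal(5.90 - 0.91, 4.99)
  expect_equal(cr$percent_vent_at_max,
               percent_of_max(0.5, s$vo2[which.max(s$power)]))
})

test_that("intensity extraction interpolates linearly in power", {
  s <- make_series()
  cr <- correct_series(s, rep(0.5, nrow(s)))
  tab <- intensity_table(cr)
  expect_equal(nrow(tab), 6)
  # endpoint: fraction 1 equals the peak-power sample
  i_pk <- which.max(s$power)
  expect_equal(tab$vo2[6], s$vo2[i_pk])
  # linear channels are interpolated exactly onto the line
  expect_equal(tab$vo2, 1 + (tab$power - 50) / 200, tolerance = 1e-10)
  expect_true(all(diff(tab$vo2) > 0))

  expect_error(intensity_table(cr, fractions = c(0.5, 1.2)),
               class = "domain_error")
  expect_error(intensity_table(cr, fractions = 0.05),
               class = "extrapolation_error")
})

test_that("final-window slopes are OLS per minute over the last seconds", {
  t <- seq(0, 300, by = 2.5)
  y <- 0.2866 * t / 60 + 1
  expect_equal(final_slope(y, t), 0.2866, tolerance = 1e-10)
  expect_equal(final_slope(rep(2, length(t)), t), 0)
  expect_error(final_slope(y[1:2], t[1:2]), class = "insufficient_data")
  # only samples inside the window contribute
  y2 <- y
  y2[t < 270] <- 99
  expect_equal(final_slope(y2, t, window = 30), 0.2866, tolerance = 1e-10)
})

test_that("the paired slope test matches a first-principles oracle", {
  a <- c(0.31, 0.12, 0.45, 0.27)
  b <- c(0.05, 0.02, 0.11, 0.09)
  r <- paired_slope_test(a, b)
  expect_equal(r$t, oracle_paired_t(a, b), tolerance = 1e-10)
  expect_equal(r$t, 4.260282, tolerance = 1e-6)
  expect_equal(r$df, 3)
  expect_equal(r$p, 2 * pt(-abs(r$t), 3), tolerance = 1e-12)
  expect_equal(r$d, mean(a - b) / sd(a - b), tolerance = 1e-12)

  same <- paired_slope_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(paired_slope_test(a, a - 1), class = "degenerate_test")
  jit <- paired_slope_test(c(2, 2, 2.0001), c(1, 1, 1))
  expect_gt(abs(jit$d), 100)
  expect_error(paired_slope_test(1:2, 2:3), class = "insufficient_data")
})

test_that("series round-trip through delimited text", {
  s <- generate_subject(sim_params(seed = 5))$series
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_rie(s, tmp)
  back <- read_rie(tmp)
  expect_equal(back$vo2, s$vo2, tolerance = 1e-6)
  expect_equal(back$ve, s$ve, tolerance = 1e-6)
  expect_error(read_rie("no/such/file.csv"), class = "schema_error")
})
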