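#' Composite-model coefficients
#'
#' The composite model predicts VO2vent (L·min⁻¹) as the sum of five additive
#' constants, a cubic in peak VE, a cubic in weight, an exponential in
#' height, and linear terms in age, VO2 peak and HRmax:
#'
#' \deqn{\hat y = \sum c_0 + v_1 VE + v_2 VE^2 + v_3 VE^3
#'   + w_1 W + w_2 W^2 + w_3 W^3 + h_s e^{h_r H} + a_1 A + p_1 P + r_1 HR}
#'
#' Only the sum of the five constants (the effective intercept) is
#' identifiable; the published set distributes it over five terms and is kept
#' verbatim, while refits return `(intercept, 0, 0, 0, 0)`.
#'
#' @param c0_list Numeric vector of five additive constants.
#' @param ve1,ve2,ve3 VE linear, quadratic, cubic terms.
#' @param w1,w2,w3 Weight linear, quadratic, cubic terms.
#' @param h_scale,h_rate Height exponential scale and rate.
#' @param age1,vp1,hr1 Age, VO2 peak and HRmax linear terms.
#' @param provenance `"published"` or `"refit"`.
#' @return An object of class `composite_coefficients`.
#' @export
composite_coefficients <- function(c0_list, ve1, ve2, ve3, w1, w2, w3,
                                   h_scale, h_rate, age1, vp1, hr1,
                                   provenance = c("refit", "published")) {
  provenance <- match.arg(provenance)
  c0_list <- as.numeric(c0_list)
  if (length(c0_list) != 5) vc_stop("domain_error", "c0_list must have 5 entries")
  vals <- c(c0_list, ve1, ve2, ve3, w1, w2, w3, h_scale, h_rate, age1, vp1, hr1)
  if (!all(is.finite(vals))) vc_stop("domain_error", "all 16 entries must be finite")
  structure(list(c0_list = c0_list, ve1 = ve1, ve2 = ve2, ve3 = ve3,
                 w1 = w1, w2 = w2, w3 = w3, h_scale = h_scale,
                 h_rate = h_rate, age1 = age1, vp1 = vp1, hr1 = hr1,
                 provenance = provenance),
            class = "composite_coefficients")
}

#' @export
print.composite_coefficients <- function(x, ...) {
  cat(sprintf("Composite VO2vent coefficients (%s); effective intercept %.6g\n",
              x$provenance, effective_intercept(x)))
  terms <- unlist(x[c("ve1", "ve2", "ve3", "w1", "w2", "w3",
                      "h_scale", "h_rate", "age1", "vp1", "hr1")])
  print(signif(terms, 6))
  invisible(x)
}

#' Effective intercept of a composite coefficient set
#'
#' @param coeffs A [composite_coefficients()] object.
#' @return The sum of the five additive constants.
#' @export
effective_intercept <- function(coeffs) sum(coeffs$c0_list)

#' The published composite coefficient set
#'
#' The 16 printed constants of the full composite model, exactly as
#' published, including the five-way split of the additive constant and the
#' height pair (scale −144.186859758223, rate 0.00006302 per cm).
#'
#' @return A [composite_coefficients()] with `provenance = "published"`.
#' @export
#' @examples
#' published_composite()$hr1  # 0.001880224895256
published_composite <- function() {
  path <- system.file("extdata", "published_composite.json",
                      package = "ventcost", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  composite_coefficients(j$c0_list, j$ve1, j$ve2, j$ve3, j$w1, j$w2, j$w3,
                         j$h_scale, j$h_rate, j$age1, j$vp1, j$hr1,
                         provenance = "published")
}

#' Read or write a composite coefficient set as JSON
#'
#' @param coeffs A [composite_coefficients()].
#' @param path JSON file path.
#' @return `read_composite()` returns a [composite_coefficients()];
#'   `write_composite()` returns `path` invisibly.
#' @export
write_composite <- function(coeffs, path) {
  jsonlite::write_json(unclass(coeffs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_composite
#' @export
read_composite <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  composite_coefficients(j$c0_list, j$ve1, j$ve2, j$ve3, j$w1, j$w2, j$w3,
                         j$h_scale, j$h_rate, j$age1, j$vp1, j$hr1,
                         provenance = j$provenance)
}

# vectorised raw evaluation, no clamping
.eval_composite_raw <- function(co, ve, weight, height, age, vo2peak, hr_max) {
  sum(co$c0_list) +
    co$ve1 * ve + co$ve2 * ve^2 + co$ve3 * ve^3 +
    co$w1 * weight + co$w2 * weight^2 + co$w3 * weight^3 +
    co$h_scale * exp(co$h_rate * height) +
    co$age1 * age + co$vp1 * vo2peak + co$hr1 * hr_max
}

# predictor ranges of the packaged derivation table, for extrapolation guards
.t1_ranges <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      t1 <- table1_cohort()
      cache <<- lapply(as.data.frame(t1)[.predictor_fields], range)
    }
    cache
  }
})

#' Evaluate the composite model for a set of participants
#'
#' Evaluates the composite form at each participant's six predictors.
#' Negative predictions (physiologically impossible) are clamped to zero
#' with a warning; the unclamped values are kept in the `"unclamped"`
#' attribute. Predictor values outside the derivation-table ranges trigger
#' an extrapolation warning.
#'
#' @param coeffs A [composite_coefficients()].
#' @param participants A [cohort_table()] or data frame with columns
#'   `ve_peak`, `age`, `weight`, `height`, `vo2peak`, `hr_max`.
#' @param guard Warn on extrapolation beyond the derivation-table predictor
#'   ranges (default `TRUE`).
#' @return Predicted VO2vent, L·min⁻¹ (one value per row).
#' @export
#' @examples
#' evaluate_composite(published_composite(), table1_cohort()[1, ])  # ~0.415
evaluate_composite <- function(coeffs, participants, guard = TRUE) {
  stopifnot(inherits(coeffs, "composite_coefficients"))
  p <- as.data.frame(participants)
  miss <- setdiff(.predictor_fields, names(p))
  if (length(miss)) {
    vc_stop("schema_error", "missing predictor column(s): ",
            paste(miss, collapse = ", "))
  }
  if (guard) {
    rngs <- .t1_ranges()
    out_of <- .predictor_fields[vapply(.predictor_fields, function(f) {
      any(p[[f]] < rngs[[f]][1] | p[[f]] > rngs[[f]][2])
    }, logical(1))]
    if (length(out_of)) {
      vc_warn("extrapolation", "predictor(s) outside the derivation range: ",
              paste(out_of, collapse = ", "))
    }
  }
  pred <- .eval_composite_raw(coeffs, p$ve_peak, p$weight, p$height,
                              p$age, p$vo2peak, p$hr_max)
  out <- pred
  if (any(pred < 0)) {
    vc_warn("negative_prediction", sum(pred < 0),
            " negative prediction(s) clamped to 0")
    out <- pmax(pred, 0)
  }
  attr(out, "unclamped") <- pred
  out
}

# design matrix of the 11 linearly entering coefficients at a fixed height rate
.composite_design <- function(df, h_rate) {
  cbind(intercept = 1,
        ve1 = df$ve_peak, ve2 = df$ve_peak^2, ve3 = df$ve_peak^3,
        w1 = df$weight, w2 = df$weight^2, w3 = df$weight^3,
        h_scale = exp(h_rate * df$height),
        age1 = df$age, vp1 = df$vo2peak, hr1 = df$hr_max)
}

.composite_rss_at <- function(df, y, h_rate) {
  X <- .composite_design(df, h_rate)
  f <- .lm.fit(X, y)
  sum(f$residuals^2)
}

#' Fit the composite model to a cohort by profiled least squares
#'
#' The composite form is linear in all coefficients except the height rate.
#' The fit therefore profiles the height rate: a coarse grid over
#' `h_rate_bracket` locates the basin, golden-section refinement minimises
#' the profiled residual sum of squares, and at each candidate rate the
#' remaining 11 identifiable coefficients are solved exactly by linear least
#' squares. The five-way constant split of the published set is not
#' identifiable; refits return a single effective intercept as
#' `(intercept, 0, 0, 0, 0)`.
#'
#' @param cohort A [cohort_table()] with a `vo2vent_measured` column, tagged
#'   STPD, `n >= 13`.
#' @param init Optional [composite_coefficients()] whose `h_rate` is added
#'   to the profile candidates (e.g. the published set), or
#'   `"from_submodels"` (the default; profiling makes an explicit coefficient
#'   start unnecessary, so this simply includes the published height rate).
#' @param h_rate_bracket Interval profiled for the height rate, per cm
#'   (default `c(-0.06, 0.06)`).
#' @param grid_points Coarse grid size (default 41).
#' @param rel_tol Convergence criterion: relative reduction of the profiled
#'   RSS between refinement iterations (default `1e-8`).
#' @return A `composite_fit`: `coefficients` ([composite_coefficients()],
#'   provenance `"refit"`), `rss`, `r2`, `adjusted_r2`, `n`,
#'   `k_predictors` (6), `n_params` (12), `converged`, `iterations` (RSS
#'   evaluations) and `h_rate`.
#' @export
#' @examples
#' fit <- fit_composite(table1_cohort())
#' c(fit$rss, fit$r2)  # ~0.673, ~0.814
fit_composite <- function(cohort, init = "from_submodels",
                          h_rate_bracket = c(-0.06, 0.06),
                          grid_points = 41, rel_tol = 1e-8) {
  df <- as.data.frame(cohort)
  if (is.null(df$vo2vent_measured) || anyNA(df$vo2vent_measured)) {
    vc_stop("schema_error", "cohort must have complete vo2vent_measured")
  }
  if (inherits(cohort, "cohort_table") && volume_condition(cohort) != "STPD") {
    vc_stop("units_error", "cohort must be STPD before fitting; see convert_cohort()")
  }
  n <- nrow(df)
  if (n < 13) vc_stop("insufficient_data", "need n >= 13, got ", n)
  y <- df$vo2vent_measured

  evals <- 0L
  rss_at <- function(h) {
    evals <<- evals + 1L
    .composite_rss_at(df, y, h)
  }
  grid <- seq(h_rate_bracket[1], h_rate_bracket[2], length.out = grid_points)
  if (inherits(init, "composite_coefficients")) {
    grid <- sort(unique(c(grid, init$h_rate)))
  } else {
    grid <- sort(unique(c(grid, 0.00006302)))
  }
  rs <- vapply(grid, rss_at, 0)
  i <- which.min(rs)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  # golden-section refinement with the relative-RSS convergence criterion
  opt <- stats::optimize(rss_at, c(lo, hi), tol = .Machine$double.eps^0.5)
  h_rate <- opt$minimum
  rss <- opt$objective
  # converged when one further local refinement pass cannot reduce the
  # profiled RSS by more than rel_tol relative
  opt2 <- stats::optimize(rss_at, c(h_rate - 1e-6, h_rate + 1e-6),
                          tol = .Machine$double.eps^0.5)
  converged <- (rss - opt2$objective) <= rel_tol * max(rss, .Machine$double.eps)
  if (opt2$objective < rss) {
    h_rate <- opt2$minimum
    rss <- opt2$objective
  }

  X <- .composite_design(df, h_rate)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) vc_stop("singular_fit", "rank-deficient composite design")
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - rss / sst  # no variance to explain
  k <- 6L
  coeffs <- composite_coefficients(
    c(beta[["intercept"]], 0, 0, 0, 0),
    beta[["ve1"]], beta[["ve2"]], beta[["ve3"]],
    beta[["w1"]], beta[["w2"]], beta[["w3"]],
    beta[["h_scale"]], h_rate,
    beta[["age1"]], beta[["vp1"]], beta[["hr1"]],
    provenance = "refit")
  structure(list(coefficients = coeffs, rss = rss, r2 = r2,
                 adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - k - 1),
                 n = n, k_predictors = k, n_params = 12L,
                 converged = converged, iterations = evals,
                 h_rate = h_rate, fitted = fitted, observed = y,
                 subject_id = df$subject_id),
            class = "composite_fit")
}

#' @export
print.composite_fit <- function(x, ...) {
  cat(sprintf(paste0("Composite fit: n = %d, RSS = %.4g, R2 = %.4f, ",
                     "adj R2 = %.4f\n  height rate %.5g, %s after %d RSS ",
                     "evaluations\n"),
              x$n, x$rss, x$r2, x$adjusted_r2, x$h_rate,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Goodness of fit of predictions against observations
#'
#' Residual sum of squares, R², adjusted R² and the model F statistic. The F
#' statistic is reported under both degrees-of-freedom conventions: counting
#' the six predictors (`f_predictors`, df `(k, n - k - 1)`) and counting the
#' raw parameter total of the published expression (`f_params`, df
#' `(n_params, n - n_params)`).
#'
#' @param observed,predicted Equal-length numeric vectors,
#'   `length >= k_predictors + 2`.
#' @param k_predictors Number of predictors (default 6).
#' @param n_params Raw parameter count of the printed expression (default 16).
#' @return A list: `rss`, `r2`, `adjusted_r2`, `f_predictors`, `f_params`,
#'   each F with its `df`.
#' @export
goodness_of_fit <- function(observed, predicted, k_predictors = 6,
                            n_params = 16) {
  n <- length(observed)
  if (length(predicted) != n) vc_stop("shape_error", "length mismatch")
  if (n < k_predictors + 2) {
    vc_stop("insufficient_data", "need at least k_predictors + 2 observations")
  }
  rss <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) vc_stop("undefined_r2", "observed values are constant")
  r2 <- 1 - rss / sst
  fstat <- function(df1, df2) {
    if (df2 <= 0 || rss == 0) return(list(value = Inf, df = c(df1, df2)))
    list(value = ((sst - rss) / df1) / (rss / df2), df = c(df1, df2))
  }
  list(rss = rss, r2 = r2,
       adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - k_predictors - 1),
       f_predictors = fstat(k_predictors, n - k_predictors - 1),
       f_params = fstat(n_params, n - n_params))
}
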