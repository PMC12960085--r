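#' Single-predictor sub-model forms
#'
#' Each of the six predictors of peak VO2vent has its own best functional
#' form: a cubic polynomial for VE and weight, a simple linear regression for
#' age, VO2 peak and HRmax, and an exponential-growth curve
#' `a * exp(k * height)` for height.
#'
#' @format A character vector of the six form names.
#' @export
submodel_forms <- c("ve_cubic", "age_linear", "height_expgrowth",
                    "weight_cubic", "vo2peak_linear", "hrmax_linear")

.form_kind <- function(form) {
  switch(form,
         ve_cubic = , weight_cubic = "cubic",
         age_linear = , vo2peak_linear = , hrmax_linear = "linear",
         height_expgrowth = "expgrowth",
         vc_stop("domain_error", "unknown sub-model form: ", form))
}

.form_predictor <- c(ve_cubic = "ve_peak", age_linear = "age",
                     height_expgrowth = "height", weight_cubic = "weight",
                     vo2peak_linear = "vo2peak", hrmax_linear = "hr_max")

.n_par <- function(kind) switch(kind, cubic = 4L, linear = 2L, expgrowth = 2L)

.new_submodel_fit <- function(form, coefficients, rss, n, x_range) {
  p <- .n_par(.form_kind(form))
  structure(list(form = form,
                 coefficients = coefficients,
                 residual_sum_squares = rss,
                 standard_error_of_estimate =
                   if (!is.na(n) && n > p) sqrt(rss / (n - p)) else NA_real_,
                 n = n, x_range = x_range),
            class = "submodel_fit")
}

#' @export
print.submodel_fit <- function(x, ...) {
  cat(sprintf("Sub-model '%s': coefficients %s\n  RSS %.5g, SEE %.4g (n = %d)\n",
              x$form, paste(signif(x$coefficients, 6), collapse = ", "),
              x$residual_sum_squares, x$standard_error_of_estimate, x$n))
  invisible(x)
}

# raw-power cubic OLS through a centered/scaled basis for conditioning;
# coefficients are reported in the raw basis (intercept, x, x^2, x^3)
.fit_cubic <- function(x, y) {
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) vc_stop("singular_fit", "constant predictor: cubic fit is rank-deficient")
  z <- (x - m) / s
  X <- cbind(1, z, z^2, z^3)
  f <- stats::lm.fit(X, y)
  if (f$rank < 4) vc_stop("singular_fit", "rank-deficient cubic design")
  b <- f$coefficients
  # expand sum b_k ((x-m)/s)^k into raw powers of x
  raw <- numeric(4)
  for (k in 0:3) {
    ck <- b[k + 1] / s^k
    for (j in 0:k) {
      raw[j + 1] <- raw[j + 1] + ck * choose(k, j) * (-m)^(k - j)
    }
  }
  list(coef = raw, rss = sum(f$residuals^2))
}

.fit_linear <- function(x, y) {
  if (stats::sd(x) == 0) vc_stop("singular_fit", "constant predictor")
  X <- cbind(1, x)
  f <- stats::lm.fit(X, y)
  list(coef = unname(f$coefficients), rss = sum(f$residuals^2))
}

# a * exp(k * x): log-linear initialisation plus the published height pair as
# a second start; Gauss-Newton refinement, best RSS wins
.fit_expgrowth <- function(x, y) {
  starts <- list(c(0.08766, 0.01293))
  if (all(y > 0)) {
    ll <- stats::lm.fit(cbind(1, x), log(y))$coefficients
    starts <- c(starts, list(c(exp(ll[1]), ll[2])))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::nls(y ~ a * exp(k * x), start = list(a = s[1], k = s[2]),
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(coef = unname(coef(fit)), rss = rss)
    }
  }
  if (is.null(best)) vc_stop("singular_fit", "exponential-growth fit failed from all starts")
  best
}

#' Fit a single-predictor sub-model
#'
#' Least-squares fit of one of the six sub-model forms. Linear and cubic
#' forms are solved exactly by ordinary least squares (the cubic through a
#' centered/scaled basis for numerical conditioning, with coefficients
#' reported in the raw power basis); the exponential-growth form is fitted by
#' Gauss-Newton from a log-linear start and from the published height
#' coefficients, keeping the lower-RSS solution.
#'
#' @param x Predictor values.
#' @param y Peak VO2vent values (L·min⁻¹), same length as `x`.
#' @param form One of [submodel_forms].
#' @return A `submodel_fit`: form, coefficients (intercept first), residual
#'   sum of squares and the standard error of estimate `sqrt(RSS / (n - p))`.
#' @export
#' @examples
#' t1 <- table1_cohort()
#' fit_submodel(t1$age, t1$vo2vent_measured, "age_linear")
fit_submodel <- function(x, y, form) {
  form <- match.arg(form, submodel_forms)
  kind <- .form_kind(form)
  p <- .n_par(kind)
  if (length(x) != length(y)) vc_stop("shape_error", "x and y lengths differ")
  if (length(x) < p + 1) {
    vc_stop("insufficient_data", "need at least ", p + 1, " observations")
  }
  res <- switch(kind,
                cubic = .fit_cubic(x, y),
                linear = .fit_linear(x, y),
                expgrowth = .fit_expgrowth(x, y))
  .new_submodel_fit(form, res$coef, res$rss, length(x), range(x))
}

#' Evaluate a sub-model at new predictor values
#'
#' Evaluates the fitted functional form. Values outside the extrapolation
#' guard (the training-data range, or the derivation-table range for the
#' published sets) trigger a warning, never an error.
#'
#' @param fit A `submodel_fit` from [fit_submodel()] or
#'   [published_submodels()].
#' @param x Predictor values.
#' @param guard Warn outside `fit$x_range` (default `TRUE`).
#' @return Predicted VO2vent, L·min⁻¹.
#' @export
evaluate_submodel <- function(fit, x, guard = TRUE) {
  stopifnot(inherits(fit, "submodel_fit"))
  if (guard && !is.null(fit$x_range) &&
      any(x < fit$x_range[1] | x > fit$x_range[2])) {
    vc_warn("extrapolation", "predictor value(s) outside the fitted range [",
            format(fit$x_range[1]), ", ", format(fit$x_range[2]), "]")
  }
  b <- unname(fit$coefficients)
  switch(.form_kind(fit$form),
         linear = b[1] + b[2] * x,
         cubic = b[1] + b[2] * x + b[3] * x^2 + b[4] * x^3,
         expgrowth = b[1] * exp(b[2] * x))
}

#' @export
predict.submodel_fit <- function(object, newdata, ...) {
  evaluate_submodel(object, newdata, ...)
}

#' The six published sub-model coefficient sets
#'
#' Returns the printed coefficients of the six single-predictor
#' relationships against peak VO2vent, exactly as published. Extrapolation
#' guards are set to the predictor ranges of the packaged derivation table.
#' Note that the stand-alone height exponential uses its own rate constant
#' (0.01293 per cm), distinct from the height rate inside the composite
#' model.
#'
#' @return A named list of six `submodel_fit` objects (RSS and SEE are `NA`:
#'   the printed source reports coefficients only).
#' @export
#' @examples
#' published_submodels()$age_linear$coefficients  # 0.5916, 0.009138
published_submodels <- function() {
  path <- system.file("extdata", "published_submodels.json",
                      package = "ventcost", mustWork = TRUE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  t1 <- table1_cohort()
  out <- lapply(names(doc), function(form) {
    co <- doc[[form]]$coefficients
    names(co) <- doc[[form]]$names
    f <- .new_submodel_fit(form, co, NA_real_, 42L,
                           range(t1[[.form_predictor[[form]]]]))
    f$residual_sum_squares <- NA_real_
    f$standard_error_of_estimate <- NA_real_
    f
  })
  names(out) <- names(doc)
  out
}

#' Read or write sub-model coefficient sets as JSON
#'
#' @param fits Named list of `submodel_fit` objects.
#' @param path JSON file path.
#' @return `read_submodels()` returns a named list of `submodel_fit`;
#'   `write_submodels()` returns `path` invisibly.
#' @export
write_submodels <- function(fits, path) {
  doc <- lapply(fits, function(f) {
    d <- list(coefficients = unname(f$coefficients))
    if (!is.null(names(f$coefficients))) d$names <- names(f$coefficients)
    d
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_submodels
#' @export
read_submodels <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(doc), function(form) {
    co <- doc[[form]]$coefficients
    nm <- doc[[form]]$names
    if (length(nm) == length(co) && !anyNA(nm)) names(co) <- nm
    .new_submodel_fit(form, co, NA_real_, NA_integer_, NULL)
  })
  names(out) <- names(doc)
  out
}
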