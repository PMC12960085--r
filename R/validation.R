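# internal: profiled composite fit returning just what validation loops need
.fit_profile <- function(df, bracket = c(-0.06, 0.06), grid_points = 41) {
  y <- df$vo2vent_measured
  rss_at <- function(h) .composite_rss_at(df, y, h)
  grid <- sort(unique(c(seq(bracket[1], bracket[2], length.out = grid_points),
                        0.00006302)))
  rs <- vapply(grid, rss_at, 0)
  i <- which.min(rs)
  opt <- stats::optimize(rss_at,
                         c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)]),
                         tol = .Machine$double.eps^0.5)
  h <- opt$minimum
  X <- .composite_design(df, h)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) vc_stop("singular_fit", "rank-deficient design in fold")
  list(h_rate = h, beta = qr.coef(qrX, y))
}

.predict_profile <- function(fit, df) {
  drop(.composite_design(df, fit$h_rate) %*% fit$beta)
}

.loocv_metrics <- function(observed, predicted, k = 6L) {
  n <- length(observed)
  rss <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  r2 <- 1 - rss / sst
  list(rmse = sqrt(mean((observed - predicted)^2)),
       mae = mean(abs(observed - predicted)),
       r2 = r2,
       adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - k - 1))
}

#' Leave-one-out cross-validation of the composite model
#'
#' Each subject is held out in turn; the composite model is refitted by
#' profiled least squares ([fit_composite()]) on the remaining `n - 1`
#' subjects and the held-out subject is predicted. Metrics (RMSE, MAE, R²,
#' adjusted R² with `k = 6` predictors at the full `n`) and the calibration
#' pair are computed on the pooled held-out predictions. The report also
#' carries the *apparent* (in-sample) metrics of the full-cohort refit,
#' whose RMSE equals `sqrt(RSS/n)` and whose calibration slope equals R² by
#' the OLS identity.
#'
#' @param cohort A [cohort_table()] with measured VO2vent, `n >= 14`.
#' @param h_rate_bracket,grid_points Profile settings, as in
#'   [fit_composite()].
#' @return A `validation_report`: `per_fold_predictions` (subject_id,
#'   observed, predicted), `rmse`, `mae`, `r2`, `adjusted_r2`,
#'   `calibration_slope`, `calibration_intercept`, `n_folds_converged`, and
#'   an `apparent` list with the in-sample counterparts.
#' @export
#' @examples
#' \donttest{
#' rep <- loocv(table1_cohort())
#' c(rep$rmse, rep$apparent$rmse)
#' }
loocv <- function(cohort, h_rate_bracket = c(-0.06, 0.06), grid_points = 41) {
  df <- as.data.frame(cohort)
  n <- nrow(df)
  if (n < 14) vc_stop("insufficient_data", "need n >= 14 for LOOCV, got ", n)
  if (is.null(df$vo2vent_measured) || anyNA(df$vo2vent_measured)) {
    vc_stop("schema_error", "cohort must have complete vo2vent_measured")
  }
  pred <- rep(NA_real_, n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    f <- tryCatch(.fit_profile(df[-i, , drop = FALSE],
                               h_rate_bracket, grid_points),
                  error = function(e) NULL)
    if (!is.null(f)) {
      pred[i] <- .predict_profile(f, df[i, , drop = FALSE])
      ok[i] <- TRUE
    }
  }
  if (mean(!ok) > 0.10) {
    vc_stop("validation_error", sum(!ok), " of ", n, " LOOCV folds failed")
  }
  obs <- df$vo2vent_measured[ok]
  prd <- pred[ok]
  met <- .loocv_metrics(obs, prd)
  cal <- calibration(obs, prd)

  full <- fit_composite(cohort, h_rate_bracket = h_rate_bracket,
                        grid_points = grid_points)
  amet <- .loocv_metrics(full$observed, full$fitted)
  acal <- calibration(full$observed, full$fitted)

  structure(list(per_fold_predictions = data.frame(
                   subject_id = df$subject_id[ok],
                   observed = obs, predicted = prd),
                 rmse = met$rmse, mae = met$mae, r2 = met$r2,
                 adjusted_r2 = met$adjusted_r2,
                 calibration_slope = cal$slope,
                 calibration_intercept = cal$intercept,
                 n_folds_converged = sum(ok),
                 apparent = c(amet, list(calibration_slope = acal$slope,
                                         calibration_intercept = acal$intercept,
                                         rss = full$rss)),
                 n = n),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0("LOOCV over %d subjects (%d folds converged)\n",
                     "  held-out:  RMSE %.4f, MAE %.4f, R2 %.3f, adj R2 %.3f, ",
                     "calibration %.3f / %.3f\n",
                     "  in-sample: RMSE %.4f, MAE %.4f, R2 %.3f, adj R2 %.3f, ",
                     "calibration %.3f / %.3f\n"),
              x$n, x$n_folds_converged,
              x$rmse, x$mae, x$r2, x$adjusted_r2,
              x$calibration_slope, x$calibration_intercept,
              x$apparent$rmse, x$apparent$mae, x$apparent$r2,
              x$apparent$adjusted_r2, x$apparent$calibration_slope,
              x$apparent$calibration_intercept))
  invisible(x)
}

#' Calibration regression of predicted on observed values
#'
#' Ordinary least squares of the predicted values (response) on the observed
#' values (regressor). Slope 1 and intercept 0 indicate perfect calibration.
#' For in-sample OLS fitted values the slope equals R² and the intercept
#' equals `(1 - R²) * mean(observed)`.
#'
#' @param observed,predicted Equal-length numeric vectors, at least 3 pairs,
#'   `observed` not constant.
#' @return A list with `slope` and `intercept`.
#' @export
calibration <- function(observed, predicted) {
  if (length(observed) != length(predicted)) vc_stop("shape_error", "length mismatch")
  if (length(observed) < 3) vc_stop("insufficient_data", "need at least 3 pairs")
  if (stats::sd(observed) == 0) {
    vc_stop("undefined_slope", "observed values are constant")
  }
  b <- stats::lm.fit(cbind(1, observed), predicted)$coefficients
  list(slope = unname(b[2]), intercept = unname(b[1]))
}

#' Bootstrap resampling of the LOOCV validation pipeline
#'
#' For each iteration the cohort is resampled with replacement to its
#' original size and the validation pipeline is rerun on the resample:
#' the composite model is refitted (apparent metrics, including the
#' adjusted R² the headline estimate corresponds to) and a within-resample
#' LOOCV is run in which all duplicates of a held-out subject leave the
#' training fold together (no leakage). Percentile 95% confidence intervals
#' are reported for every metric and for each identifiable refit
#' coefficient. Fully reproducible for a given `seed`.
#'
#' @param cohort A [cohort_table()] with measured VO2vent, `n >= 14`.
#' @param n_iterations Number of bootstrap iterations, `>= 100`
#'   (default 500).
#' @param seed Integer seed (recorded in the report).
#' @param grid_points Profile grid size for the inner fits (default 41).
#' @return A `bootstrap_report`: `n_iterations`, `seed`, `metric_cis`
#'   (percentile 95% intervals for apparent r2 / adjusted r2 / rmse / mae
#'   and LOOCV rmse / mae / r2), `coefficient_cis`, `raw_distributions`
#'   (matrix of per-iteration metrics and coefficients) and `n_failed`.
#' @export
bootstrap_validation <- function(cohort, n_iterations = 500, seed,
                                 grid_points = 41) {
  df <- as.data.frame(cohort)
  n <- nrow(df)
  if (n < 14) vc_stop("insufficient_data", "need n >= 14, got ", n)
  if (n_iterations < 100) vc_stop("domain_error", "need n_iterations >= 100")
  if (missing(seed)) vc_stop("domain_error", "a seed is required for reproducibility")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  metric_names <- c("apparent_r2", "apparent_adjusted_r2", "apparent_rmse",
                    "apparent_mae", "loocv_rmse", "loocv_mae", "loocv_r2")
  coef_names <- c("intercept", "ve1", "ve2", "ve3", "w1", "w2", "w3",
                  "h_scale", "h_rate", "age1", "vp1", "hr1")
  M <- matrix(NA_real_, n_iterations, length(metric_names) + length(coef_names),
              dimnames = list(NULL, c(metric_names, coef_names)))
  failed <- 0L
  for (b in seq_len(n_iterations)) {
    idx <- sample.int(n, n, replace = TRUE)
    db <- df[idx, , drop = FALSE]
    res <- tryCatch({
      y <- db$vo2vent_measured
      f <- .fit_profile(db, grid_points = grid_points)
      fitted <- .predict_profile(f, db)
      am <- .loocv_metrics(y, fitted)
      # within-resample LOOCV: duplicates of a subject are held out together
      pr <- rep(NA_real_, n)
      for (s in unique(db$subject_id)) {
        hold <- db$subject_id == s
        fs <- .fit_profile(db[!hold, , drop = FALSE], grid_points = grid_points)
        pr[hold] <- .predict_profile(fs, db[hold, , drop = FALSE])
      }
      lm_ <- .loocv_metrics(y, pr)
      c(am$r2, am$adjusted_r2, am$rmse, am$mae,
        lm_$rmse, lm_$mae, lm_$r2,
        f$beta[["intercept"]], f$beta[["ve1"]], f$beta[["ve2"]],
        f$beta[["ve3"]], f$beta[["w1"]], f$beta[["w2"]], f$beta[["w3"]],
        f$beta[["h_scale"]], f$h_rate, f$beta[["age1"]], f$beta[["vp1"]],
        f$beta[["hr1"]])
    }, error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else M[b, ] <- res
  }
  if (failed == n_iterations) vc_stop("bootstrap_error", "all iterations failed")
  ci <- function(col) unname(stats::quantile(M[, col], c(0.025, 0.975),
                                             na.rm = TRUE, names = FALSE))
  structure(list(n_iterations = n_iterations, seed = seed,
                 metric_cis = lapply(stats::setNames(metric_names, metric_names), ci),
                 coefficient_cis = lapply(stats::setNames(coef_names, coef_names), ci),
                 raw_distributions = M,
                 n_failed = failed),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("Bootstrap validation: %d iterations (%d failed), seed %d\n",
              x$n_iterations, x$n_failed, x$seed))
  for (m in names(x$metric_cis)) {
    cat(sprintf("  %-22s 95%% CI (%.3f, %.3f)\n", m,
                x$metric_cis[[m]][1], x$metric_cis[[m]][2]))
  }
  invisible(x)
}

#' Collinearity screening of the six predictors
#'
#' Pairwise Pearson correlations among the six predictors and the variance
#' inflation factor of each: `VIF_i = 1 / (1 - R2_i)` where `R2_i` is from
#' the OLS regression of predictor `i` on the other five.
#'
#' @param cohort A [cohort_table()], `n >= 8`, no constant predictor.
#' @return A `collinearity_report`: `pearson_matrix` (6×6, unit diagonal)
#'   and `vif` (named, all `>= 1`).
#' @export
#' @examples
#' collinearity(table1_cohort())$pearson_matrix["vo2peak", "height"]  # ~0.761
collinearity <- function(cohort) {
  df <- as.data.frame(cohort)[.predictor_fields]
  if (nrow(df) < 8) vc_stop("insufficient_data", "need n >= 8")
  sds <- vapply(df, stats::sd, 0)
  if (any(sds == 0)) {
    vc_stop("degenerate_predictor", "constant predictor(s): ",
            paste(names(sds)[sds == 0], collapse = ", "))
  }
  P <- stats::cor(df)
  vif <- vapply(seq_along(df), function(i) {
    X <- cbind(1, as.matrix(df[, -i]))
    r <- stats::lm.fit(X, df[[i]])$residuals
    sst <- sum((df[[i]] - mean(df[[i]]))^2)
    r2 <- 1 - sum(r^2) / sst
    if (r2 > 1 - 1e-10) {
      vc_stop("degenerate_predictor", "predictor '", names(df)[i],
              "' is perfectly explained by the others (VIF -> Inf)")
    }
    1 / (1 - r2)
  }, 0)
  names(vif) <- names(df)
  structure(list(pearson_matrix = P, vif = vif),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("Pairwise Pearson correlations:\n")
  print(round(x$pearson_matrix, 3))
  cat("Variance inflation factors:\n")
  print(round(x$vif, 2))
  invisible(x)
}

#' Residuals-versus-predicted diagnostics
#'
#' Residuals (observed − predicted) of a validation report, with an OLS
#' trend of the residuals on the predicted values as a check for systematic
#' deviation across the prediction range.
#'
#' @param report A `validation_report` from [loocv()].
#' @return A list: `table` (subject_id, predicted, residual), `trend_slope`,
#'   `trend_se`, `trend_p` (two-sided t test of zero slope).
#' @export
residual_diagnostics <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  d <- report$per_fold_predictions
  resid <- d$observed - d$predicted
  tab <- data.frame(subject_id = d$subject_id, predicted = d$predicted,
                    residual = resid)
  if (stats::sd(d$predicted) == 0 || all(resid == 0)) {
    return(list(table = tab,
                trend_slope = 0, trend_se = NA_real_, trend_p = NA_real_))
  }
  f <- stats::lm(resid ~ d$predicted)
  s <- summary(f)$coefficients
  list(table = tab, trend_slope = unname(s[2, 1]),
       trend_se = unname(s[2, 2]), trend_p = unname(s[2, 4]))
}
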