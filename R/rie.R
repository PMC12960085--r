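#' Breath-by-breath ramp-incremental exercise series
#'
#' One subject's ramp test: breath-wise time, power, oxygen uptake and
#' expired ventilation, optionally breathing frequency and tidal volume.
#' When `fr` and `vt` are both present, `ve` must agree with `fr * vt`
#' within 10% at every sample.
#'
#' @param time Breath times, s, strictly increasing.
#' @param power Power output, W, `>= 0`.
#' @param vo2 Oxygen uptake, L·min⁻¹, `> 0`.
#' @param ve Expired ventilation, L·min⁻¹, `> 0`.
#' @param fr Optional breathing frequency, breaths·min⁻¹.
#' @param vt Optional tidal volume, L.
#' @param volume_condition Volume condition of `ve` (`"STPD"` or `"BTPS"`).
#' @param averaging_width Breaths per sample (1 = raw breaths).
#' @return An object of class `rie_series` (a data frame).
#' @export
rie_series <- function(time, power, vo2, ve, fr = NULL, vt = NULL,
                       volume_condition = c("STPD", "BTPS"),
                       averaging_width = 1L) {
  volume_condition <- match.arg(volume_condition)
  n <- length(time)
  lens <- c(length(power), length(vo2), length(ve),
            if (!is.null(fr)) length(fr), if (!is.null(vt)) length(vt))
  if (any(lens != n)) vc_stop("shape_error", "channel lengths differ")
  if (n < 2 || any(diff(time) <= 0)) {
    vc_stop("domain_error", "time must be strictly increasing with >= 2 samples")
  }
  if (any(power < 0)) vc_stop("domain_error", "power must be >= 0")
  if (any(vo2 <= 0) || any(ve <= 0)) {
    vc_stop("domain_error", "vo2 and ve must be positive")
  }
  if (!is.null(fr) && !is.null(vt)) {
    rel <- abs(ve - fr * vt) / ve
    if (any(rel > 0.10)) {
      vc_stop("domain_error", "ve and fr*vt disagree by more than 10% at ",
              sum(rel > 0.10), " sample(s)")
    }
  }
  df <- data.frame(time = time, power = power, vo2 = vo2, ve = ve)
  if (!is.null(fr)) df$fr <- fr
  if (!is.null(vt)) df$vt <- vt
  structure(df, volume_condition = volume_condition,
            averaging_width = as.integer(averaging_width),
            class = c("rie_series", "data.frame"))
}

#' @export
print.rie_series <- function(x, ...) {
  cat(sprintf(paste0("Ramp-test series: %d samples over %.1f s, peak power ",
                     "%.0f W, VE %s (averaging width %d)\n"),
              nrow(x), max(x$time) - min(x$time), max(x$power),
              attr(x, "volume_condition"), attr(x, "averaging_width")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read or write a breath-by-breath series
#'
#' Delimited text with headers `time_s`, `power_w`, `vo2_lmin`, `ve_lmin`
#' and optionally `fr_bpm`, `vt_l`.
#'
#' @param path File path.
#' @param volume_condition Volume condition of the `ve` column.
#' @param series An [rie_series()].
#' @return `read_rie()` returns an [rie_series()]; `write_rie()` returns
#'   `path` invisibly.
#' @export
read_rie <- function(path, volume_condition = "STPD") {
  if (!file.exists(path)) vc_stop("schema_error", "file not found: ", path)
  d <- utils::read.csv(path)
  need <- c("time_s", "power_w", "vo2_lmin", "ve_lmin")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    vc_stop("schema_error", "missing column(s): ", paste(miss, collapse = ", "))
  }
  rie_series(d$time_s, d$power_w, d$vo2_lmin, d$ve_lmin,
             fr = d$fr_bpm, vt = d$vt_l, volume_condition = volume_condition)
}

#' @rdname read_rie
#' @export
write_rie <- function(series, path) {
  d <- as.data.frame(series)
  out <- data.frame(time_s = d$time, power_w = d$power,
                    vo2_lmin = d$vo2, ve_lmin = d$ve)
  if (!is.null(d$fr)) out$fr_bpm <- d$fr
  if (!is.null(d$vt)) out$vt_l <- d$vt
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average a breath series over fixed-width blocks
#'
#' Non-overlapping block means of `width` breaths for every channel (block
#' time is the mean breath time); a trailing partial block is dropped.
#' Seven-breath averaging is the conventional smoothing for ramp-test gas
#' exchange.
#'
#' @param raw An [rie_series()].
#' @param width Breaths per block, `>= 1` (default 7).
#' @return An [rie_series()] with `averaging_width = width`.
#' @export
average_breaths <- function(raw, width = 7L) {
  stopifnot(inherits(raw, "rie_series"))
  width <- as.integer(width)
  if (width < 1L) vc_stop("domain_error", "width must be >= 1")
  if (width == 1L) return(raw)
  d <- as.data.frame(raw)
  n_blocks <- nrow(d) %/% width
  if (n_blocks < 1L) {
    vc_stop("insufficient_data", "fewer breaths (", nrow(d),
            ") than averaging width (", width, ")")
  }
  g <- rep(seq_len(n_blocks), each = width)
  d <- d[seq_along(g), , drop = FALSE]
  agg <- lapply(d, function(ch) as.numeric(tapply(ch, g, mean)))
  rie_series(agg$time, agg$power, agg$vo2, agg$ve, fr = agg$fr, vt = agg$vt,
             volume_condition = attr(raw, "volume_condition"),
             averaging_width = width)
}

#' Predict the VO2vent trajectory of a ramp test
#'
#' Evaluates the composite model breath-by-breath, sliding the instantaneous
#' VE through the VE terms while all other predictors stay fixed at the
#' subject's values (VE is the only predictor that varies within a test).
#' Predictions are clamped at zero. Two alternative modes are provided:
#' `"peak_anchored"` scales the subject's peak prediction by
#' `VE(t) / VE_peak`, and `rest_offset = TRUE` subtracts the prediction at
#' the first (pre-ramp baseline) sample's VE.
#'
#' @param coeffs A [composite_coefficients()].
#' @param series An [rie_series()], `ve` tagged STPD (convert first
#'   otherwise).
#' @param subject One participant row (a [cohort_table()] row or data frame
#'   with the six predictor columns).
#' @param mode `"instantaneous"` (default) or `"peak_anchored"`.
#' @param rest_offset Subtract the baseline-VE prediction (default `FALSE`).
#' @return Numeric VO2vent trajectory, L·min⁻¹, one value per sample.
#' @export
predict_vent_series <- function(coeffs, series, subject,
                                mode = c("instantaneous", "peak_anchored"),
                                rest_offset = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(coeffs, "composite_coefficients"),
            inherits(series, "rie_series"))
  if (attr(series, "volume_condition") != "STPD") {
    vc_stop("units_error",
            "series VE is BTPS; convert with btps_to_stpd() first")
  }
  s <- as.data.frame(subject)
  if (nrow(s) != 1) vc_stop("shape_error", "subject must be a single row")
  ve <- series$ve
  pred_at <- function(v) {
    .eval_composite_raw(coeffs, v, s$weight, s$height, s$age, s$vo2peak,
                        s$hr_max)
  }
  vent <- switch(mode,
                 instantaneous = pred_at(ve),
                 peak_anchored = pred_at(s$ve_peak) * ve / s$ve_peak)
  if (rest_offset) vent <- vent - pred_at(ve[1])
  if (any(vent < 0)) {
    vc_warn("negative_prediction", sum(vent < 0),
            " negative VO2vent value(s) clamped to 0")
  }
  pmax(vent, 0)
}

#' Subtract a VO2vent trajectory from measured VO2
#'
#' Computes the ventilation-corrected oxygen uptake
#' `vo2vcorr = vo2 - vo2vent` sample-by-sample. Negative corrected values
#' are permitted but flagged with a warning.
#'
#' @param series An [rie_series()].
#' @param vent VO2vent trajectory from [predict_vent_series()], same length.
#' @return A `correction_result`: the per-sample table (`time`, `power`,
#'   `vo2`, `vo2vent`, `vo2vcorr`), `wpeak` (W) and `percent_vent_at_max`
#'   (VO2vent as a percentage of VO2 at the peak-power sample).
#' @export
correct_series <- function(series, vent) {
  stopifnot(inherits(series, "rie_series"))
  d <- as.data.frame(series)
  if (length(vent) != nrow(d)) vc_stop("shape_error", "length mismatch")
  vcorr <- d$vo2 - vent
  if (any(vcorr < 0)) {
    vc_warn("negative_vcorr", sum(vcorr < 0),
            " negative VO2vcorr sample(s); VO2vent exceeds measured VO2 there")
  }
  i_pk <- which.max(d$power)
  # re-derive the stored VO2vent from the stored difference (<= 1 ulp
  # adjustment) so that vo2vcorr == vo2 - vo2vent holds bit-exactly
  vent_adj <- d$vo2 - vcorr
  structure(list(samples = data.frame(time = d$time, power = d$power,
                                      vo2 = d$vo2, vo2vent = vent_adj,
                                      vo2vcorr = vcorr),
                 wpeak = d$power[i_pk],
                 percent_vent_at_max = percent_of_max(vent[i_pk], d$vo2[i_pk])),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf(paste0("Ventilation-corrected ramp test: Wpeak %.0f W, ",
                     "VO2vent at peak = %.1f%% of VO2\n"),
              x$wpeak, x$percent_vent_at_max))
  print(utils::head(x$samples))
  if (nrow(x$samples) > 6) cat("...\n")
  invisible(x)
}

#' Channel values at fractions of peak power
#'
#' Peak power (`Wpeak`) is the maximal power in the series; for each
#' requested fraction the channels are linearly interpolated *in power* at
#' `fraction * Wpeak`. If power is non-monotone the last crossing is used.
#'
#' @param result A `correction_result` from [correct_series()].
#' @param fractions Fractions of Wpeak in `(0, 1]`
#'   (default `c(0.35, 0.55, 0.75, 0.85, 0.95, 1)`).
#' @return A data frame with one row per fraction: `fraction`, `power`,
#'   `vo2`, `vo2vcorr`, `vo2vent`.
#' @export
intensity_table <- function(result,
                            fractions = c(0.35, 0.55, 0.75, 0.85, 0.95, 1)) {
  stopifnot(inherits(result, "correction_result"))
  if (any(fractions <= 0 | fractions > 1)) {
    vc_stop("domain_error", "fractions must lie in (0, 1]")
  }
  d <- result$samples
  wpeak <- result$wpeak
  i_pk <- which.max(d$power)
  interp_last <- function(channel, target) {
    if (target >= wpeak) return(channel[i_pk])
    if (target < d$power[1]) {
      vc_stop("extrapolation_error", "target power ", format(target),
              " W is below the first sample's power")
    }
    # last crossing: latest index with power <= target followed by > target
    below <- which(d$power[-length(d$power)] <= target &
                     d$power[-1] > target)
    if (!length(below)) {
      i <- max(which(d$power <= target))
      return(channel[i])
    }
    i <- max(below)
    w0 <- d$power[i]; w1 <- d$power[i + 1]
    channel[i] + (channel[i + 1] - channel[i]) * (target - w0) / (w1 - w0)
  }
  out <- do.call(rbind, lapply(fractions, function(f) {
    tgt <- f * wpeak
    data.frame(fraction = f, power = tgt,
               vo2 = interp_last(d$vo2, tgt),
               vo2vcorr = interp_last(d$vo2vcorr, tgt),
               vo2vent = interp_last(d$vo2vent, tgt))
  }))
  rownames(out) <- NULL
  out
}

#' Slope of a channel over the final seconds of a test
#'
#' OLS slope of the channel on time over `[t_end - window, t_end]` (both
#' endpoints inclusive), expressed per minute.
#'
#' @param values Channel values (e.g. VO2, L·min⁻¹).
#' @param time Sample times, s, same length.
#' @param window Window length, s (default 30); at least 3 samples must fall
#'   inside it.
#' @return Slope in channel units per minute.
#' @export
final_slope <- function(values, time, window = 30) {
  if (length(values) != length(time)) vc_stop("shape_error", "length mismatch")
  keep <- time >= (max(time) - window)
  if (sum(keep) < 3) {
    vc_stop("insufficient_data", "fewer than 3 samples in the final ",
            window, " s")
  }
  tmin <- time[keep] / 60
  b <- stats::lm.fit(cbind(1, tmin), values[keep])$coefficients
  unname(b[2])
}

#' Paired t test of two per-subject slope vectors
#'
#' Paired samples t test on the differences, with Cohen's d for paired data
#' (`mean(diff) / sd(diff)`).
#'
#' @param slopes_a,slopes_b Equal-length per-subject values, `n >= 3`.
#' @return A list: `t`, `df`, `p`, `d`, `mean_diff`.
#' @export
paired_slope_test <- function(slopes_a, slopes_b) {
  n <- length(slopes_a)
  if (length(slopes_b) != n) vc_stop("shape_error", "length mismatch")
  if (n < 3) vc_stop("insufficient_data", "need n >= 3 pairs")
  diffs <- slopes_a - slopes_b
  if (stats::sd(diffs) == 0) {
    # identical vectors: no difference at all, t = 0 by convention; a
    # constant non-zero difference has an undefined (infinite) statistic
    if (all(diffs == 0)) {
      return(list(t = 0, df = n - 1, p = 1, d = 0, mean_diff = 0))
    }
    vc_stop("degenerate_test", "zero-variance differences")
  }
  tt <- stats::t.test(slopes_a, slopes_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = mean(diffs) / stats::sd(diffs),
       mean_diff = mean(diffs))
}
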