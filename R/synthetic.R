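#' Simulation parameters for synthetic ramp tests
#'
#' Defines the physiological structure of a simulated ramp-incremental
#' cycle test: a linear power ramp, a mono-exponential (first-order) VO2
#' response to it, expired ventilation linear in VO2 below the gas-exchange
#' threshold (GET) with a smooth exponential excess above it, tidal volume
#' saturating toward `vt_max` while breathing frequency rises to supply VE,
#' breath intervals shortening as frequency rises, and multiplicative
#' Gaussian breath-to-breath noise on VO2 and VE.
#'
#' @param ramp_rate Ramp slope, W·min⁻¹ (default 36).
#' @param baseline_power Power at ramp onset, W (default 50).
#' @param test_duration Ramp duration, s (default 600).
#' @param vo2_baseline VO2 at zero power, L·min⁻¹ (default 0.5).
#' @param vo2_gain Steady-state VO2 per W, L·min⁻¹·W⁻¹ (default 0.010).
#' @param tau Time constant of the first-order VO2 kinetics, s (default 30).
#' @param get_fraction Fraction of the noise-free end-test VO2 at which VE
#'   departs from linearity (default 0.6).
#' @param ve_intercept VE at zero VO2, L·min⁻¹ (default 5).
#' @param ve_slope_below VE per VO2 below GET, L·min⁻¹ per L·min⁻¹
#'   (default 22).
#' @param ve_excess_rate Exponential rate of the above-GET VE excess, per
#'   L·min⁻¹ of VO2 (default 2.2).
#' @param vt_max Tidal-volume plateau, L (default 3.0).
#' @param vt_half VE at which tidal volume reaches half its plateau,
#'   L·min⁻¹ (default 20).
#' @param fr_base Minimum breathing frequency, breaths·min⁻¹ (default 14).
#' @param breath_noise_sd Fractional SD of the multiplicative breath noise
#'   (default 0.05).
#' @param seed Integer seed (default 1).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(ramp_rate = 36, baseline_power = 50,
                       test_duration = 600, vo2_baseline = 0.5,
                       vo2_gain = 0.010, tau = 30, get_fraction = 0.6,
                       ve_intercept = 5, ve_slope_below = 22,
                       ve_excess_rate = 2.2, vt_max = 3.0, vt_half = 20,
                       fr_base = 14, breath_noise_sd = 0.05, seed = 1L) {
  p <- list(ramp_rate = ramp_rate, baseline_power = baseline_power,
            test_duration = test_duration, vo2_baseline = vo2_baseline,
            vo2_gain = vo2_gain, tau = tau, get_fraction = get_fraction,
            ve_intercept = ve_intercept, ve_slope_below = ve_slope_below,
            ve_excess_rate = ve_excess_rate, vt_max = vt_max,
            vt_half = vt_half, fr_base = fr_base,
            breath_noise_sd = breath_noise_sd, seed = as.integer(seed))
  pos <- c("ramp_rate", "baseline_power", "test_duration", "vo2_baseline",
           "vo2_gain", "tau", "ve_intercept", "ve_slope_below",
           "ve_excess_rate", "vt_max", "vt_half", "fr_base")
  if (any(unlist(p[pos]) <= 0)) vc_stop("domain_error", "parameters must be positive")
  if (p$get_fraction <= 0 || p$get_fraction >= 1) {
    vc_stop("domain_error", "get_fraction must lie in (0, 1)")
  }
  if (p$breath_noise_sd < 0) vc_stop("domain_error", "breath_noise_sd must be >= 0")
  structure(p, class = "sim_params")
}

# noise-free channel values at time t (s)
.sim_deterministic <- function(p, t) {
  power <- p$baseline_power + p$ramp_rate * t / 60
  r <- p$vo2_gain * p$ramp_rate / 60  # L.min^-1 per s of ramp
  vo2 <- p$vo2_baseline + p$vo2_gain * p$baseline_power +
    r * (t - p$tau * (1 - exp(-t / p$tau)))
  vo2_end <- p$vo2_baseline + p$vo2_gain * p$baseline_power +
    r * (p$test_duration - p$tau * (1 - exp(-p$test_duration / p$tau)))
  vo2_get <- p$get_fraction * vo2_end
  excess <- ifelse(vo2 > vo2_get,
                   exp(p$ve_excess_rate * (vo2 - vo2_get)) - 1 -
                     p$ve_excess_rate * (vo2 - vo2_get),
                   0)
  ve <- p$ve_intercept + p$ve_slope_below * vo2 + excess
  list(power = power, vo2 = vo2, ve = ve, vo2_get = vo2_get)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

#' Generate one synthetic subject and ramp test
#'
#' Simulates a breath-by-breath ramp-incremental test under `params` and
#' fills a participant record from it: `ve_peak` and `vo2peak` are the
#' maxima of the generated series; age, weight, height, hr_max come from
#' the `anthropometrics` skeleton. Breath times advance by `60 / fr`, so
#' sampling becomes denser as breathing frequency rises; VE equals
#' `fr * vt` exactly at every breath. Fully reproducible for a given
#' `params$seed`.
#'
#' @param params A [sim_params()].
#' @param anthropometrics Optional one-row data frame/list with `subject_id`,
#'   `age`, `weight`, `height`, `hr_max` (defaults: "sim1", 28 y, 72 kg,
#'   178 cm, 185 beats·min⁻¹).
#' @return A list with `record` (one-row data frame of the participant
#'   fields) and `series` (an [rie_series()], STPD).
#' @export
#' @examples
#' sub <- generate_subject(sim_params(seed = 7))
#' sub$record$vo2peak
generate_subject <- function(params = sim_params(), anthropometrics = NULL) {
  stopifnot(inherits(params, "sim_params"))
  a <- c(anthropometrics,
         list(subject_id = "sim1", age = 28, weight = 72, height = 178,
              hr_max = 185))
  a <- a[!duplicated(names(a))]
  .with_seed(params$seed, {
    t <- 0
    rows <- list()
    while (t <= params$test_duration) {
      det <- .sim_deterministic(params, t)
      vo2 <- det$vo2 * (1 + stats::rnorm(1, 0, params$breath_noise_sd))
      ve <- det$ve * (1 + stats::rnorm(1, 0, params$breath_noise_sd))
      vo2 <- max(vo2, 0.05 * det$vo2)
      ve <- max(ve, 0.05 * det$ve)
      vt_des <- params$vt_max * ve / (ve + params$vt_half)
      fr <- max(ve / vt_des, params$fr_base)
      vt <- ve / fr
      rows[[length(rows) + 1L]] <-
        c(time = t, power = det$power, vo2 = vo2, ve = ve, fr = fr, vt = vt)
      t <- t + 60 / fr
    }
    d <- as.data.frame(do.call(rbind, rows))
    series <- rie_series(d$time, d$power, d$vo2, d$ve, fr = d$fr, vt = d$vt,
                         volume_condition = "STPD")
    record <- data.frame(subject_id = a$subject_id, ve_peak = max(d$ve),
                         age = a$age, weight = a$weight, height = a$height,
                         vo2peak = max(d$vo2), hr_max = a$hr_max,
                         vo2vent_measured = NA_real_, sex = "unknown",
                         stringsAsFactors = FALSE)
    list(record = record, series = series)
  })
}

#' Generate a model-true synthetic cohort
#'
#' Draws `n` participants with predictors uniform over the ranges of the
#' packaged derivation table and sets their "measured" VO2vent to the
#' composite-model prediction plus Gaussian noise. Rows whose noisy VO2vent
#' would violate the record invariants (`0 < vo2vent < vo2peak`) are
#' redrawn, so the returned cohort is always valid. Being model-true by
#' construction, these cohorts give downstream validation code a known
#' ground truth.
#'
#' @param n Number of subjects, `>= 14`.
#' @param params Unused placeholder for future series-level coupling;
#'   kept for interface symmetry (default [sim_params()]).
#' @param coeffs Generating [composite_coefficients()]
#'   (default [published_composite()]).
#' @param noise_sd SD of the additive Gaussian noise, L·min⁻¹
#'   (default 0.13, the residual scale of the derivation fit).
#' @param seed Integer seed.
#' @return A [cohort_table()] with `vo2vent_measured`, tagged STPD.
#' @export
#' @examples
#' g <- generate_cohort(42, seed = 11)
#' fit_composite(g)$r2
generate_cohort <- function(n, params = sim_params(),
                            coeffs = published_composite(),
                            noise_sd = 0.13, seed = 1L) {
  if (n < 14) vc_stop("insufficient_data", "need n >= 14, got ", n)
  rngs <- .t1_ranges()
  .with_seed(seed, {
    draw <- function(m) {
      d <- data.frame(subject_id = character(m))
      for (f in .predictor_fields) {
        d[[f]] <- stats::runif(m, rngs[[f]][1], rngs[[f]][2])
      }
      pred <- .eval_composite_raw(coeffs, d$ve_peak, d$weight, d$height,
                                  d$age, d$vo2peak, d$hr_max)
      d$vo2vent_measured <- pred + stats::rnorm(m, 0, noise_sd)
      d
    }
    d <- draw(n)
    for (pass in 1:1000) {
      bad <- d$vo2vent_measured <= 0 | d$vo2vent_measured >= d$vo2peak
      if (!any(bad)) break
      d[bad, ] <- draw(sum(bad))
    }
    if (any(bad)) vc_stop("domain_error", "could not draw a valid cohort")
    d$subject_id <- sprintf("sim%03d", seq_len(n))
    cohort_table(d, volume_condition = "STPD")
  })
}
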