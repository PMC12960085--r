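#' Gas-volume conversion parameters
#'
#' Conditions for converting expired-gas volumes from BTPS (body temperature,
#' ambient pressure, saturated) to STPD (standard temperature and pressure,
#' dry). Defaults are body temperature 37 °C, barometric pressure 635 mmHg
#' (site-specific; the derivation data were collected at altitude) and
#' standard atmospheric pressure 760 mmHg.
#'
#' @param btemp Body temperature, °C (> −273).
#' @param pb Barometric pressure, mmHg (> 0).
#' @param atm Standard atmospheric pressure, mmHg (> 0).
#' @return A list of class `volume_conversion_params`.
#' @export
volume_conversion_params <- function(btemp = 37, pb = 635, atm = 760) {
  if (btemp <= -273) vc_stop("domain_error", "btemp must exceed -273 degC")
  if (pb <= 0 || atm <= 0) vc_stop("domain_error", "pressures must be positive")
  structure(list(btemp = btemp, pb = pb, atm = atm),
            class = "volume_conversion_params")
}

#' Convert a gas volume from BTPS to STPD
#'
#' Multiplies the volume by a temperature ratio and a pressure ratio:
#' `volume * 273 / (273 + btemp) * pb / atm`. The conversion is linear and
#' strictly order-preserving in the volume. By default no saturated
#' water-vapor correction is applied; `vapor_correction = TRUE` substitutes
#' `pb - 47` mmHg (saturation pressure at 37 °C) for `pb`, the textbook dry
#' correction.
#'
#' @param volume Volume (L) or volume rate (L·min⁻¹) at BTPS, `>= 0`.
#'   Vectorised.
#' @param params A [volume_conversion_params()].
#' @param vapor_correction Apply the `pb - 47` water-vapor correction
#'   (default `FALSE`).
#' @return The same quantity at STPD.
#' @export
#' @examples
#' btps_to_stpd(100)  # 73.580 at the default 37 degC, 635/760 mmHg
btps_to_stpd <- function(volume, params = volume_conversion_params(),
                         vapor_correction = FALSE) {
  stopifnot(inherits(params, "volume_conversion_params"))
  if (any(volume < 0)) vc_stop("domain_error", "volume must be >= 0")
  pb <- if (vapor_correction) params$pb - 47 else params$pb
  volume * 273 / (273 + params$btemp) * pb / params$atm
}

#' Convert a cohort's ventilation volumes from BTPS to STPD
#'
#' Applies [btps_to_stpd()] to the `ve_peak` column of a BTPS-tagged cohort
#' and retags it STPD. An already-STPD cohort is returned unchanged.
#'
#' @inheritParams btps_to_stpd
#' @param cohort A [cohort_table()].
#' @return An STPD-tagged [cohort_table()].
#' @export
convert_cohort <- function(cohort, params = volume_conversion_params(),
                           vapor_correction = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (volume_condition(cohort) == "STPD") return(cohort)
  df <- as.data.frame(cohort)
  df$ve_peak <- btps_to_stpd(df$ve_peak, params, vapor_correction)
  cohort_table(df, volume_condition = "STPD")
}
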