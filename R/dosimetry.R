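# Unit-exact irradiance and dose arithmetic.
#
# Lamp outputs are quoted in mW/cm^2 at the sample position; fluences in
# J/m^2 (or kJ/m^2 when large). 1 mW/cm^2 = 10 J/(m^2 s).

#' Convert an irradiance to a dose rate
#'
#' @param irradiance_mw_cm2 Irradiance in mW/cm^2 (>= 0).
#' @return Dose rate in J/(m^2 s); 8.5 mW/cm^2 gives 85 J/(m^2 s).
#' @export
irradiance_to_dose_rate <- function(irradiance_mw_cm2) {
  if (any(irradiance_mw_cm2 < 0)) stop("irradiance must be >= 0")
  10 * irradiance_mw_cm2
}

#' Total dose delivered over an exposure
#'
#' @param dose_rate_j_m2_s Dose rate in J/(m^2 s).
#' @param time_s Exposure time in seconds (>= 0).
#' @return Dose in J/m^2; 65 J/(m^2 s) for 8 s gives 520 J/m^2.
#' @export
total_dose <- function(dose_rate_j_m2_s, time_s) {
  if (any(dose_rate_j_m2_s < 0)) stop("dose rate must be >= 0")
  if (any(time_s < 0)) stop("time must be >= 0")
  dose_rate_j_m2_s * time_s
}

#' Render a dose the way exposure conditions are reported
#'
#' Two significant figures, switching to kJ/m^2 at 1000 J/m^2: 1600 J/m^2
#' renders as "1.6 kJ/m2", 39600 as "40 kJ/m2", 520 as "520 J/m2".
#'
#' @param dose_j_m2 Dose in J/m^2.
#' @return Character string.
#' @export
format_dose <- function(dose_j_m2) {
  vapply(dose_j_m2, function(d) {
    if (d < 0) stop("dose must be >= 0")
    v <- signif(d, 2L)
    if (v >= 1000)
      paste0(format(v / 1000, scientific = FALSE, trim = TRUE), " kJ/m2")
    else
      paste0(format(v, scientific = FALSE, trim = TRUE), " J/m2")
  }, character(1))
}

#' Render a dose rate per second or per minute
#'
#' @param dose_rate_j_m2_s Dose rate in J/(m^2 s).
#' @param per `"s"` (default) or `"min"`; 150 J/(m^2 s) renders as
#'   "9 kJ/m2-min".
#' @return Character string.
#' @export
format_dose_rate <- function(dose_rate_j_m2_s, per = c("s", "min")) {
  per <- match.arg(per)
  mult <- if (per == "min") 60 else 1
  v <- signif(dose_rate_j_m2_s * mult, 2L)
  unit <- if (v >= 1000) { v <- v / 1000; "kJ/m2" } else "J/m2"
  paste0(format(v, scientific = FALSE, trim = TRUE), " ", unit, "-", per)
}
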