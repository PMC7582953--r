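# Small spectroscopic filters and sequence descriptors: amide temperature
# coefficients, H/D exchange half-times, the methanol-d4 thermometer,
# hydrophobicity and charge census.

# Hydrogen-bond evidence thresholds (both exclusive, as printed).
#' @keywords internal
.hbond_temp_coeff_ppb_k <- -4.5
#' @keywords internal
.hbond_hd_halftime_min <- 20

#' Amide proton temperature coefficient
#'
#' Ordinary least-squares slope of the amide 1HN chemical shift against
#' temperature, in ppb/K, from a series of HSQC spectra (typically
#' 20-45 degrees C).  Amides with a coefficient above -4.5 ppb/K
#' (exclusive) are hydrogen-bond candidates; linearity of the series (R^2
#' reported) is itself evidence of the absence of structural transitions
#' over the range.
#'
#' @param temperatures_c Temperatures in degrees C (>= 3 distinct values;
#'   Kelvin increments are identical so the slope is per K either way).
#' @param shifts_ppm 1HN chemical shifts in ppm.
#' @return List of class `temp_coefficient`: `slope_ppb_k`, `slope_err`,
#'   `r_squared`, `hbond_candidate`, `n`.
#' @examples
#' temp_coefficient(c(20, 25, 30, 35, 45), 8.3 - 6e-3 * c(20, 25, 30, 35, 45))
#' @export
temp_coefficient <- function(temperatures_c, shifts_ppm) {
  if (length(temperatures_c) != length(shifts_ppm))
    stop("temperatures and shifts must have equal length")
  if (length(unique(temperatures_c)) < 3L)
    stop("at least 3 distinct temperatures are required")
  fit <- stats::lm(shifts_ppm ~ temperatures_c)
  # exact linear series are a legitimate input; silence the
  # "essentially perfect fit" note
  sm <- suppressWarnings(summary(fit))
  slope <- stats::coef(fit)[[2]] * 1000     # ppm/K -> ppb/K
  err <- sm$coefficients[2, "Std. Error"] * 1000
  structure(list(slope_ppb_k = slope, slope_err = err,
                 r_squared = sm$r.squared,
                 hbond_candidate = slope > .hbond_temp_coeff_ppb_k,
                 n = length(shifts_ppm)),
            class = "temp_coefficient")
}

#' @export
print.temp_coefficient <- function(x, ...) {
  cat(sprintf("ddH/dT = %+.2f +/- %.2f ppb/K (R^2 = %.3f, n = %d)%s\n",
              x$slope_ppb_k, x$slope_err, x$r_squared, x$n,
              if (x$hbond_candidate) "  [H-bond candidate]" else ""))
  invisible(x)
}

#' H/D exchange half-time
#'
#' Monoexponential fit of amide peak intensity versus time after
#' dissolution in D2O; the half-exchange time is `t1/2 = ln(2)/k`.
#' Amides with `t1/2 > 20 min` (exclusive) are slow-exchanging and count
#' as hydrogen-bond candidates.  Non-decaying series are flagged
#' (`decaying = FALSE`) rather than silently returned.
#'
#' @param times_min Time points in minutes (>= 3).
#' @param intensities Positive peak intensities.
#' @return List of class `hd_exchange`: `half_time_min`, `rate_per_min`,
#'   `slow_exchange`, `decaying`, plus the underlying [fit_exponential_decay()].
#' @examples
#' t <- c(2, 5, 10, 20, 40, 80)
#' hd_half_exchange(t, exp(-log(2) * t / 60))
#' @export
hd_half_exchange <- function(times_min, intensities) {
  fit <- fit_exponential_decay(times_min, intensities)
  t_half <- if (fit$decaying) log(2) / fit$rate else Inf
  structure(list(half_time_min = t_half, rate_per_min = fit$rate,
                 slow_exchange = fit$decaying &&
                   t_half > .hbond_hd_halftime_min,
                 decaying = fit$decaying, fit = fit),
            class = "hd_exchange")
}

#' @export
print.hd_exchange <- function(x, ...) {
  cat(sprintf("H/D exchange: t1/2 = %.1f min%s%s\n", x$half_time_min,
              if (x$slow_exchange) "  [slow, H-bond candidate]" else "",
              if (x$decaying) "" else "  [NOT DECAYING]"))
  invisible(x)
}

# Methanol-d4 chemical-shift thermometer (Findeisen-Brand-Berger
# calibration): T/K = 409.0 - 36.54*dd - 21.85*dd^2, dd = CH3-OH 1H shift
# difference in ppm.  Quoted valid over ~181-330 K, i.e. dd in
# [1.241, 2.503] ppm.
#' @keywords internal
.methanol_poly <- c(409.0, -36.54, -21.85)
#' @keywords internal
.methanol_dd_range <- c(1.241, 2.503)

#' Temperature from the methanol-d4 NMR thermometer
#'
#' Converts the 1H chemical-shift difference between the residual methyl
#' and hydroxyl signals of pure methanol-d4 into the sample temperature,
#' using the published quadratic calibration
#' `T/K = 409.0 - 36.54 dd - 21.85 dd^2`.  Monotone decreasing in the
#' shift difference; inputs outside the calibrated range (roughly
#' 181-330 K, `dd` 1.241-2.503 ppm) are rejected.
#'
#' @param delta_ppm CH3-OH shift difference in ppm.
#' @return Temperature in Kelvin, vectorized.
#' @examples
#' methanol_temperature(1.5)
#' @export
methanol_temperature <- function(delta_ppm) {
  if (any(!is.finite(delta_ppm)))
    stop("delta_ppm must be finite")
  if (any(delta_ppm < .methanol_dd_range[1] |
          delta_ppm > .methanol_dd_range[2]))
    stop(sprintf("delta_ppm outside the calibration range [%.3f, %.3f] ppm",
                 .methanol_dd_range[1], .methanol_dd_range[2]))
  p <- .methanol_poly
  p[1] + p[2] * delta_ppm + p[3] * delta_ppm^2
}

#' Shift difference expected at a given temperature (inverse thermometer)
#'
#' Numerical inverse of [methanol_temperature()] on its valid range,
#' mainly for calibration round trips.
#'
#' @param temperature_k Temperature in Kelvin.
#' @return CH3-OH shift difference in ppm.
#' @export
methanol_shift_difference <- function(temperature_k) {
  p <- .methanol_poly
  vapply(temperature_k, function(tk) {
    disc <- p[2]^2 - 4 * p[3] * (p[1] - tk)
    if (disc < 0) stop("temperature outside the calibration range")
    dd <- (-p[2] - sqrt(disc)) / (2 * p[3])
    if (dd < .methanol_dd_range[1] || dd > .methanol_dd_range[2])
      stop("temperature outside the calibration range")
    dd
  }, 1.0)
}

# Kyte-Doolittle hydropathy scale (+4.5 Ile .. -4.5 Arg).
#' @keywords internal
.kyte_doolittle <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Sequence hydrophobicity and charge census
#'
#' Descriptors used to compare three-finger protein constructs: the mean
#' Kyte-Doolittle hydropathy index over the sequence (bounded by -4.5 for
#' poly-Arg and +4.5 for poly-Ile), and the census of charged groups at
#' neutral pH - positive = Arg + Lys + 1 (the N-terminus), negative =
#' Asp + Glu + 1 (the C-terminus).  His residues, which only charge
#' around pH 6, are counted separately; Cys thiols are not counted.
#'
#' @param sequence One-letter amino-acid string (or character vector of
#'   residues).
#' @return Object of class `sequence_profile`: `sequence`, `length`,
#'   `mean_kd_index`, `positive_count`, `negative_count`, `his_count`.
#' @examples
#' sequence_profile(strrep("I", 20))  # mean index +4.5
#' @export
sequence_profile <- function(sequence) {
  aa <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  aa <- toupper(aa)
  bad <- which(!aa %in% names(.kyte_doolittle))
  if (length(bad) > 0)
    stop("unknown amino-acid letter(s) at position(s): ",
         paste(sprintf("%d ('%s')", bad, aa[bad]), collapse = ", "))
  structure(list(
    sequence = paste(aa, collapse = ""),
    length = length(aa),
    mean_kd_index = mean(.kyte_doolittle[aa]),
    positive_count = sum(aa %in% c("R", "K")) + 1L,
    negative_count = sum(aa %in% c("D", "E")) + 1L,
    his_count = sum(aa == "H")),
    class = "sequence_profile")
}

#' @export
print.sequence_profile <- function(x, ...) {
  cat(sprintf("Sequence profile (%d aa): KD index %+.2f, charges +%d/-%d, His %d\n",
              x$length, x$mean_kd_index, x$positive_count,
              x$negative_count, x$his_count))
  invisible(x)
}
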