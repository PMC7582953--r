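# Physical constants and unit policy.
#
# Internal unit policy (conversions centralized here):
#   correlation times  ns      (converted to s only inside spectral densities)
#   relaxation rates   s^-1
#   frequencies        rad/s (angular), MHz for nominal spectrometer fields
#   distances          Angstrom
#   energies           kcal/mol or multiples of kB*T

#' @keywords internal
.mfdyn_const <- list(
  gamma_h    = 2.6752218744e8,   # 1H  gyromagnetic ratio, rad s^-1 T^-1
  gamma_n    = -2.7126e7,        # 15N gyromagnetic ratio, rad s^-1 T^-1 (negative)
  mu0        = 4 * pi * 1e-7,    # vacuum permeability, T^2 J^-1 m^3
  hbar       = 1.054571817e-34,  # reduced Planck constant, J s
  r_gas_kcal = 1.98720425864083e-3  # molar gas constant, kcal mol^-1 K^-1
)

#' Nuclear interaction constants for the 15N-1H spin pair
#'
#' Bundles the constants entering the dipolar and chemical shift anisotropy
#' (CSA) relaxation mechanisms.  Defaults follow the historical
#' Modelfree/FastModelFree conventions: an effective N-H bond length of
#' 1.02 Angstrom and an axially symmetric 15N CSA of -160 ppm.  Absolute
#' order parameters shift by a few percent under other common choices
#' (e.g. r_NH = 1.04 A, CSA = -172 ppm); both values are therefore
#' configurable and are recorded in every fit result.
#'
#' @param r_nh_angstrom Effective N-H internuclear distance in Angstrom.
#' @param csa_ppm 15N chemical shift anisotropy (delta_sigma) in ppm.
#' @param gamma_h,gamma_n Gyromagnetic ratios in rad s^-1 T^-1.  gamma_n is
#'   negative for 15N; the sign is carried consistently and enters the
#'   heteronuclear NOE through the gamma_H/gamma_N ratio.
#' @return An object of class `nuclear_constants`.
#' @examples
#' nuclear_constants()
#' nuclear_constants(r_nh_angstrom = 1.04, csa_ppm = -172)
#' @export
nuclear_constants <- function(r_nh_angstrom = 1.02, csa_ppm = -160,
                              gamma_h = .mfdyn_const$gamma_h,
                              gamma_n = .mfdyn_const$gamma_n) {
  stopifnot(is.numeric(r_nh_angstrom), length(r_nh_angstrom) == 1L,
            is.numeric(csa_ppm), length(csa_ppm) == 1L)
  if (!is.finite(r_nh_angstrom) || r_nh_angstrom <= 0)
    stop("r_nh_angstrom must be a positive finite number")
  if (gamma_h <= 0) stop("gamma_h must be positive")
  if (gamma_n >= 0) stop("gamma_n must be negative for 15N")
  structure(list(r_nh_angstrom = r_nh_angstrom, csa_ppm = csa_ppm,
                 gamma_h = gamma_h, gamma_n = gamma_n),
            class = "nuclear_constants")
}

#' @export
print.nuclear_constants <- function(x, ...) {
  cat("15N-1H nuclear constants\n")
  cat(sprintf("  r_NH      : %.3f Angstrom\n", x$r_nh_angstrom))
  cat(sprintf("  CSA       : %.1f ppm\n", x$csa_ppm))
  cat(sprintf("  gamma_H   : %.6e rad/s/T\n", x$gamma_h))
  cat(sprintf("  gamma_N   : %.6e rad/s/T\n", x$gamma_n))
  invisible(x)
}

#' Spectrometer field description
#'
#' Describes one static magnetic field by its nominal 1H resonance frequency.
#' The 15N angular frequency is derived through the gyromagnetic ratios, so
#' `omega_n / omega_h == gamma_n / gamma_h` (negative) by construction.
#' Spectral densities are evaluated at frequency magnitudes; the sign of
#' gamma_N only enters the NOE cross-relaxation term.
#'
#' @param proton_mhz 1H frequency in MHz (e.g. 600, 800).
#' @param temperature_k Sample temperature in Kelvin.
#' @param constants A [nuclear_constants()] object (for the gamma ratio).
#' @return An object of class `spectrometer_field` with elements
#'   `proton_mhz`, `omega_h` and `omega_n` (rad/s, signed) and
#'   `temperature_k`.
#' @examples
#' spectrometer_field(800, temperature_k = 310.15)
#' @export
spectrometer_field <- function(proton_mhz, temperature_k = 310.15,
                               constants = nuclear_constants()) {
  stopifnot(is.numeric(proton_mhz), length(proton_mhz) == 1L)
  if (!is.finite(proton_mhz) || proton_mhz <= 0)
    stop("proton_mhz must be a positive finite number")
  if (!is.finite(temperature_k) || temperature_k <= 0)
    stop("temperature_k must be positive")
  omega_h <- 2 * pi * proton_mhz * 1e6
  structure(list(proton_mhz = proton_mhz,
                 omega_h = omega_h,
                 omega_n = omega_h * constants$gamma_n / constants$gamma_h,
                 temperature_k = temperature_k),
            class = "spectrometer_field")
}

#' @export
print.spectrometer_field <- function(x, ...) {
  cat(sprintf("Spectrometer field: %.1f MHz (1H), T = %.2f K\n",
              x$proton_mhz, x$temperature_k))
  cat(sprintf("  omega_H = %.4e rad/s, omega_N = %.4e rad/s\n",
              x$omega_h, x$omega_n))
  invisible(x)
}

#' Thermal energy in kcal/mol
#'
#' `kB*T` expressed per mole (i.e. `R*T`), the conversion factor between
#' energies quoted in kcal/mol and in units of `kB*T`.
#'
#' @param temperature_k Temperature in Kelvin.
#' @return Numeric, kcal/mol per kB*T.
#' @examples
#' kbt_kcal_per_mol(303.15)  # ~0.6024 at 30 degrees C
#' @export
kbt_kcal_per_mol <- function(temperature_k) {
  if (any(!is.finite(temperature_k)) || any(temperature_k <= 0))
    stop("temperature_k must be positive")
  .mfdyn_const$r_gas_kcal * temperature_k
}
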