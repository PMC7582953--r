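# Forward 15N relaxation model: dipolar + CSA (+ exchange) rates from
# model-free spectral densities.

# Dipolar and CSA interaction strengths (rad^2/s^2).
#   d2 = [ (mu0/4pi) * hbar * gamma_H * gamma_N / r_NH^3 ]^2
#   c2 = (omega_N * delta_sigma)^2 / 3
#' @keywords internal
.interaction_constants <- function(field, constants) {
  r_m <- constants$r_nh_angstrom * 1e-10
  d <- (.mfdyn_const$mu0 / (4 * pi)) * .mfdyn_const$hbar *
    constants$gamma_h * constants$gamma_n / r_m^3
  c2 <- (field$omega_n * constants$csa_ppm * 1e-6)^2 / 3
  list(d2 = d^2, c2 = c2)
}

#' Scale an exchange contribution between spectrometer fields
#'
#' Exchange contributions to R2 from fast us-ms conformational exchange are
#' proportional to the square of the static field, so
#' `rex(target) = rex(ref) * (target/ref)^2`.  This is the rule that turns
#' the 3.0 s^-1 threshold at 800 MHz into 2.3 s^-1 at 700 MHz and
#' 1.7 s^-1 at 600 MHz.
#'
#' @param rex_ref Exchange contribution (s^-1) at `ref_mhz`.
#' @param ref_mhz,target_mhz 1H spectrometer frequencies in MHz.
#' @return Exchange contribution at `target_mhz`, s^-1.
#' @examples
#' rex_at_field(3.0, 800, 600)  # 1.6875
#' @export
rex_at_field <- function(rex_ref, ref_mhz, target_mhz) {
  if (any(!is.finite(ref_mhz)) || any(ref_mhz <= 0) ||
      any(!is.finite(target_mhz)) || any(target_mhz <= 0))
    stop("spectrometer frequencies must be positive")
  if (any(rex_ref < 0)) stop("rex_ref must be non-negative")
  rex_ref * (target_mhz / ref_mhz)^2
}

#' Predict R1, R2 and heteronuclear NOE for one residue
#'
#' Standard expressions for backbone amide 15N relaxation by the
#' 15N-1H dipolar interaction and the axially symmetric 15N CSA:
#'
#' \deqn{R_1 = (d^2/4)[J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H+\omega_N)] + c^2 J(\omega_N)}
#' \deqn{R_2 = (d^2/8)[4J(0) + J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H) + 6J(\omega_H+\omega_N)] + (c^2/6)[4J(0) + 3J(\omega_N)]
#'   + R_{ex}}
#' \deqn{NOE = 1 + (d^2/4)(\gamma_H/\gamma_N)
#'   [6J(\omega_H+\omega_N) - J(\omega_H-\omega_N)] / R_1}
#'
#' with `d^2`, `c^2` from the configured [nuclear_constants()].  Spectral
#' densities are evaluated at frequency magnitudes; the negative 15N
#' gyromagnetic ratio enters through the `gamma_H/gamma_N` factor in the
#' NOE.  Any exchange contribution carried by `params` is rescaled from its
#' stored field to the requested one with [rex_at_field()] and added to R2
#' only.
#'
#' @inheritParams spectral_density
#' @param field A [spectrometer_field()] object.
#' @param constants A [nuclear_constants()] object.
#' @return An object of class `relaxation_triple`: list with `r1`, `r2`
#'   (s^-1) and `noe` (unitless).
#' @examples
#' p <- model_free_params(2, s2 = 0.85, tau_e_ps = 50)
#' predict_relaxation(p, diffusion_tensor("isotropic", 4.3),
#'                    spectrometer_field(800))
#' @export
predict_relaxation <- function(params, tensor, field,
                               constants = nuclear_constants(),
                               nh_orientation = NULL) {
  stopifnot(inherits(field, "spectrometer_field"),
            inherits(constants, "nuclear_constants"))
  ic <- .interaction_constants(field, constants)
  wh <- abs(field$omega_h)
  wn <- abs(field$omega_n)
  # J at 0, wN, wH - wN, wH, wH + wN (magnitude convention)
  j <- spectral_density(params, tensor,
                        omega = c(0, wn, wh - wn, wh, wh + wn),
                        nh_orientation = nh_orientation)
  r1 <- (ic$d2 / 4) * (j[3] + 3 * j[2] + 6 * j[5]) + ic$c2 * j[2]
  r2 <- (ic$d2 / 8) * (4 * j[1] + j[3] + 3 * j[2] + 6 * j[4] + 6 * j[5]) +
    (ic$c2 / 6) * (4 * j[1] + 3 * j[2])
  if (!is.null(params$rex))
    r2 <- r2 + rex_at_field(params$rex, params$rex_field_mhz, field$proton_mhz)
  noe <- 1 + (ic$d2 / 4) * (constants$gamma_h / constants$gamma_n) *
    (6 * j[5] - j[3]) / r1
  structure(list(r1 = r1, r2 = r2, noe = noe), class = "relaxation_triple")
}

#' @export
print.relaxation_triple <- function(x, ...) {
  cat(sprintf("R1 = %.4f s^-1, R2 = %.4f s^-1, NOE = %.4f\n",
              x$r1, x$r2, x$noe))
  invisible(x)
}
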