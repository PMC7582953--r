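# Containers for per-residue internal-motion parameters and the global
# rotational diffusion tensor.

#' Model-free internal motion parameters for one residue
#'
#' The five standard Lipari-Szabo parameter sets used by
#' Modelfree/FastModelFree-style analyses:
#'
#' * model 1: `s2`
#' * model 2: `s2`, `tau_e_ps`
#' * model 3: `s2`, `rex`
#' * model 4: `s2`, `tau_e_ps`, `rex`
#' * model 5: `s2f`, `s2s`, `tau_s_ns` (extended two-timescale form;
#'   the overall order parameter is the product `s2 = s2f * s2s`)
#'
#' Parameters not used by a model must be left `NULL`; the constructor
#' enforces this so a parameter set always identifies its model uniquely.
#' Exchange contributions are stored at the field where they were measured
#' (`rex_field_mhz`) and are only ever rescaled explicitly with
#' [rex_at_field()].
#'
#' @param model_id Integer in 1..5.
#' @param s2 Generalized order parameter, in `[0, 1]`.  For model 5 it may
#'   be omitted and is computed as `s2f * s2s`; if given it must match the
#'   product within `1e-6`.
#' @param tau_e_ps Effective correlation time of fast internal motion, ps
#'   (models 2 and 4; also written tau_f).
#' @param rex Conformational exchange contribution to R2, s^-1, at
#'   `rex_field_mhz` (models 3 and 4).  Must be non-negative.
#' @param rex_field_mhz 1H frequency (MHz) at which `rex` is quoted.
#' @param s2f,s2s Squared order parameters of the fast and slow internal
#'   motions (model 5), each in `[0, 1]`.
#' @param tau_s_ns Correlation time of the slow internal motion, ns
#'   (model 5; typically 0.5-2 ns).
#' @return An object of class `model_free_params`.
#' @examples
#' model_free_params(2, s2 = 0.85, tau_e_ps = 50)
#' model_free_params(5, s2f = 0.8, s2s = 0.9, tau_s_ns = 1.2)
#' @export
model_free_params <- function(model_id, s2 = NULL, tau_e_ps = NULL,
                              rex = NULL, rex_field_mhz = 800,
                              s2f = NULL, s2s = NULL, tau_s_ns = NULL) {
  if (!model_id %in% 1:5) stop("model_id must be one of 1, 2, 3, 4, 5")
  model_id <- as.integer(model_id)
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
      stop(sprintf("%s must be a single number in [0, 1]", nm))
  }
  need <- function(x, nm) if (is.null(x))
    stop(sprintf("model %d requires %s", model_id, nm))
  forbid <- function(x, nm) if (!is.null(x))
    stop(sprintf("%s is not a parameter of model %d", nm, model_id))

  if (model_id %in% 1:4) {
    need(s2, "s2"); chk01(s2, "s2")
    forbid(s2f, "s2f"); forbid(s2s, "s2s"); forbid(tau_s_ns, "tau_s_ns")
  }
  if (model_id %in% c(2L, 4L)) {
    need(tau_e_ps, "tau_e_ps")
    if (tau_e_ps < 0) stop("tau_e_ps must be non-negative")
  } else {
    forbid(tau_e_ps, "tau_e_ps")
  }
  if (model_id %in% c(3L, 4L)) {
    need(rex, "rex")
    if (!is.finite(rex) || rex < 0) stop("rex must be non-negative")
    if (rex_field_mhz <= 0) stop("rex_field_mhz must be positive")
  } else {
    forbid(rex, "rex")
  }
  if (model_id == 5L) {
    need(s2f, "s2f"); need(s2s, "s2s"); need(tau_s_ns, "tau_s_ns")
    chk01(s2f, "s2f"); chk01(s2s, "s2s")
    if (tau_s_ns <= 0) stop("tau_s_ns must be positive")
    if (!is.null(s2)) {
      if (abs(s2 - s2f * s2s) > 1e-6)
        stop("for model 5, s2 must equal s2f * s2s")
    }
    s2 <- s2f * s2s
  }
  structure(list(model_id = model_id, s2 = s2, tau_e_ps = tau_e_ps,
                 rex = if (model_id %in% c(3L, 4L)) rex else NULL,
                 rex_field_mhz = if (model_id %in% c(3L, 4L)) rex_field_mhz else NULL,
                 s2f = s2f, s2s = s2s, tau_s_ns = tau_s_ns),
            class = "model_free_params")
}

#' @export
print.model_free_params <- function(x, ...) {
  cat(sprintf("Model-free parameters (model %d): S2 = %.3f", x$model_id, x$s2))
  if (!is.null(x$tau_e_ps)) cat(sprintf(", tau_e = %.1f ps", x$tau_e_ps))
  if (!is.null(x$rex))
    cat(sprintf(", Rex = %.2f s^-1 @ %g MHz", x$rex, x$rex_field_mhz))
  if (!is.null(x$s2f))
    cat(sprintf(" (S2f = %.3f, S2s = %.3f, tau_s = %.2f ns)",
                x$s2f, x$s2s, x$tau_s_ns))
  cat("\n")
  invisible(x)
}

#' Rotational diffusion tensor
#'
#' Global Brownian tumbling model: either isotropic (a single correlation
#' time `tau_r = 1/(6 D_iso)`) or axially symmetric, parameterized by the
#' isotropic-equivalent `tau_r`, the anisotropy ratio
#' `2 Dz / (Dx + Dy) = D_par / D_perp` (with `Dx = Dy = D_perp`), and the
#' polar orientation of the unique axis in the structure frame.  Fully
#' anisotropic (rhombic) tensors are not implemented.
#'
#' @param kind `"isotropic"` or `"axially_symmetric"`.
#' @param tau_r_ns Isotropic rotational correlation time in ns
#'   (`1/(6 D_iso)` with `D_iso = (2 D_perp + D_par)/3`).
#' @param anisotropy Ratio `D_par / D_perp`; must be 1 for the isotropic
#'   kind.  Values > 1 are prolate, < 1 oblate.
#' @param axis_theta,axis_phi Polar angles (rad) of the unique axis.
#' @return An object of class `diffusion_tensor`.
#' @examples
#' diffusion_tensor("isotropic", tau_r_ns = 4.3)
#' diffusion_tensor("axially_symmetric", 4.3, anisotropy = 1.3,
#'                  axis_theta = 0.4, axis_phi = 1.0)
#' @export
diffusion_tensor <- function(kind = c("isotropic", "axially_symmetric"),
                             tau_r_ns, anisotropy = 1,
                             axis_theta = 0, axis_phi = 0) {
  kind <- match.arg(kind)
  if (!is.finite(tau_r_ns) || tau_r_ns <= 0) stop("tau_r_ns must be positive")
  if (!is.finite(anisotropy) || anisotropy <= 0)
    stop("anisotropy must be positive")
  if (kind == "isotropic" && abs(anisotropy - 1) > 1e-12)
    stop("isotropic tensor must have anisotropy = 1")
  structure(list(kind = kind, tau_r_ns = tau_r_ns, anisotropy = anisotropy,
                 axis_theta = axis_theta, axis_phi = axis_phi),
            class = "diffusion_tensor")
}

#' @export
print.diffusion_tensor <- function(x, ...) {
  cat(sprintf("Rotational diffusion tensor (%s): tau_R = %.2f ns",
              x$kind, x$tau_r_ns))
  if (x$kind == "axially_symmetric")
    cat(sprintf(", D_par/D_perp = %.2f, axis (theta, phi) = (%.2f, %.2f) rad",
                x$anisotropy, x$axis_theta, x$axis_phi))
  cat("\n")
  invisible(x)
}

# Unique-axis unit vector of an axially symmetric tensor.
#' @keywords internal
.tensor_axis <- function(tensor) {
  st <- sin(tensor$axis_theta)
  c(st * cos(tensor$axis_phi), st * sin(tensor$axis_phi),
    cos(tensor$axis_theta))
}
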