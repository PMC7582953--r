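# Lipari-Szabo spectral densities for isotropic and axially symmetric
# rotational diffusion.

# Lorentzian tau / (1 + (omega*tau)^2); tau in s, omega in rad/s.
#' @keywords internal
.lorentz <- function(tau_s, omega) tau_s / (1 + (omega * tau_s)^2)

# Internal-motion descriptors shared by all five models:
#   J(w) = (2/5) * sum_k A_k * [ S2 * L(tau_k) + (amp - S2) * L(tau_k') ]
# with 1/tau_k' = 1/tau_k + 1/tau_int.  For models 1-4 amp = 1 and tau_int
# is tau_e (tau_int = 0 collapses the second term); for model 5 amp = S2f
# and tau_int is tau_s (the fast motion is taken in the tau_f -> 0 limit).
#' @keywords internal
.internal_motion <- function(params) {
  if (params$model_id == 5L) {
    list(s2 = params$s2, amp = params$s2f, tau_int_s = params$tau_s_ns * 1e-9)
  } else {
    tau_e <- if (is.null(params$tau_e_ps)) 0 else params$tau_e_ps * 1e-12
    list(s2 = params$s2, amp = 1, tau_int_s = tau_e)
  }
}

# Correlation times (s) and orientation weights of the tensor.
# For isotropic tensors a single term with weight 1; for axially symmetric
# tensors the standard three-Lorentzian decomposition with weights set by
# the angle between the NH vector and the unique axis.
#' @keywords internal
.tensor_terms <- function(tensor, nh_orientation = NULL) {
  tau_r <- tensor$tau_r_ns * 1e-9
  if (tensor$kind == "isotropic")
    return(list(weights = 1, taus = tau_r))
  if (is.null(nh_orientation))
    stop("nh_orientation is required for an axially symmetric tensor")
  v <- as.numeric(nh_orientation)
  if (length(v) != 3L || any(!is.finite(v)) || sum(v^2) == 0)
    stop("nh_orientation must be a finite length-3 vector")
  v <- v / sqrt(sum(v^2))
  ct <- sum(v * .tensor_axis(tensor))
  ct2 <- ct^2
  w <- c((3 * ct2 - 1)^2 / 4,
         3 * ct2 * (1 - ct2),
         0.75 * (1 - ct2)^2)
  d_iso <- 1 / (6 * tau_r)
  d_perp <- 3 * d_iso / (2 + tensor$anisotropy)
  d_par <- tensor$anisotropy * d_perp
  taus <- 1 / c(6 * d_perp,
                5 * d_perp + d_par,
                2 * d_perp + 4 * d_par)
  list(weights = w, taus = taus)
}

#' Lipari-Szabo spectral density
#'
#' Evaluates the model-free spectral density `J(omega)` for a residue with
#' internal-motion parameters `params` tumbling with diffusion tensor
#' `tensor`.  For models 1-4 the standard two-Lorentzian form is used, with
#' the effective internal correlation time combined with each global
#' correlation time as `1/tau' = 1/tau_k + 1/tau_e`.  Model 5 uses the
#' extended two-timescale form in the fast limit of the faster motion:
#' `J = (2/5) [ S2 L(tau_k) + (S2f - S2) L(tau'_k) ]` with
#' `1/tau'_k = 1/tau_k + 1/tau_s`.  For an axially symmetric tensor the
#' three-Lorentzian orientation-weighted decomposition is applied and
#' `nh_orientation` (the NH bond vector in the tensor frame) is required.
#'
#' @param params A [model_free_params()] object.
#' @param tensor A [diffusion_tensor()] object.
#' @param omega Angular frequency (rad/s), vectorized.  Negative inputs are
#'   rejected; callers evaluate at frequency magnitudes.
#' @param nh_orientation Length-3 NH bond vector (need not be normalized);
#'   required iff `tensor` is axially symmetric.
#' @return `J(omega)` in s/rad, same length as `omega`.
#' @examples
#' p <- model_free_params(1, s2 = 1)
#' d <- diffusion_tensor("isotropic", 5)
#' spectral_density(p, d, omega = 0)  # rigid limit: (2/5) * tau_R = 2 ns/rad
#' @export
spectral_density <- function(params, tensor, omega, nh_orientation = NULL) {
  stopifnot(inherits(params, "model_free_params"),
            inherits(tensor, "diffusion_tensor"))
  if (any(!is.finite(omega)) || any(omega < 0))
    stop("omega must be finite and non-negative (evaluate at magnitudes)")
  im <- .internal_motion(params)
  tt <- .tensor_terms(tensor, nh_orientation)
  j <- numeric(length(omega))
  for (k in seq_along(tt$taus)) {
    tau_k <- tt$taus[k]
    term <- im$s2 * .lorentz(tau_k, omega)
    if (im$amp - im$s2 > 0 && im$tau_int_s > 0) {
      tau_p <- 1 / (1 / tau_k + 1 / im$tau_int_s)
      term <- term + (im$amp - im$s2) * .lorentz(tau_p, omega)
    }
    j <- j + tt$weights[k] * term
  }
  0.4 * j
}
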