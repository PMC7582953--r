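# Backbone conformational entropy from order parameters, and the
# corresponding free-energy / affinity estimates.

#' Conformational entropy of one NH bond vector from its order parameter
#'
#' The model-independent relation between a bond-vector order parameter
#' and its conformational entropy (the diffusion-in-a-cone /
#' bond-vector-distribution result popularized by Yang & Kay):
#'
#' \deqn{S_{conf}/k_B = \ln\left[\pi\,(3 - \sqrt{1 + 8S})\right]}
#'
#' evaluated with the positive root `S = +sqrt(S2)` (default
#' `formula = "cone_bv"`).  The entropy decreases monotonically with
#' increasing S2 and diverges to `-Inf` in the rigid limit `S2 -> 1`,
#' which is guarded.  `formula = "cone_bv_half"` applies an additional
#' factor 1/2, a convention found in some applications of the relation;
#' every downstream result records which convention produced it.
#'
#' @param s2 Squared generalized order parameter, strictly in (0, 1).
#' @param formula `"cone_bv"` (default) or `"cone_bv_half"`.
#' @return Entropy in units of kB (per residue), vectorized over `s2`.
#' @examples
#' residue_entropy(0.7) - residue_entropy(0.85)
#' @export
residue_entropy <- function(s2, formula = c("cone_bv", "cone_bv_half")) {
  formula <- match.arg(formula)
  if (any(!is.finite(s2))) stop("s2 must be finite")
  if (any(s2 <= 0)) stop("s2 must be positive")
  if (any(s2 >= 1))
    stop("s2 must be strictly below 1 (rigid limit: entropy -> -Inf)")
  ent <- log(pi * (3 - sqrt(1 + 8 * sqrt(s2))))
  if (formula == "cone_bv_half") ent <- ent / 2
  ent
}

#' Backbone conformational entropy penalty of an order-parameter change
#'
#' Entropy change when the average order parameter of `n_residues`
#' backbone amides moves from `s2_initial` to `s2_final` (e.g. rigidified
#' upon receptor binding):
#' `dS = n * [residue_entropy(s2_final) - residue_entropy(s2_initial)]`,
#' reported per mole and as the free-energy penalty `-T*dS` in kcal/mol
#' and in units of kB*T at the stated temperature.  Only backbone
#' conformational entropy is counted.
#'
#' @param s2_initial,s2_final Average order parameters before and after.
#' @param n_residues Number of residues affected.
#' @param temperature_k Temperature in Kelvin (30 degrees C = 303.15 K).
#' @param formula Entropy convention, see [residue_entropy()].
#' @return Object of class `entropy_estimate`: list with `delta_s_kb`
#'   (total, units of kB), `delta_s_cal_mol_k` (cal mol^-1 K^-1),
#'   `minus_t_ds_kcal_mol`, `minus_t_ds_kbt`, inputs, and `formula_id`.
#' @examples
#' entropy_penalty(0.7, 0.85, n_residues = 15, temperature_k = 303.15)
#' @export
entropy_penalty <- function(s2_initial, s2_final, n_residues,
                            temperature_k = 303.15,
                            formula = c("cone_bv", "cone_bv_half")) {
  formula <- match.arg(formula)
  if (n_residues < 1) stop("n_residues must be >= 1")
  if (temperature_k <= 0) stop("temperature_k must be positive")
  ds_kb <- n_residues * (residue_entropy(s2_final, formula) -
                           residue_entropy(s2_initial, formula))
  structure(list(
    s2_initial = s2_initial, s2_final = s2_final,
    n_residues = n_residues, temperature_k = temperature_k,
    delta_s_kb = ds_kb,
    delta_s_cal_mol_k = ds_kb * .mfdyn_const$r_gas_kcal * 1000,
    minus_t_ds_kcal_mol = -ds_kb * kbt_kcal_per_mol(temperature_k),
    minus_t_ds_kbt = -ds_kb,
    formula_id = formula),
    class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("Conformational entropy change (%s): S2 %.2f -> %.2f, n = %d, T = %.2f K\n",
              x$formula_id, x$s2_initial, x$s2_final, x$n_residues,
              x$temperature_k))
  cat(sprintf("  dS    = %+.2f kB (%+.2f cal/mol/K)\n",
              x$delta_s_kb, x$delta_s_cal_mol_k))
  cat(sprintf("  -T*dS = %+.2f kcal/mol (%+.2f kB*T)\n",
              x$minus_t_ds_kcal_mol, x$minus_t_ds_kbt))
  invisible(x)
}

#' Boltzmann affinity ratio from a free-energy difference
#'
#' Fold change in affinity (dissociation constant) implied by a
#' free-energy difference: `ratio = exp(dG / kB*T)`.  Provide the
#' difference either directly in units of kB*T or in kcal/mol together
#' with a temperature.
#'
#' @param delta_g_kbt Free-energy difference in kB*T units.
#' @param delta_g_kcal_mol Alternative input in kcal/mol (requires
#'   `temperature_k`).
#' @param temperature_k Temperature (K) for the kcal/mol conversion.
#' @return List with `fold_change`, `log10_fold_change`, `delta_g_kbt`.
#' @examples
#' affinity_ratio(5.7)  # ~299-fold, > 2 orders of magnitude
#' @export
affinity_ratio <- function(delta_g_kbt = NULL, delta_g_kcal_mol = NULL,
                           temperature_k = NULL) {
  if (is.null(delta_g_kbt)) {
    if (is.null(delta_g_kcal_mol) || is.null(temperature_k))
      stop("provide delta_g_kbt, or delta_g_kcal_mol with temperature_k")
    delta_g_kbt <- delta_g_kcal_mol / kbt_kcal_per_mol(temperature_k)
  }
  if (!is.finite(delta_g_kbt)) stop("free-energy difference must be finite")
  ratio <- exp(delta_g_kbt)
  list(fold_change = ratio, log10_fold_change = log10(ratio),
       delta_g_kbt = delta_g_kbt)
}
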