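# Per-residue model-free fitting: round trips, selection, invariances,
# Monte-Carlo error behaviour.

tensor43 <- diffusion_tensor("isotropic", 4.3)

fit_single <- function(params, mc_reps = 0, ...) {
  ds <- single_residue_dataset(params)
  fit_residue_models(ds, tensor43, mc_reps = mc_reps, seed = 1, ...)
}

test_that("noiseless round trip recovers every model to 3 significant figures", {
  cases <- list(
    model_free_params(1, s2 = 0.9),
    model_free_params(2, s2 = 0.80, tau_e_ps = 50),
    model_free_params(3, s2 = 0.88, rex = 3.5, rex_field_mhz = 800),
    model_free_params(4, s2 = 0.75, tau_e_ps = 60, rex = 5,
                      rex_field_mhz = 800),
    model_free_params(5, s2f = 0.75, s2s = 0.85, tau_s_ns = 1.5))
  for (p in cases) {
    fit <- fit_single(p)
    expect_identical(fit$status, "ok")
    expect_identical(fit$model, p$model_id)
    expect_equal(fit$s2, p$s2, tolerance = 1e-3)
    if (!is.null(p$tau_e_ps))
      expect_equal(fit$tau_e_ps, p$tau_e_ps, tolerance = 1e-3)
    if (!is.null(p$rex))
      expect_equal(fit$rex, p$rex, tolerance = 1e-3)
    if (p$model_id == 5L) {
      expect_equal(fit$s2f, p$s2f, tolerance = 1e-3)
      expect_equal(fit$s2s, p$s2s, tolerance = 1e-3)
      expect_equal(fit$tau_s_ns, p$tau_s_ns, tolerance = 1e-3)
    }
  }
})

test_that("reported S2 stays in [0, 1] and parameters match their model", {
  spec <- dynamics_profile_spec(n_residues = 30, seed = 21,
                                scheme = small_scheme())
  prof <- make_profile(spec)
  ds <- simulate_dataset(prof, spec)
  fit <- suppressWarnings(
    fit_residue_models(ds, tensor43, mc_reps = 0, seed = 1))
  done <- fit[fit$status %in% c("ok", "no_model"), ]
  expect_true(all(done$s2 >= 0 & done$s2 <= 1))
  expect_true(all(is.na(done$rex[done$model %in% c(1, 2, 5)])))
  expect_true(all(!is.na(done$rex[done$model %in% c(3, 4)])))
  expect_true(all(done$rex[!is.na(done$rex)] >= 0))
  # one selected model per non-excluded residue
  expect_true(all(!is.na(done$model)))
})

test_that("fit is invariant to residue ordering", {
  spec <- dynamics_profile_spec(n_residues = 20, seed = 3,
                                scheme = small_scheme(20), n_rex = 2,
                                n_doubled = 0, n_broadened = 0,
                                n_proline = 0)
  prof <- make_profile(spec)
  ds <- simulate_dataset(prof, spec)
  shuffled <- as.data.frame(ds)[sample(nrow(ds)), ]
  ds2 <- relaxation_dataset(shuffled, protein = attr(ds, "protein"),
                            temperature_k = attr(ds, "temperature_k"))
  f1 <- fit_residue_models(ds, tensor43, mc_reps = 0, seed = 1)
  f2 <- fit_residue_models(ds2, tensor43, mc_reps = 0, seed = 1)
  expect_equal(as.data.frame(f1), as.data.frame(f2))
})

test_that("the 600 MHz R2 row does not widen the S2 confidence interval", {
  p <- model_free_params(3, s2 = 0.85, rex = 4, rex_field_mhz = 800)
  ds_two <- single_residue_dataset(p, sigma = 0.02)
  one <- as.data.frame(ds_two)[ds_two$field_mhz == 800, ]
  ds_one <- relaxation_dataset(one, temperature_k = 310.15)
  f_two <- fit_residue_models(ds_two, tensor43, mc_reps = 300, seed = 11)
  f_one <- fit_residue_models(ds_one, tensor43, mc_reps = 300, seed = 11)
  expect_lte(f_two$s2_err, f_one$s2_err * 1.15)  # 15% MC slack
})

test_that("Monte-Carlo uncertainties are consistent between 100 and 400 reps", {
  p <- model_free_params(2, s2 = 0.8, tau_e_ps = 50)
  ds <- single_residue_dataset(p, sigma = 0.03)
  f100 <- fit_residue_models(ds, tensor43, mc_reps = 100, seed = 5)
  f400 <- fit_residue_models(ds, tensor43, mc_reps = 400, seed = 5)
  # the SD estimate itself converges: agreement within ~ 1/sqrt(2*100)
  expect_equal(f100$s2_err / f400$s2_err, 1, tolerance = 0.25)
  expect_gt(f400$s2_err, 0)
})

test_that("residues with too few observables are skipped with a warning", {
  rec <- data.frame(residue_id = 1L, residue_name = "ALA", field_mhz = 800,
                    r1 = NA, r1_err = NA, r2 = 8.1, r2_err = 0.2,
                    noe = NA, noe_err = NA, flags = "")
  ds <- relaxation_dataset(rec)
  expect_warning(fit <- fit_residue_models(ds, tensor43, mc_reps = 0),
                 "skipped")
  expect_identical(fit$status, "skipped_insufficient")
})

test_that("flagged residues are excluded and a hopeless residue is flagged no_model", {
  p <- model_free_params(2, s2 = 0.8, tau_e_ps = 50)
  ds <- single_residue_dataset(p)
  df <- as.data.frame(ds)
  df$flags <- "proline"
  ds_pro <- relaxation_dataset(df)
  fit <- fit_residue_models(ds_pro, tensor43, mc_reps = 0)
  expect_identical(fit$status, "excluded_flag")

  # internally inconsistent observables (R2 far below the rigid floor at
  # matching R1/NOE) with tiny sigmas cannot be fit by any model
  df2 <- as.data.frame(single_residue_dataset(p, sigma = 1e-4))
  df2$r2 <- df2$r2 * 0.3
  ds_bad <- relaxation_dataset(df2)
  fit_bad <- fit_residue_models(ds_bad, tensor43, mc_reps = 0)
  expect_identical(fit_bad$status, "no_model")
})
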