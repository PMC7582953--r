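# Synthetic-data generator: determinism, forward-model equality, noise
# calibration, preset structure.

test_that("profiles are deterministic given the seed", {
  spec <- dynamics_profile_spec(seed = 123)
  p1 <- make_profile(spec)
  p2 <- make_profile(spec)
  expect_identical(p1, p2)
  d1 <- simulate_dataset(p1, spec)
  d2 <- simulate_dataset(p2, spec)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  # a different seed changes the draw
  p3 <- make_profile(dynamics_profile_spec(seed = 124))
  expect_false(identical(p1$s2, p3$s2))
})

test_that("zero-noise datasets equal the forward model exactly", {
  spec <- dynamics_profile_spec(n_residues = 15, seed = 6,
                                scheme = small_scheme(15), n_rex = 1,
                                n_doubled = 0, n_broadened = 0,
                                n_proline = 0)
  prof <- make_profile(spec)
  ds <- simulate_dataset(prof, spec, noise = FALSE)
  tensor <- diffusion_tensor("isotropic", spec$tau_r_ns)
  for (i in c(2, 7, 11)) {
    row <- prof[i, ]
    params <- switch(as.character(row$model),
      "1" = model_free_params(1, s2 = row$s2),
      "2" = model_free_params(2, s2 = row$s2, tau_e_ps = row$tau_e_ps),
      "3" = model_free_params(3, s2 = row$s2, rex = row$rex),
      "4" = model_free_params(4, s2 = row$s2, tau_e_ps = row$tau_e_ps,
                              rex = row$rex))
    tr <- predict_relaxation(params, tensor,
                             spectrometer_field(800, spec$temperature_k))
    rec <- ds[ds$residue_id == row$residue_id & ds$field_mhz == 800, ]
    expect_equal(rec$r1, tr$r1, tolerance = 1e-12)
    expect_equal(rec$r2, tr$r2, tolerance = 1e-12)
    expect_equal(rec$noe, tr$noe, tolerance = 1e-12)
  }
})

test_that("two-field output mirrors the 800-full + 600-R2-only design", {
  spec <- dynamics_profile_spec(n_residues = 12, seed = 8,
                                scheme = small_scheme(12), n_rex = 0,
                                n_proline = 0, n_doubled = 0,
                                n_broadened = 0)
  ds <- simulate_dataset(make_profile(spec), spec)
  at600 <- ds[ds$field_mhz == 600, ]
  at800 <- ds[ds$field_mhz == 800, ]
  expect_true(all(is.na(at600$r1)) && all(is.na(at600$noe)))
  expect_true(all(!is.na(at600$r2)))
  expect_true(all(!is.na(at800$r1)) && all(!is.na(at800$noe)))
})

test_that("noise magnitude matches the spec empirically", {
  spec <- dynamics_profile_spec(n_residues = 10, seed = 40,
                                scheme = small_scheme(10),
                                n_rex = 0, n_doubled = 0, n_broadened = 0,
                                n_proline = 0, noise_fractional = 0.03)
  prof <- make_profile(spec)
  clean <- simulate_dataset(prof, spec, noise = FALSE)
  set.seed(2024)
  devs <- replicate(200, {
    noisy <- simulate_dataset(prof, spec, seed = sample.int(1e6, 1))
    (noisy$r2 - clean$r2) / clean$r2
  })
  expect_equal(sd(devs), 0.03, tolerance = 0.05)
})

test_that("the default preset reproduces the region ordering of the fold", {
  spec <- dynamics_profile_spec(seed = 1)
  prof <- make_profile(spec)
  rm <- region_mean(setNames(prof$s2, prof$residue_id), spec$scheme)
  m <- setNames(rm$mean, rm$region)
  expect_true(m["head"] > m["loop_i"])
  expect_true(m["loop_i"] > m["loop_ii"])
  expect_true(m["loop_ii"] > m["loop_iii"])
  expect_equal(m[["head"]], 0.88, tolerance = 0.02)
  expect_equal(m[["loop_iii"]], 0.66, tolerance = 0.05)
})

test_that("intensity tables follow the printed delay schedules", {
  spec <- dynamics_profile_spec(n_residues = 10, seed = 14,
                                scheme = small_scheme(10), n_rex = 0,
                                n_doubled = 0, n_broadened = 0,
                                n_proline = 0)
  ds <- simulate_dataset(make_profile(spec), spec, intensity_tables = TRUE)
  it <- attr(ds, "intensities")
  r1_tab <- it[it$experiment == "r1" & it$residue_id == 2, ]
  expect_setequal(round(r1_tab$delay_s, 3), round(relaxation_delays("r1"), 3))
  r2_tab <- it[it$experiment == "r2" & it$residue_id == 2, ]
  expect_setequal(round(r2_tab$delay_s, 3), round(relaxation_delays("r2"), 3))
  # decay fit on the emitted table recovers the record rate
  f <- fit_exponential_decay(r1_tab$delay_s, r1_tab$intensity)
  rec <- ds[ds$residue_id == 2 & ds$field_mhz == 800, ]
  expect_equal(f$rate, rec$r1, tolerance = 0.15 * rec$r1)
})

test_that("impossible specs are rejected", {
  expect_error(dynamics_profile_spec(seed = 1, n_rex = 1000), "exceeds")
  expect_error(dynamics_profile_spec(n_residues = 100), "seed")
  expect_error(dynamics_profile_spec(seed = 1, tau_r_ns = -2), "positive")
  expect_error(dynamics_profile_spec(seed = 1, noise_fractional = -0.1),
               "noise")
})
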