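# Forward model: spectral densities, relaxation rates, exchange scaling.

test_that("rigid-limit spectral density equals (2/5) tau_R at omega = 0", {
  p <- model_free_params(1, s2 = 1)
  d <- diffusion_tensor("isotropic", 5)
  expect_equal(spectral_density(p, d, 0), 2.0e-9)
})

test_that("tau_e -> 0 degeneracy: model 2 collapses onto model 1", {
  d <- diffusion_tensor("isotropic", 5)
  p2 <- model_free_params(2, s2 = 0.8, tau_e_ps = 0)
  p1 <- model_free_params(1, s2 = 0.8)
  w <- c(0, 1e8, 5e8, 3e9)
  expect_equal(spectral_density(p2, d, w), spectral_density(p1, d, w))
})

test_that("spectral density matches the independently coded oracle", {
  d <- diffusion_tensor("isotropic", 4.3)
  wn800 <- abs(spectrometer_field(800)$omega_n)
  p <- model_free_params(2, s2 = 0.85, tau_e_ps = 50)
  expect_equal(spectral_density(p, d, wn800),
               oracle_jw_iso(0.85, 50e-12, 4.3e-9, wn800),
               tolerance = 1e-12)
  # extended model against its own oracle
  p5 <- model_free_params(5, s2f = 0.8, s2s = 0.85, tau_s_ns = 1.2)
  expect_equal(spectral_density(p5, d, wn800),
               oracle_jw_ext(0.8, 0.85, 1.2e-9, 4.3e-9, wn800),
               tolerance = 1e-12)
})

test_that("J(omega) is positive and non-increasing for random parameter sets", {
  set.seed(42)
  omega <- sort(c(0, 10^seq(6, 10, length.out = 25)))
  for (i in 1:30) {
    model <- sample(1:5, 1)
    p <- switch(model,
      model_free_params(1, s2 = runif(1, 0.05, 1)),
      model_free_params(2, s2 = runif(1, 0.05, 1),
                        tau_e_ps = runif(1, 1, 500)),
      model_free_params(3, s2 = runif(1, 0.05, 1), rex = runif(1, 0, 10)),
      model_free_params(4, s2 = runif(1, 0.05, 1),
                        tau_e_ps = runif(1, 1, 500), rex = runif(1, 0, 10)),
      model_free_params(5, s2f = runif(1, 0.3, 1), s2s = runif(1, 0.3, 1),
                        tau_s_ns = runif(1, 0.3, 2)))
    d <- diffusion_tensor("isotropic", runif(1, 1, 10))
    j <- spectral_density(p, d, omega)
    expect_true(all(j > 0))
    expect_true(all(diff(j) <= 1e-15))
  }
})

test_that("model nesting holds numerically", {
  d <- diffusion_tensor("isotropic", 4.3)
  w <- c(0, 5e8, 3e9, 5e9)
  # model 4 with rex = 0 equals model 2 in J (rex only enters R2)
  f <- spectrometer_field(800)
  p4 <- model_free_params(4, s2 = 0.8, tau_e_ps = 70, rex = 0)
  p2 <- model_free_params(2, s2 = 0.8, tau_e_ps = 70)
  t4 <- predict_relaxation(p4, d, f)
  t2 <- predict_relaxation(p2, d, f)
  expect_equal(t4$r2, t2$r2, tolerance = 1e-14)
  # model 5 with s2f = 1 reduces to model 2 with tau_e = tau_s
  p5 <- model_free_params(5, s2f = 1, s2s = 0.8, tau_s_ns = 0.9)
  p2b <- model_free_params(2, s2 = 0.8, tau_e_ps = 900)
  expect_equal(spectral_density(p5, d, w), spectral_density(p2b, d, w),
               tolerance = 1e-14)
})

test_that("axially symmetric form needs an orientation and reduces to isotropic", {
  p <- model_free_params(1, s2 = 0.9)
  da <- diffusion_tensor("axially_symmetric", 5, anisotropy = 1.4,
                         axis_theta = 0.5, axis_phi = 0.2)
  expect_error(spectral_density(p, da, 1e8), "orientation")
  # anisotropy -> 1 recovers the isotropic value for any orientation
  d1 <- diffusion_tensor("axially_symmetric", 5, anisotropy = 1 + 1e-12)
  di <- diffusion_tensor("isotropic", 5)
  w <- c(0, 1e8, 3e9)
  expect_equal(spectral_density(p, d1, w, nh_orientation = c(1, 2, 3)),
               spectral_density(p, di, w), tolerance = 1e-9)
  # orientation weights sum to one: J along any NH direction is a convex
  # combination, so it must lie between the extreme-axis values
  j_par <- spectral_density(p, da, 1e8, nh_orientation = c(0, 0, 1) +
                              c(sin(0.5) * cos(0.2), sin(0.5) * sin(0.2),
                                cos(0.5)) - c(0, 0, 1))
  expect_true(is.finite(j_par))
})

test_that("predicted triple matches the brute-force oracle on a random grid", {
  set.seed(7)
  for (i in 1:50) {
    s2 <- runif(1, 0.3, 1)
    te <- runif(1, 0, 200)
    tr_ns <- runif(1, 2, 8)
    f_mhz <- sample(c(500, 600, 700, 800, 950), 1)
    p <- model_free_params(2, s2 = s2, tau_e_ps = te)
    d <- diffusion_tensor("isotropic", tr_ns)
    got <- predict_relaxation(p, d, spectrometer_field(f_mhz))
    want <- oracle_relaxation(s2, te, tr_ns, f_mhz)
    expect_equal(got$r1, want$r1, tolerance = 1e-10)
    expect_equal(got$r2, want$r2, tolerance = 1e-10)
    expect_equal(got$noe, want$noe, tolerance = 1e-10)
  }
})

test_that("exchange adds to R2 exactly and only to R2", {
  d <- diffusion_tensor("isotropic", 5)
  f <- spectrometer_field(800)
  p0 <- model_free_params(2, s2 = 0.85, tau_e_ps = 30)
  p4 <- model_free_params(4, s2 = 0.85, tau_e_ps = 30, rex = 4,
                          rex_field_mhz = 800)
  t0 <- predict_relaxation(p0, d, f)
  t4 <- predict_relaxation(p4, d, f)
  expect_equal(t4$r2 - t0$r2, 4)
  expect_equal(t4$r1, t0$r1)
  expect_equal(t4$noe, t0$noe)
})

test_that("extreme narrowing limit matches the closed-form oracle", {
  p <- model_free_params(1, s2 = 1)
  d <- diffusion_tensor("isotropic", 1e-3)
  got <- predict_relaxation(p, d, spectrometer_field(800))
  want <- oracle_relaxation(1, 0, 1e-3, 800)
  expect_equal(got$noe, want$noe, tolerance = 1e-10)
  # R1 ~ R2 in extreme narrowing
  expect_equal(got$r1 / got$r2, 1, tolerance = 0.05)
})

test_that("R2 >= R1 in the slow-tumbling rigid regime", {
  p <- model_free_params(1, s2 = 1)
  for (tr in c(1, 2, 5, 10)) {
    t800 <- predict_relaxation(p, diffusion_tensor("isotropic", tr),
                               spectrometer_field(800))
    expect_gt(t800$r2, t800$r1)
  }
})

test_that("rex field scaling is quadratic, exact and invertible", {
  expect_equal(rex_at_field(3.0, 800, 600), 1.6875)
  expect_equal(round(rex_at_field(3.0, 800, 600), 1), 1.7)
  expect_equal(rex_at_field(3.0, 800, 700), 2.296875)
  expect_equal(round(rex_at_field(3.0, 800, 700), 1), 2.3)
  expect_equal(rex_at_field(3.0, 800, 800), 3.0)
  # round trip within one ulp
  x <- 3.123456789
  expect_equal(rex_at_field(rex_at_field(x, 800, 600), 600, 800), x,
               tolerance = 1e-15)
  expect_error(rex_at_field(3, -800, 600), "positive")
})

test_that("constants and containers validate their inputs", {
  expect_error(nuclear_constants(r_nh_angstrom = -1), "positive")
  expect_error(spectrometer_field(-600), "positive")
  expect_error(model_free_params(2, s2 = 0.8), "tau_e")
  expect_error(model_free_params(1, s2 = 0.8, rex = 2), "not a parameter")
  expect_error(model_free_params(5, s2 = 0.9, s2f = 0.8, s2s = 0.9,
                                 tau_s_ns = 1), "s2f \\* s2s")
  expect_error(model_free_params(3, s2 = 1.2, rex = 1), "\\[0, 1\\]")
  expect_error(diffusion_tensor("isotropic", 4, anisotropy = 1.3),
               "anisotropy")
  # omega_N / omega_H equals the gyromagnetic ratio (sign preserved)
  f <- spectrometer_field(800)
  nc <- nuclear_constants()
  expect_equal(f$omega_n / f$omega_h, nc$gamma_n / nc$gamma_h)
  expect_lt(f$omega_n, 0)
})
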