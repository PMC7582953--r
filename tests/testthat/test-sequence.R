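# Temperature coefficients, H/D exchange, methanol thermometer,
# sequence descriptors.

test_that("temperature coefficients recover exact linear inputs", {
  t_c <- c(20, 25, 30, 35, 40, 45)
  flat <- temp_coefficient(t_c, rep(8.30, 6))
  expect_equal(flat$slope_ppb_k, 0)
  expect_true(flat$hbond_candidate)          # 0 > -4.5

  lin <- temp_coefficient(t_c, 8.5 - 6.0e-3 * t_c)
  expect_equal(lin$slope_ppb_k, -6.0, tolerance = 1e-9)
  expect_false(lin$hbond_candidate)
  expect_equal(lin$r_squared, 1, tolerance = 1e-9)
})

test_that("the -4.5 ppb/K boundary is exclusive and noise is handled", {
  t_c <- c(20, 25, 30, 35, 40, 45)
  exact <- temp_coefficient(t_c, 8.5 - 4.5e-3 * t_c)
  expect_false(exact$hbond_candidate)        # exactly -4.5 is not a candidate
  set.seed(77)
  noisy <- temp_coefficient(t_c, 8.5 - 4.5e-3 * t_c + rnorm(6, 0, 0.003))
  expect_lt(abs(noisy$slope_ppb_k - (-4.5)), 3 * noisy$slope_err)
  expect_error(temp_coefficient(c(20, 20, 20), c(8, 8, 8)), "distinct")
})

test_that("slope is invariant to shift offset and linear in shift scaling", {
  t_c <- c(20, 30, 40)
  s <- c(8.40, 8.35, 8.28)
  a <- temp_coefficient(t_c, s)
  b <- temp_coefficient(t_c, s + 1.23)
  expect_equal(a$slope_ppb_k, b$slope_ppb_k, tolerance = 1e-12)
  d <- temp_coefficient(t_c, 2 * s)
  expect_equal(d$slope_ppb_k, 2 * a$slope_ppb_k, tolerance = 1e-9)
})

test_that("H/D half-exchange times and the 20-minute rule", {
  t <- c(2, 5, 10, 20, 40, 80, 160)
  at20 <- hd_half_exchange(t, exp(-log(2) * t / 20))
  expect_equal(at20$half_time_min, 20, tolerance = 1e-6)
  expect_false(at20$slow_exchange)           # strict threshold
  at60 <- hd_half_exchange(t, exp(-log(2) * t / 60))
  expect_equal(at60$half_time_min, 60, tolerance = 1e-6)
  expect_true(at60$slow_exchange)
  set.seed(31)
  noisy <- hd_half_exchange(t, exp(-log(2) * t / 35) *
                              (1 + rnorm(length(t), 0, 0.02)))
  expect_equal(noisy$half_time_min, 35, tolerance = 0.1 * 35)
  expect_warning(flat <- hd_half_exchange(t, seq(1, 2, length.out = 7)),
                 "do not decay")
  expect_false(flat$decaying)
})

test_that("methanol thermometer matches the published polynomial and inverts", {
  for (dd in c(1.3, 1.5, 1.8, 2.1))
    expect_equal(methanol_temperature(dd), oracle_methanol_t(dd),
                 tolerance = 1e-12)
  # monotone decreasing: larger shift difference = colder
  expect_gt(methanol_temperature(1.3), methanol_temperature(1.6))
  # round trip T -> dd -> T
  for (tk in c(285, 300, 315, 328)) {
    dd <- methanol_shift_difference(tk)
    expect_equal(methanol_temperature(dd), tk, tolerance = 0.1)
  }
  expect_error(methanol_temperature(0.5), "range")
  expect_error(methanol_temperature(3.5), "range")
})

test_that("sequence profiles: hydropathy extremes, charges, His census", {
  poly_i <- sequence_profile(strrep("I", 20))
  expect_equal(poly_i$mean_kd_index, 4.5)
  poly_r <- sequence_profile(strrep("R", 20))
  expect_equal(poly_r$mean_kd_index, -4.5)
  expect_equal(poly_r$positive_count, 21L)   # 20 Arg + N-terminus
  expect_equal(poly_r$negative_count, 1L)    # C-terminus only

  gh <- sequence_profile("GH")
  expect_equal(gh$his_count, 1L)
  expect_equal(gh$mean_kd_index, (-0.4 + -3.2) / 2)

  expect_error(sequence_profile("ACXDE"), "position\\(s\\): 3")
})

test_that("sequence profile mean is permutation invariant and composes", {
  s1 <- "ACDEFGHIKL"
  s2 <- "MNPQRSTVWY"
  p1 <- sequence_profile(s1)
  p2 <- sequence_profile(s2)
  perm <- sequence_profile(paste(rev(strsplit(s1, "")[[1]]), collapse = ""))
  expect_equal(perm$mean_kd_index, p1$mean_kd_index)
  both <- sequence_profile(paste0(s1, s2))
  expect_equal(both$mean_kd_index,
               (10 * p1$mean_kd_index + 10 * p2$mean_kd_index) / 20)
})
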