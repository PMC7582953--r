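# Threshold classification, R1*R2 indicator, region aggregation.

test_that("exchange thresholds reproduce the printed field series", {
  expect_equal(as.numeric(rex_threshold(800)), 3.0)
  expect_equal(attr(rex_threshold(700), "reported"), 2.3)
  expect_equal(as.numeric(rex_threshold(700)), 2.296875)
  expect_equal(attr(rex_threshold(600), "reported"), 1.7)
  expect_equal(as.numeric(rex_threshold(600)), 1.6875)
  expect_equal(as.numeric(rex_threshold(400)), 0.75)
  expect_equal(as.numeric(rex_threshold(600)) / as.numeric(rex_threshold(800)),
               0.5625)
})

test_that("classification rules follow the S2 and rex thresholds", {
  expect_identical(classify_residue(model_free_params(1, s2 = 0.66)),
                   "fast_ps_ns")
  expect_identical(
    classify_residue(model_free_params(3, s2 = 0.9, rex = 4,
                                       rex_field_mhz = 800)),
    "us_ms_exchange")
  # model 5: any of S2f, S2s (or product) below 0.8 counts as fast motion
  expect_true("fast_ps_ns" %in% classify_residue(
    model_free_params(5, s2f = 0.75, s2s = 0.95, tau_s_ns = 1)))
  # boundary is exclusive: S2 = 0.8 and rex = threshold are not flagged
  expect_identical(classify_residue(model_free_params(1, s2 = 0.8)),
                   "ordered")
  expect_identical(
    classify_residue(model_free_params(3, s2 = 0.85, rex = 3.0,
                                       rex_field_mhz = 800)),
    "ordered")
  # rex measured at 600 MHz is rescaled before comparison
  expect_identical(
    classify_residue(model_free_params(3, s2 = 0.85, rex = 2.0,
                                       rex_field_mhz = 600)),
    "us_ms_exchange")
  # flags
  expect_identical(classify_residue(NULL, flags = "proline"), "no_data")
  expect_setequal(
    classify_residue(model_free_params(1, s2 = 0.7),
                     flags = c("doubled", "broadened")),
    c("fast_ps_ns", "ms_s_two_conformers", "broadened"))
  # no_data excludes everything else
  expect_identical(classify_residue(model_free_params(1, s2 = 0.5),
                                    flags = "overlapped"), "no_data")
})

test_that("classification is a pure function of its inputs", {
  p <- model_free_params(4, s2 = 0.7, tau_e_ps = 40, rex = 5)
  l1 <- classify_residue(p, flags = "doubled")
  l2 <- classify_residue(p, flags = "doubled")
  expect_identical(l1, l2)
})

test_that("R1*R2 indicator flags exactly the exchange sites of a synthetic set", {
  # homogeneous noiseless baseline: the exchange bump dominates the
  # population statistics, so the rule isolates the planted sites exactly
  spec <- dynamics_profile_spec(
    n_residues = 40, seed = 17,
    scheme = region_scheme(6:10, 12:18, 20:25, residue_ids = 1:40),
    s2_by_region = list(head = c(0.85, 0.005), loop_i = c(0.85, 0.005),
                        loop_ii = c(0.85, 0.005), loop_iii = c(0.85, 0.005),
                        c_tail = c(0.85, 0.005)),
    n_rex = 5, rex_range_s1 = c(6, 6.0001),
    n_doubled = 0, n_broadened = 0, n_proline = 0)
  prof <- make_profile(spec)
  ds <- simulate_dataset(prof, spec, noise = FALSE)
  ind <- r1r2_indicator(ds)
  truth <- prof$residue_id[!is.na(prof$rex)]
  expect_setequal(ind$residue_id[ind$elevated], truth)
})

test_that("uniform rigid protein yields no R1*R2 flags; tiny sets warn", {
  spec <- dynamics_profile_spec(
    n_residues = 30, seed = 4, scheme = small_scheme(),
    s2_by_region = list(head = c(0.88, 0), loop_i = c(0.88, 0),
                        loop_ii = c(0.88, 0), loop_iii = c(0.88, 0),
                        c_tail = c(0.88, 0)),
    n_rex = 0, n_doubled = 0, n_broadened = 0, n_proline = 0)
  prof <- make_profile(spec)
  prof$model <- 1L
  prof$tau_e_ps <- NA_real_
  ds <- simulate_dataset(prof, spec, noise = FALSE)
  ind <- r1r2_indicator(ds)
  expect_false(any(ind$elevated))

  one <- single_residue_dataset(model_free_params(1, s2 = 0.9))
  expect_warning(ind1 <- r1r2_indicator(one), "too few")
  expect_false(any(ind1$elevated))
})

test_that("region schemes partition the sequence and validate overlaps", {
  sch <- region_scheme(6:16, 26:45, 55:70, c_tail = 86:100,
                       residue_ids = 1:100)
  all_assigned <- c(unlist(sch$regions), sch$excluded)
  expect_setequal(all_assigned, 1:100)
  expect_false(1 %in% unlist(sch$regions))   # first residue excluded
  expect_error(region_scheme(1:10, 5:20, 30:40, residue_ids = 1:50),
               "overlap")
  expect_error(region_scheme(6:16, 26:45, 55:70, residue_ids = 1:60),
               "outside")
})

test_that("region means aggregate correctly and warn on empty regions", {
  sch <- region_scheme(6:16, 26:45, 55:70, c_tail = 86:100,
                       residue_ids = 1:100)
  vals <- setNames(rep(0.8, 100), 1:100)
  rm <- region_mean(vals, sch)
  expect_true(all(abs(rm$mean - 0.8) < 1e-12))
  expect_equal(rm$n_available, rm$n_total)

  # exact recovery of a two-level profile
  vals2 <- setNames(ifelse(1:100 %in% sch$regions$loop_iii, 0.6, 0.9), 1:100)
  rm2 <- region_mean(vals2, sch)
  expect_equal(rm2$mean[rm2$region == "loop_iii"], 0.6)
  expect_equal(rm2$mean[rm2$region == "head"], 0.9)

  # linearity and permutation invariance
  perm <- sample(100)
  rm3 <- region_mean(vals2[perm], sch)
  expect_equal(rm3$mean, rm2$mean)
  rm4 <- region_mean(2 * vals2 + 1, sch)
  expect_equal(rm4$mean, 2 * rm2$mean + 1)

  # region with no data -> NA mean plus warning, n_available reported
  vals5 <- vals2[!(as.integer(names(vals2)) %in% sch$regions$loop_ii)]
  expect_warning(rm5 <- region_mean(vals5, sch), "loop_ii")
  expect_true(is.na(rm5$mean[rm5$region == "loop_ii"]))
  expect_equal(rm5$n_available[rm5$region == "loop_ii"], 0)
  expect_equal(rm5$n_total[rm5$region == "loop_ii"], 20)
})
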