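# Ensemble superposition and disorder metrics.

sch20 <- region_scheme(4:6, 9:12, 14:17, residue_ids = 1:20)

test_that("identical models superpose to themselves with zero disorder", {
  ens <- simulate_ensemble(20, sch20,
                           sigma_by_region = c(head = 0, loop_i = 0,
                                               loop_ii = 0, loop_iii = 0,
                                               c_tail = 0),
                           sigma_default = 0, seed = 1)
  al <- superpose_ensemble(ens, selection = sch20$regions$head)
  expect_equal(al$coords, ens$coords, tolerance = 1e-9)
  expect_equal(attr(al, "mean_structure"),
               ens$coords[, , 1], tolerance = 1e-9,
               ignore_attr = TRUE)
  dp <- disorder_profile(al, sch20)
  expect_true(all(dp$per_residue$displacement < 1e-9))
  expect_true(all(dp$per_region$rmsd < 1e-9))
})

test_that("arbitrary rigid motions are removed by superposition", {
  ens <- simulate_ensemble(20, sch20,
                           sigma_by_region = c(head = 0, loop_i = 0,
                                               loop_ii = 0, loop_iii = 0,
                                               c_tail = 0),
                           sigma_default = 0, seed = 2)
  set.seed(33)
  rotmat <- function() {
    th <- runif(3, 0, 2 * pi)
    rz <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
    ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0,
                   -sin(th[2]), 0, cos(th[2])), 3, 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cos(th[3]), -sin(th[3]),
                   0, sin(th[3]), cos(th[3])), 3, 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  for (m in seq_len(n_models(ens)))
    ens$coords[, , m] <- ens$coords[, , m] %*% rotmat() +
      matrix(runif(3, -20, 20), nrow(ens$atoms), 3, byrow = TRUE)
  al <- superpose_ensemble(ens, selection = sch20$regions$head)
  # post-superposition pairwise RMSD ~ 0
  d <- al$coords[, , 1] - al$coords[, , 10]
  expect_lt(sqrt(mean(rowSums(d^2))), 1e-9)
})

test_that("RMSD metrics are invariant under a global rigid motion", {
  ens <- simulate_ensemble(20, sch20, seed = 5)
  al1 <- superpose_ensemble(ens, selection = sch20$regions$head)
  rot <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- ens
  for (m in seq_len(n_models(moved)))
    moved$coords[, , m] <- moved$coords[, , m] %*% rot +
      matrix(c(5, -3, 11), nrow(moved$atoms), 3, byrow = TRUE)
  al2 <- superpose_ensemble(moved, selection = sch20$regions$head)
  expect_equal(disorder_profile(al2, sch20)$per_region$rmsd,
               disorder_profile(al1, sch20)$per_region$rmsd,
               tolerance = 1e-9)
})

test_that("selection atoms align tightly while displaced regions keep their amplitude", {
  ens <- simulate_ensemble(20, sch20,
                           sigma_by_region = c(head = 0, loop_i = 0,
                                               loop_ii = 2.0, loop_iii = 0,
                                               c_tail = 0),
                           sigma_default = 0, seed = 8)
  al <- superpose_ensemble(ens, selection = sch20$regions$head)
  dp <- disorder_profile(al, sch20)
  expect_lt(dp$per_region$rmsd[dp$per_region$region == "head"], 0.2)
  expect_equal(dp$per_region$rmsd[dp$per_region$region == "loop_ii"],
               2.0 * sqrt(3), tolerance = 0.15)
})

test_that("region RMSD estimates sigma*sqrt(3) within 10% at 20 models", {
  ens <- simulate_ensemble(20, sch20,
                           sigma_by_region = c(head = 0.2, loop_i = 0.8,
                                               loop_ii = 1.5, loop_iii = 1.5,
                                               c_tail = 0.2),
                           sigma_default = 0.2, seed = 12)
  al <- superpose_ensemble(ens, selection = sch20$regions$head)
  dp <- disorder_profile(al, sch20)
  per <- dp$per_region
  for (rg in c("loop_i", "loop_ii", "loop_iii")) {
    sigma <- c(loop_i = 0.8, loop_ii = 1.5, loop_iii = 1.5)[[rg]]
    expect_equal(per$rmsd[per$region == rg], sigma * sqrt(3),
                 tolerance = 0.10)
  }
  # ordering: loops more disordered than the head
  expect_true(all(per$rmsd[per$region != "head"] >
                    per$rmsd[per$region == "head"]))
})

test_that("union-region RMSD lies between the two region values", {
  ens <- simulate_ensemble(20, sch20, seed = 19)
  al <- superpose_ensemble(ens, selection = sch20$regions$head)
  dp <- disorder_profile(al, sch20)
  per <- dp$per_region
  union_scheme <- region_scheme(c(4:6, 9:12), 14:17, 18:19,
                                residue_ids = 1:20)
  dp_u <- disorder_profile(al, union_scheme)
  u <- dp_u$per_region$rmsd[dp_u$per_region$region == "loop_i"]
  a <- per$rmsd[per$region == "loop_i"]
  b <- per$rmsd[per$region == "loop_ii"]
  expect_gte(u, min(a, b))
  expect_lte(u, max(a, b))
})

test_that("generator determinism and input validation", {
  e1 <- simulate_ensemble(5, sch20, seed = 99)
  e2 <- simulate_ensemble(5, sch20, seed = 99)
  expect_identical(e1$coords, e2$coords)
  expect_error(simulate_ensemble(1, sch20, seed = 1), "n_models")
  expect_error(simulate_ensemble(5, sch20, sigma_default = -1, seed = 1),
               "non-negative")
  expect_error(simulate_ensemble(5, sch20), "seed")

  ens <- simulate_ensemble(3, sch20, seed = 1)
  expect_error(superpose_ensemble(ens, selection = 900:905), "absent")
  al <- superpose_ensemble(ens)
  bad_scheme <- region_scheme(4:6, 9:12, 25:30, residue_ids = 1:40)
  expect_error(disorder_profile(al, bad_scheme), "absent")
  expect_error(disorder_profile(ens, sch20), "not superposed")
})

test_that("NH orientations are unit vectors roughly along the amide direction", {
  ens <- simulate_ensemble(2, sch20,
                           sigma_by_region = c(head = 0, loop_i = 0,
                                               loop_ii = 0, loop_iii = 0,
                                               c_tail = 0),
                           sigma_default = 0, seed = 3)
  nh <- nh_orientations(ens)
  expect_true(all(is.na(nh["1", ])))          # no preceding carbonyl
  norms <- sqrt(rowSums(nh[-1, ]^2))
  expect_equal(unname(norms), rep(1, nrow(nh) - 1), tolerance = 1e-9)
})
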