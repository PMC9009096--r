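# Deterministic generators: water spheres, solute insertion, synthetic
# feature trajectories.

test_that("molecule counts follow the density-volume arithmetic", {
  # N = rho V / m for water at 0.997 g/cm^3
  expect_equal(n_molecules_at_density(8.5, 0.997), 86L)
  # doubling the radius multiplies N by 8 within rounding
  n1 <- n_molecules_at_density(8.5)
  n2 <- n_molecules_at_density(17)
  expect_lt(abs(n2 - 8 * n1), 8)
})

test_that("built spheres satisfy the builder post-conditions", {
  sys <- build_water_sphere(build_spec("SPC", 8.5, 0.997, seed = 1))
  expect_equal(nrow(sys$com), 86L)
  expect_true(all(rowSums(sys$com^2) < 8.5^2))
  # no intermolecular close contacts after relaxation
  D <- as.matrix(dist(sys$positions))
  mol <- sys$topology$atoms$mol
  D[outer(mol, mol, "==")] <- Inf
  expect_gt(min(D), 1.5)
  # O-H geometry preserved by the rigid representation
  wm <- water_model("SPC")
  oh <- sqrt(sum((sys$positions[1, ] - sys$positions[2, ])^2))
  expect_equal(oh, wm$r_OH, tolerance = 1e-9)
  # pure function of (spec, seed)
  sys2 <- build_water_sphere(build_spec("SPC", 8.5, 0.997, seed = 1))
  expect_identical(sys$positions, sys2$positions)
  sys3 <- build_water_sphere(build_spec("SPC", 8.5, 0.997, seed = 2))
  expect_false(identical(sys$positions, sys3$positions))
})

test_that("unreachable densities fail with a clear error", {
  expect_error(build_water_sphere(build_spec("SPC", 6, 3.5, seed = 1)),
               "cannot place")
})

test_that("solute insertion removes exactly the overlapping solvent", {
  sys <- build_water_sphere(build_spec("SPC", 8.5, 0.997, seed = 1))
  sol <- toy_solute()
  out <- insert_solute(sys, sol)
  # removed count equals a brute-force overlap scan
  removed_bf <- 0
  st <- sol$topology
  sp <- sweep(sol$positions, 2,
              colMeans(sol$positions[st$atoms$mass > 0, ]))
  for (m in seq_len(nrow(sys$com))) {
    idx <- which(sys$topology$atoms$mol == m)
    hit <- FALSE
    for (i in idx) for (j in seq_len(nrow(sp))) {
      cut <- 0.5 * (sys$topology$atoms$sigma[i] + st$atoms$sigma[j])
      if (sqrt(sum((sys$positions[i, ] - sp[j, ])^2)) < cut) hit <- TRUE
    }
    removed_bf <- removed_bf + hit
  }
  expect_equal(out$removed, removed_bf)
  expect_gt(out$removed, 0)
  # the solute is the last, frozen molecule
  nm <- nrow(out$com)
  expect_false(out$free[nm])
  expect_true(all(out$free[-nm]))
  # idempotence: re-inserting into the already-carved system removes nothing
  out2 <- insert_solute(out, sol)
  expect_equal(out2$removed, 1L)  # only the previous solute copy overlaps
  # a solute larger than the cavity is rejected
  big <- sol
  big$positions <- sol$positions * 20
  expect_error(insert_solute(sys, big), "fit inside")
})

test_that("point solute with no excluded volume removes nothing", {
  sys <- build_water_sphere(build_spec("SPC", 8.5, 0.50, seed = 2))
  pt <- list(topology = topology(mass = 1, charge = 0, sigma = 0, epsilon = 0,
                                 mol = 1L, name = "P"),
             positions = matrix(c(4, 4, 4), 1, 3))
  out <- insert_solute(sys, pt)
  expect_equal(out$removed, 0L)
  expect_equal(nrow(out$com), nrow(sys$com) + 1L)
})

test_that("synthetic feature trajectories have the planted structure", {
  means <- rbind(c(0, 0, 0, 0), c(5, 5, 0, 0))
  s <- synth_feature_trajectory(means, sds = 1, weights = c(0.48, 0.52),
                                n_frames = 941, seed = 3)
  n1 <- sum(s$labels == 1)
  p <- 0.48
  expect_lt(abs(n1 - 941 * p), 3 * sqrt(941 * p * (1 - p)))
  # zero covariance: exact repeated means
  s0 <- synth_feature_trajectory(means, sds = 0, n_frames = 10, seed = 4)
  expect_true(all(s0$features[s0$labels == 1, 1] == 0))
  expect_true(all(s0$features[s0$labels == 2, 1] == 5))
  # fixed seed: bit-identical
  a <- synth_feature_trajectory(means, 1, c(0.5, 0.5), 50, seed = 5)
  b <- synth_feature_trajectory(means, 1, c(0.5, 0.5), 50, seed = 5)
  expect_identical(a$features, b$features)
})

test_that("built spheres stay finite under short dynamics", {
  sys <- build_water_sphere(build_spec("TIP3P-FB", 7, 0.997, seed = 6))
  cfg <- simulation_config("NVT", dt = 0.001, n_steps = 1000, tau_t = 0.4,
                           traj_stride = 1000, log_stride = 200, seed = 7)
  run <- run_simulation(sys, cfg)
  expect_true(all(is.finite(run$log$T)))
  expect_true(all(is.finite(run$final$positions)))
})
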