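# Conductor-like reaction field of a single spherical cavity: projection,
# diagonal solve, energies, forces and the volume derivative, all pinned to
# the closed-form conductor (image-charge) oracle and finite differences.

ke <- npbc_constants$k_e
g302 <- build_lebedev_grid(302)
g110 <- build_lebedev_grid(110)

test_that("potential projection: symmetry selects the expected coefficients", {
  cav <- spherical_cavity(10)
  b <- harmonic_basis(6)
  # centered charge: only the monopole survives
  phi <- potential_coeffs(charge_distribution(1, matrix(0, 1, 3)), cav,
                          g110, b)
  expect_equal(phi[1], ke * sqrt(4 * pi) / 10, tolerance = 1e-10)
  expect_lt(max(abs(phi[-1])), 1e-10)
  # charge on the z axis: m = 0 only, magnitudes fall off as (r/R)^l; at
  # r/R = 0.3 the multipole tail beyond the 302-rule precision is negligible
  phi <- potential_coeffs(charge_distribution(1, matrix(c(0, 0, 3), 1, 3)),
                          cav, g302, b)
  for (l in 0:6) {
    expect_equal(phi[sh_index(l, 0)],
                 ke * 4 * pi / (2 * l + 1) * 0.3^l / 10 *
                   sqrt((2 * l + 1) / (4 * pi)),
                 tolerance = 1e-9)
    if (l > 0) expect_lt(max(abs(phi[sh_index(l, setdiff(-l:l, 0))])), 1e-8)
  }
  # parity: equal charges at +/- z kill the odd-l coefficients
  phi <- potential_coeffs(charge_distribution(c(1, 1),
                                              rbind(c(0, 0, 4), c(0, 0, -4))),
                          cav, g110, b)
  odd <- unlist(lapply(c(1, 3, 5), function(l) sh_index(l, -l:l)))
  expect_lt(max(abs(phi[odd])), 1e-12)
})

test_that("ASC solve is linear, diagonal, and zero for zero potential", {
  cav <- spherical_cavity(10)
  expect_equal(solve_asc(numeric(16), cav), numeric(16))
  set.seed(1)
  a <- rnorm(16); b <- rnorm(16)
  expect_equal(solve_asc(2 * a + 3 * b, cav),
               2 * solve_asc(a, cav) + 3 * solve_asc(b, cav),
               tolerance = 1e-12)
})

test_that("Born conductor limit: centered and off-center closed forms", {
  cav <- spherical_cavity(10)
  d0 <- charge_distribution(1, matrix(0, 1, 3))
  rf <- reaction_field(d0, cav, g302, harmonic_basis(10))
  expect_equal(rf$energy, -ke / 20, tolerance = 1e-10)
  expect_lt(max(abs(rf$forces)), 1e-10)
  expect_equal(rf$dE_dV, ke / (8 * pi * 10^4), tolerance = 1e-8)
  # monotone convergence to the summed Kirkwood series, rel 1e-4 at l_max 16
  for (t in c(0.2, 0.5)) {
    dt_ <- charge_distribution(1, matrix(c(0, 0, 10 * t), 1, 3))
    exact <- born_offcenter_energy(1, 10 * t, 10)
    prev <- 0
    for (lm in c(4, 8, 16)) {
      e <- suppressWarnings(
        reaction_field(dt_, cav, g302, harmonic_basis(lm))$energy)
      expect_lt(e, prev)      # each added l lowers the energy
      prev <- e
    }
    expect_rel_equal(prev, exact, 1e-4)
  }
  # l_max = 0 truncation equals the centered-charge (pure Born) value
  d5 <- charge_distribution(1, matrix(c(0, 0, 5), 1, 3))
  e0 <- reaction_field(d5, cav, g302, harmonic_basis(0))$energy
  expect_equal(e0, -ke / 20, tolerance = 1e-10)
})

test_that("energy is rotation invariant and scales quadratically in charge", {
  cav <- spherical_cavity(8)
  set.seed(11)
  pos <- matrix(rnorm(12, sd = 1.3), 4, 3)   # interior: |r|/R <= ~0.5
  q <- runif(4, -1, 1)
  b <- harmonic_basis(8)
  e1 <- reaction_field(charge_distribution(q, pos), cav, g302, b)$energy
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  e2 <- reaction_field(charge_distribution(q, pos %*% R), cav, g302, b)$energy
  expect_lt(abs(e1 - e2), 1e-10 * abs(e1))
  e4 <- reaction_field(charge_distribution(2 * q, pos), cav, g302, b)$energy
  expect_equal(e4, 4 * e1, tolerance = 1e-12)
  expect_lt(e1, 0)  # conductor energy strictly negative
})

test_that("forces and dE/dV pass central finite-difference checks", {
  cav <- spherical_cavity(10)
  b <- harmonic_basis(10)
  set.seed(3)
  pos <- matrix(rnorm(15, sd = 3), 5, 3)
  q <- runif(5, -1, 1)
  rf <- reaction_field(charge_distribution(q, pos), cav, g302, b)
  h <- 1e-4
  for (k in 1:5) for (a in 1:3) {
    pp <- pos; pp[k, a] <- pp[k, a] + h
    pm <- pos; pm[k, a] <- pm[k, a] - h
    fd <- -(reaction_field(charge_distribution(q, pp), cav, g302, b)$energy -
              reaction_field(charge_distribution(q, pm), cav, g302, b)$energy) /
      (2 * h)
    expect_rel_equal(rf$forces[k, a], fd, 1e-5)
  }
  # off-center single charge: force points away from the center
  d <- charge_distribution(1, matrix(c(0, 0, 5), 1, 3))
  f <- reaction_field(d, cav, g302, b)$forces
  expect_gt(f[1, 3], 0)
  expect_lt(max(abs(f[1, 1:2])), 1e-8)
  # rigid translation of a two-charge system: sum of forces matches the
  # translational derivative of the energy
  pos2 <- rbind(c(1, 0, 2), c(-1, 1, 1))
  q2 <- c(0.5, -0.8)
  rf2 <- reaction_field(charge_distribution(q2, pos2), cav, g302, b)
  for (a in 1:3) {
    sh <- c(0, 0, 0); sh[a] <- h
    ep <- reaction_field(charge_distribution(q2, sweep(pos2, 2, -sh)), cav,
                         g302, b)$energy
    em <- reaction_field(charge_distribution(q2, sweep(pos2, 2, sh)), cav,
                         g302, b)$energy
    expect_equal(sum(rf2$forces[, a]), -(ep - em) / (2 * h),
                 tolerance = 1e-5 * max(abs(rf2$forces)))
  }
  # volume derivative against [E(R+h) - E(R-h)] / dV
  hr <- 1e-4 * 10
  dist <- charge_distribution(q, pos)
  ep <- reaction_field(dist, spherical_cavity(10 + hr), g302, b)$energy
  em <- reaction_field(dist, spherical_cavity(10 - hr), g302, b)$energy
  fd <- (ep - em) / (4 / 3 * pi * ((10 + hr)^3 - (10 - hr)^3))
  expect_rel_equal(rf$dE_dV, fd, 1e-5)
  # zero charge distribution
  expect_equal(reaction_field(charge_distribution(0, matrix(0, 1, 3)), cav,
                              g302, b)$dE_dV, 0)
})

test_that("scaled dielectric mode applies f(eps) = (eps-1)/eps", {
  d0 <- charge_distribution(1, matrix(0, 1, 3))
  e78 <- reaction_field(d0, spherical_cavity(10, dielectric_mode = "scaled",
                                             epsilon = 78.36),
                        g302, harmonic_basis(4))$energy
  expect_equal(e78, -ke / 20 * (78.36 - 1) / 78.36, tolerance = 1e-10)
})

test_that("charges on or outside the boundary are rejected", {
  cav <- spherical_cavity(5)
  expect_error(charge_distribution(1, matrix(c(0, 0, 5), 1, 3), cav),
               "on or outside")
  expect_error(reaction_field(charge_distribution(1, matrix(c(0, 0, 7), 1, 3)),
                              cav, g302, harmonic_basis(4)),
               "on or outside")
})

test_that("spectral path agrees with the quadrature path for interior charges", {
  set.seed(5)
  pos <- matrix(rnorm(15, sd = 2), 5, 3)   # interior charges
  q <- runif(5, -1, 1)
  sp <- npbcmd:::cpp_reaction_field_spectral(pos, q, 10, c(0, 0, 0), 10L,
                                             g302$points, g302$weights, 1.0)
  qd <- reaction_field(charge_distribution(q, pos), spherical_cavity(10),
                       g302, harmonic_basis(10))
  expect_rel_equal(sp$energy, qd$energy, 1e-7)
  expect_lt(max(abs(sp$forces - qd$forces)), 1e-5)
  expect_rel_equal(sp$dEdV, qd$dE_dV, 1e-5)
})
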