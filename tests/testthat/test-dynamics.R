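# Integrators (velocity Verlet, RATTLE, rigid-body quaternion), thermostat,
# pressure and barostat, and the simulation driver.

test_that("velocity Verlet reproduces uniform acceleration exactly", {
  topo <- atom_gas_topology(1, mass = 10)
  fconst <- matrix(c(2, 0, -1), 1, 3)   # kJ/mol/A
  st <- list(positions = matrix(0, 1, 3), velocities = matrix(c(1, 0, 0), 1, 3),
             time = 0)
  for (i in 1:50) st <- velocity_verlet_step(st, topo, function(p) fconst, 0.01)
  acc <- fconst * 100 / 10
  t <- 0.5
  expect_equal(st$positions, matrix(c(1, 0, 0) * t + 0.5 * acc * t^2, 1, 3),
               tolerance = 1e-12)
})

test_that("velocity Verlet bounds the energy drift of a harmonic oscillator", {
  # force constant k = 100 kJ/mol/A^2, mass 10 amu -> period 2*pi/sqrt(k*100/m)
  k <- 100; m <- 10
  period <- 2 * pi / sqrt(k * 100 / m)
  dt <- period / 100
  topo <- atom_gas_topology(1, mass = m)
  st <- list(positions = matrix(c(0.3, 0, 0), 1, 3),
             velocities = matrix(0, 1, 3), time = 0)
  e <- function(s) 0.5 * k * s$positions[1, 1]^2 +
    0.5 * m * sum(s$velocities^2) * 0.01
  e0 <- e(st)
  es <- numeric(1000)
  for (i in 1:1000) {
    st <- velocity_verlet_step(st, topo, function(p) -k * p, dt)
    es[i] <- e(st)
  }
  # symplectic integrator: the energy error oscillates (O((w dt)^2)) but has
  # no secular drift
  expect_lt(abs(mean(es[901:1000]) - mean(es[1:100])) / e0, 1e-4)
  expect_lt(max(abs(es - e0)) / e0, 1e-3)
})

test_that("RATTLE restores constraints and conserves momentum", {
  m <- c(2, 3)
  cons <- matrix(c(1, 2, 1.5), 1, 3)
  # already satisfied: identity
  x <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  v <- rbind(c(0.1, 0.2, 0), c(0.1, -0.3, 0))
  v[, 1] <- c(0, 0)  # no relative velocity along the bond
  pr <- rattle_project(x, v, cons, m)
  expect_equal(pr$positions, x, tolerance = 1e-12)
  # stretched by 1%: restored, with momentum conserved
  x2 <- rbind(c(0, 0, 0), c(1.515, 0, 0))
  v2 <- rbind(c(0.2, 0, 0), c(-0.1, 0, 0))
  pr2 <- rattle_project(x2, v2, cons, m)
  expect_equal(sqrt(sum((pr2$positions[1, ] - pr2$positions[2, ])^2)), 1.5,
               tolerance = 1e-9)
  expect_equal(colSums(pr2$positions * m), colSums(x2 * m), tolerance = 1e-12)
  expect_equal(colSums(pr2$velocities * m), colSums(v2 * m), tolerance = 1e-12)
  r <- pr2$positions[1, ] - pr2$positions[2, ]
  expect_lt(abs(sum(r * (pr2$velocities[1, ] - pr2$velocities[2, ]))), 1e-9)
  # the three constraints of a water triangle are satisfied simultaneously
  geom <- rbind(c(0, 0, 0), c(1, 0, 0), c(-0.35, 0.95, 0))
  cons3 <- rbind(c(1, 2, 1.0), c(1, 3, 1.0), c(2, 3, 1.63))
  set.seed(5)
  x3 <- geom + matrix(rnorm(9, sd = 0.02), 3, 3)
  pr3 <- rattle_project(x3, matrix(rnorm(9), 3, 3), cons3, c(16, 1, 1))
  for (k in 1:3) {
    d <- sqrt(sum((pr3$positions[cons3[k, 1], ] -
                     pr3$positions[cons3[k, 2], ])^2))
    expect_equal(d, cons3[k, 3], tolerance = 1e-9)
  }
})

test_that("a RATTLE-constrained diatomic keeps its bond length for 1e4 steps", {
  topo <- topology(mass = c(2, 2), charge = c(0.2, -0.2), sigma = c(0, 0),
                   epsilon = c(0, 0), mol = c(1L, 1L),
                   constraints = matrix(c(1, 2, 1.2), 1, 3))
  st <- list(positions = rbind(c(0, 0, 0), c(1.2, 0, 0)),
             velocities = rbind(c(0, 0.5, 0), c(0, -0.5, 0.3)), time = 0)
  worst <- 0
  for (i in 1:10000) {
    st <- velocity_verlet_step(st, topo, function(p) 0 * p, 0.002)
    if (i %% 500 == 0)
      worst <- max(worst, abs(sqrt(sum((st$positions[1, ] -
                                          st$positions[2, ])^2)) - 1.2))
  }
  expect_lt(worst, 1e-9)
})

test_that("torque-free rigid rotors conserve L, energy and follow the polhode", {
  # symmetric top
  fr <- npbcmd:::cpp_free_rotor(c(2, 2, 5), c(1, 0, 0, 0), c(1, 2, 4),
                                0.001, 10000, 1e-9, 50)
  expect_lt(diff(range(fr$kinetic)) / fr$kinetic[1], 1e-8)
  # asymmetric top: energy conserved, body-frame L on the polhode curve
  I <- c(2, 5, 9); L0 <- c(3, 4, 5)
  fr2 <- npbcmd:::cpp_free_rotor(I, c(1, 0, 0, 0), L0, 0.001, 20000, 1e-9, 200)
  expect_lt(diff(range(fr2$kinetic)) / fr2$kinetic[1], 1e-6)
  # bounded oscillation, no secular drift
  nk <- length(fr2$kinetic)
  expect_lt(abs(mean(fr2$kinetic[(nk - 9):nk]) - mean(fr2$kinetic[1:10])) /
              fr2$kinetic[1], 1e-7)
  # polhode: |L| and 2*KE_rot define the intersection of sphere and ellipsoid;
  # check the body-frame angular momentum stays on both surfaces
  for (r in seq(1, nrow(fr2$quaternions), by = 20)) {
    q <- fr2$quaternions[r, ]
    lb <- crossprod(npbcmd:::quat_to_mat(q), L0)
    expect_equal(sum(lb^2), sum(L0^2), tolerance = 1e-8)
    expect_equal(0.5 * sum(lb^2 / I) * 0.01, fr2$kinetic[1], tolerance = 1e-6)
  }
  # cross-check a coarse step against a 20x finer reference propagation
  frc <- npbcmd:::cpp_free_rotor(I, c(1, 0, 0, 0), L0, 0.002, 500, 1e-12, 500)
  frf <- npbcmd:::cpp_free_rotor(I, c(1, 0, 0, 0), L0, 0.0001, 10000, 1e-12,
                                 10000)
  qc <- frc$quaternions[nrow(frc$quaternions), ]
  qf <- frf$quaternions[nrow(frf$quaternions), ]
  expect_lt(min(max(abs(qc - qf)), max(abs(qc + qf))), 5e-4)
  # zero angular momentum: orientation constant
  fr0 <- npbcmd:::cpp_free_rotor(c(1, 2, 3), c(0.5, 0.5, 0.5, 0.5),
                                 c(0, 0, 0), 0.01, 100, 1e-9, 100)
  expect_equal(fr0$quaternions[nrow(fr0$quaternions), ],
               c(0.5, 0.5, 0.5, 0.5), tolerance = 1e-12)
})

test_that("rigid_body_step conserves energy for an interacting rigid pair", {
  # two rigid diatomics with LJ sites, short NVE propagation in R
  topo <- topology(mass = rep(2, 4), charge = rep(0, 4),
                   sigma = rep(3, 4), epsilon = rep(0.3, 4),
                   mol = c(1L, 1L, 2L, 2L), name = rep("X", 4))
  pos <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(4.5, 0.3, 0), c(5.7, 0.5, 0.4))
  sys <- make_rigid_system(topo, pos, radius = 50)
  set.seed(12)
  sys <- init_velocities(sys, 150)
  ff <- function(p) pair_energy_forces(p, topo)$forces
  e <- function(s) pair_energy_forces(s$positions, topo)$energy +
    with(kinetic_info(s), translational + rotational)
  e0 <- e(sys)
  for (i in 1:400) sys <- rigid_body_step(sys, ff, 0.002)
  expect_lt(abs(e(sys) - e0) / abs(e0), 1e-4)
})

test_that("thermostat factor limits: decoupled, fixed point, canonical sampling", {
  expect_equal(bussi_thermostat(10, 100, 300, Inf, 0.002), 1)
  kbar <- 0.5 * 100 * npbc_constants$k_B * 300
  # deterministic part at K = Kbar with suppressed noise: scale exactly 1
  # with the noise pinned at its mean-square values (r1^2 + chisq = n_dof)
  expect_equal(bussi_thermostat(kbar, 100, 300, 0.5, 0.002, r1 = 0,
                                chisq = 100), 1, tolerance = 1e-12)
  # long ideal-gas run: kinetic energy follows the gamma(ndf/2) distribution
  set.seed(77)
  n <- 32
  pos <- matrix(runif(3 * n, -4, 4), n, 3)
  sys <- monatomic_system(pos, radius = 60, mass = 20)
  sys <- init_velocities(sys, 300)
  cfg <- simulation_config("NVT", dt = 0.01, n_steps = 16000, tau_t = 0.05,
                           temperature = 300, wall = FALSE, lj = FALSE,
                           coulomb = FALSE, traj_stride = 16000,
                           log_stride = 20, seed = 78)
  run <- run_simulation(sys, cfg, init_velocities = FALSE)
  ek <- run$log$E_kin[-(1:100)] / npbc_constants$k_B / 300  # in kT units
  ndf <- run$n_dof
  expect_equal(ndf, 3L * n)
  ks <- suppressWarnings(stats::ks.test(ek, function(q)
    stats::pgamma(q, shape = ndf / 2, rate = 1)))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(ek), ndf / 2, tolerance = 0.02 * ndf / 2)
})

test_that("pressure: ideal gas identity, one-term virial, LJ volume-scaling oracle", {
  kB <- npbc_constants$k_B
  n <- 50; T <- 320; R <- 12
  V <- 4 / 3 * pi * R^3
  ek <- 1.5 * n * kB * T
  expect_equal(pressure(ek, 0, V), n * kB * T / V * npbc_constants$p_bar,
               tolerance = 1e-12)
  expect_error(pressure(1, 0, -3), "positive")
  # single pair: W = r . F by hand
  topo <- atom_gas_topology(2, charge = 1)
  pos <- rbind(c(0, 0, 0), c(8, 0, 0))
  pf <- pair_energy_forces(pos, topo)
  expect_equal(pf$virial, 8 * pf$forces[2, 1] * -1 * -1, tolerance = 1e-10)
  expect_equal(pf$virial, npbc_constants$k_e / 8, tolerance = 1e-10)
  # mini LJ cluster: virial equals -3V dU/dV under uniform scaling
  set.seed(41)
  nn <- 20
  topo2 <- atom_gas_topology(nn, sigma = 3, eps = 0.5)
  p0 <- matrix(rnorm(3 * nn, sd = 4), nn, 3)
  u <- function(s) pair_energy_forces(p0 * s, topo2)$energy
  h <- 1e-6
  dUdlam <- (u(1 + h) - u(1 - h)) / (2 * h)   # dU/d(lambda), V ~ lambda^3
  w <- pair_energy_forces(p0, topo2)$virial
  expect_rel_equal(w, -dUdlam, 0.01)
})

test_that("weak-coupling barostat factor: fixed point, sign, plug-in arithmetic", {
  expect_equal(berendsen_scale(1000, 1000, 4, 0.002), 1)
  expect_gt(berendsen_scale(1500, 1000, 4, 0.002), 1)   # expand under excess P
  mu <- berendsen_scale(2000, 1000, 4.0, 0.002, beta = 4.5e-5, alpha = 1)
  expect_equal(mu, (1 + 4.5e-5 * (0.002 / 4) * 1000)^(1 / 3),
               tolerance = 1e-12)
  expect_warning(berendsen_scale(1e7, 1, 0.1, 0.1), "clamped")
})

test_that("driver: rest state stays at rest and trajectories are seed-reproducible", {
  sys <- small_water(0.1, radius = 8.5, seed = 3)
  cfg <- simulation_config("NVE", dt = 0.002, n_steps = 50, wall = FALSE,
                           traj_stride = 50, log_stride = 50, seed = NULL)
  # zero-temperature start, no thermostat: molecules only relax along forces;
  # a single isolated molecule feels no force and must not move
  one <- monatomic_system(matrix(c(1, 2, 0), 1, 3), radius = 10)
  r1 <- run_simulation(one, simulation_config("NVE", dt = 0.01, n_steps = 100,
                                              wall = FALSE, traj_stride = 100,
                                              log_stride = 100, seed = NULL),
                       init_velocities = FALSE)
  expect_equal(r1$final$positions, one$positions, tolerance = 1e-14)
  # bit-identical trajectories under the same seed
  cfg2 <- simulation_config("NVT", dt = 0.002, n_steps = 100, tau_t = 0.4,
                            traj_stride = 20, log_stride = 20, seed = 99)
  a <- run_simulation(sys, cfg2)
  b <- run_simulation(sys, cfg2)
  expect_identical(a$trajectory$positions, b$trajectory$positions)
  expect_identical(a$log, b$log)
})

test_that("NVE rigid water conserves total energy over 10 ps", {
  sys <- small_water(0.30, radius = 8.5, seed = 4)   # ~26 molecules
  set.seed(9)
  sys <- init_velocities(sys, 298.15)
  cfg <- simulation_config("NVE", dt = 0.001, n_steps = 10000, wall = FALSE,
                           traj_stride = 10000, log_stride = 100, seed = NULL)
  run <- run_simulation(sys, cfg, init_velocities = FALSE)
  etot <- run$log$E_pair + run$log$E_kin
  expect_lt((max(etot) - min(etot)) / mean(run$log$E_kin), 1e-3)
})

test_that("NVT equipartition: mean kinetic temperature within 1% of target", {
  sys <- small_water(0.5, radius = 8.5, seed = 6)
  cfg <- simulation_config("NVT", dt = 0.002, n_steps = 60000, tau_t = 0.4,
                           temperature = 298.15, traj_stride = 60000,
                           log_stride = 20, seed = 13)
  run <- run_simulation(sys, cfg)
  expect_gte(run$n_dof, 100)
  tmean <- mean(run$log$T[-(1:500)])
  expect_lt(abs(tmean - 298.15) / 298.15, 0.01)
})

test_that("NPT with an ideal gas relaxes the radius to the gas-law volume", {
  set.seed(21)
  n <- 40; T <- 300; P0 <- 200 # bar
  kB <- npbc_constants$k_B
  Vstar <- n * kB * T / (P0 / npbc_constants$p_bar)
  Rstar <- (3 * Vstar / (4 * pi))^(1 / 3)
  pos <- matrix(runif(3 * n, -3, 3), n, 3)
  sys <- monatomic_system(pos, radius = 1.35 * Rstar, mass = 20)
  cfg <- simulation_config("NPT", dt = 0.005, n_steps = 30000, tau_t = 0.1,
                           temperature = T, pressure = P0, tau_p = 1.0,
                           beta = 4.5e-3, lj = FALSE, coulomb = FALSE,
                           traj_stride = 30000, log_stride = 50, seed = 22)
  run <- run_simulation(sys, cfg)
  r_traj <- run$log$R
  # the radius relaxes toward Rstar and stays there on average
  expect_lt(abs(mean(tail(r_traj, 200)) - Rstar) / Rstar, 0.05)
  # the gap to the fixed point shrinks as the run progresses
  gaps <- abs(sapply(split(r_traj, cut(seq_along(r_traj), 6)), mean) - Rstar)
  expect_lt(gaps[6], 0.5 * gaps[1])
})
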