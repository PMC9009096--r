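# Pair interactions, virtual sites, boundary mean-field potential, rough wall.

test_that("Lennard-Jones zero crossing and Coulomb constant", {
  topo <- atom_gas_topology(2, sigma = 3.0, eps = 0.5)
  pos <- rbind(c(0, 0, 0), c(3.0, 0, 0))
  pf <- pair_energy_forces(pos, topo)
  expect_equal(pf$energy, 0, tolerance = 1e-12)
  expect_equal(abs(pf$forces[1, 1]), 24 * 0.5 / 3.0, tolerance = 1e-10)
  # two unit charges at 10 A
  topo2 <- atom_gas_topology(2, charge = 1)
  pf2 <- pair_energy_forces(rbind(c(0, 0, 0), c(10, 0, 0)), topo2)
  expect_equal(pf2$energy, 138.935458, tolerance = 1e-6)
  expect_equal(pf2$virial, pf2$energy, tolerance = 1e-10) # W = r.F = kq^2/r
})

test_that("internal forces sum to zero and overlaps are rejected", {
  set.seed(2)
  n <- 12
  topo <- atom_gas_topology(n, charge = rep(c(0.3, -0.3), 6), sigma = 3,
                            eps = 0.4)
  pos <- matrix(rnorm(3 * n, sd = 4), n, 3)
  pf <- pair_energy_forces(pos, topo)
  expect_lt(max(abs(colSums(pf$forces))), 1e-9)
  pos[2, ] <- pos[1, ] + 1e-8
  expect_error(pair_energy_forces(pos, topo), "overlap")
})

test_that("virtual sites: construction symmetry, idempotence, degeneracy", {
  topo <- topology(mass = c(12, 12, 14, 0, 0), charge = c(0, 0, 0, 0.1, 0.1),
                   sigma = rep(0, 5), epsilon = rep(0, 5), mol = rep(1L, 5),
                   name = c("C1", "C2", "N", "LP1", "LP2"),
                   virtual_sites = list(
                     list(site = 4L, parents = c(3L, 1L, 2L), a = 0.1, b = 0.1,
                          c = 0.3),
                     list(site = 5L, parents = c(3L, 1L, 2L), a = 0.1, b = 0.1,
                          c = -0.3)))
  pos <- rbind(c(1, 0.5, 0), c(-1, 0.5, 0), c(0, -0.5, 0), c(0, 0, 0),
               c(0, 0, 0))
  p1 <- project_virtual_sites(pos, topo)
  # +/- c sites are mirror images across the parent plane (z = 0)
  expect_equal(p1[4, 1:2], p1[5, 1:2])
  expect_equal(p1[4, 3], -p1[5, 3])
  expect_gt(abs(p1[4, 3]), 0)
  # repeated application is idempotent
  expect_equal(project_virtual_sites(p1, topo), p1)
  # zero-offset parameters place the site on its anchor parent
  topo0 <- topo; topo0$virtual_sites[[1]]$a <- 0
  topo0$virtual_sites[[1]]$b <- 0; topo0$virtual_sites[[1]]$c <- 0
  expect_equal(project_virtual_sites(pos, topo0)[4, ], pos[3, ])
  # collinear parents are degenerate for an out-of-plane rule
  expect_error(project_virtual_sites(rbind(c(1, 0, 0), c(-1, 0, 0),
                                           c(0, 0, 0), c(0, 0, 0),
                                           c(0, 0, 0)), topo),
               "collinear")
})

test_that("virtual-site force transfer matches the parent-coordinate gradient", {
  # energy: a fixed external charge interacting with a charged virtual site
  topo <- topology(mass = c(12, 12, 14, 0), charge = c(0, 0, 0, 0.5),
                   sigma = rep(0, 4), epsilon = rep(0, 4), mol = rep(1L, 4),
                   virtual_sites = list(list(site = 4L, parents = c(3L, 1L, 2L),
                                             a = 0.15, b = -0.1, c = 0.25)))
  qext <- -0.8
  rext <- c(0.5, 2.5, 1.0)
  energy <- function(parents) {
    pos <- rbind(parents, c(0, 0, 0))
    pos <- project_virtual_sites(pos, topo)
    npbc_constants$k_e * 0.5 * qext / sqrt(sum((pos[4, ] - rext)^2))
  }
  parents <- rbind(c(1, 0.3, 0), c(-1, 0, 0.2), c(0.1, -0.7, 0))
  pos <- project_virtual_sites(rbind(parents, c(0, 0, 0)), topo)
  # force on the site from the external charge
  d <- pos[4, ] - rext
  fs <- npbc_constants$k_e * 0.5 * qext * d / sum(d^2)^1.5
  forces <- matrix(0, 4, 3)
  forces[4, ] <- fs
  forces <- vsite_spread_forces(pos, forces, topo)
  expect_equal(forces[4, ], c(0, 0, 0))
  h <- 1e-6
  for (k in 1:3) for (a in 1:3) {
    pp <- parents; pp[k, a] <- pp[k, a] + h
    pm <- parents; pm[k, a] <- pm[k, a] - h
    fd <- -(energy(pp) - energy(pm)) / (2 * h)
    expect_equal(forces[k, a], fd, tolerance = 1e-5 * max(abs(forces), 1))
  }
})

test_that("mean-field potential: activation, flat case, packaged coefficients", {
  mf <- meanfield_potential(c(2.5), cutoff_start = 10)
  # constant polynomial: energy but no force anywhere in the active shell
  ev <- eval_meanfield(mf, c(0.5, 3, 9.9), derivative = TRUE)
  expect_equal(ev$value, rep(2.5, 3))
  expect_equal(ev$deriv, rep(0, 3))
  # outside the active shell the potential vanishes
  expect_equal(eval_meanfield(mf, 10.5), 0)
  # packaged coefficients evaluate to the plain power sum (Horner == direct)
  tp <- tip3pfb_meanfield()
  x <- seq(0, 7.9, by = 0.37)
  direct <- vapply(x, function(xi)
    sum(tp$coefficients * xi^(seq_along(tp$coefficients) - 1)), 0)
  expect_lt(max(abs(eval_meanfield(tp, x) - direct)), 1e-10)
  expect_equal(eval_meanfield(tp, 1.0),
               sum(tp$coefficients * 1.0^(0:10)), tolerance = 1e-12)
})

test_that("mean-field energy/forces act radially on molecule COMs", {
  sys <- monatomic_system(rbind(c(0, 0, 0), c(0, 0, 17)), radius = 20)
  mf <- meanfield_potential(c(1, -0.5, 0.05), cutoff_start = 10)
  out <- meanfield_energy_forces(sys, mf)
  # molecule at the center is outside the active shell (boundary distance 20)
  expect_equal(out$forces[1, ], c(0, 0, 0))
  # molecule at boundary distance 3: radial force = +U'(3) toward the wall
  d <- eval_meanfield(mf, 3, derivative = TRUE)$deriv
  expect_equal(out$forces[2, ], c(0, 0, d), tolerance = 1e-12)
  expect_equal(out$energy, eval_meanfield(mf, 3), tolerance = 1e-12)
  expect_equal(out$virial, d * 17, tolerance = 1e-12)
})

test_that("rough wall resets escaped molecules to the Maxwell mean speed", {
  set.seed(31)
  pos <- rbind(c(0, 0, 0), c(0, 0, 9.0))   # second molecule outside R = 8.5
  sys <- monatomic_system(pos, radius = 8.5, mass = 18)
  sys$vel <- rbind(c(1, 0, 0), c(0, 0, 2))
  out <- rough_wall(sys, 298.15)
  expect_equal(out$events, 1L)
  expect_equal(out$system$vel[1, ], c(1, 0, 0))  # inside molecule untouched
  vmean <- sqrt(8 * npbc_constants$k_B * 298.15 * 100 / (pi * 18))
  expect_equal(sqrt(sum(out$system$vel[2, ]^2)), vmean, tolerance = 1e-12)
  # new velocity points inward
  expect_lt(sum(out$system$vel[2, ] * out$system$com[2, ]), 0)
  # all molecules inside: nothing happens
  sys2 <- monatomic_system(rbind(c(0, 0, 0), c(0, 0, 5)), radius = 8.5)
  expect_equal(rough_wall(sys2, 298.15)$events, 0L)
})

test_that("escaped rigid molecules get the equipartition angular momentum", {
  set.seed(32)
  sys <- small_water(0.15, radius = 6, seed = 8)
  m <- which.max(rowSums(sys$com^2))
  sys$com[m, ] <- sys$com[m, ] / sqrt(sum(sys$com[m, ]^2)) * 7  # push outside
  sys <- npbcmd:::rebuild_positions(sys)
  out <- rough_wall(sys, 298.15)
  expect_gte(out$events, 1L)
  lmag <- sqrt(sum(out$system$angmom[m, ]^2))
  expect_equal(lmag, sqrt(sum(sys$inertia[m, ]) *
                            npbc_constants$k_B * 298.15 * 100),
               tolerance = 1e-10)
})
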