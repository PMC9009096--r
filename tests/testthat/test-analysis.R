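# Structural observables: finite-sphere g(r), HWHM extraction, shell
# densities, continuous hydrogen-bond strength.

# minimal trajectory object from a list of coordinate frames
mk_traj <- function(frames, topo, radius) {
  arr <- array(0, c(nrow(frames[[1]]), 3, length(frames)))
  for (k in seq_along(frames)) arr[, , k] <- frames[[k]]
  structure(list(positions = arr, radius = rep(radius, length(frames)),
                 time = seq_along(frames), topology = topo),
            class = "npbc_trajectory")
}

test_that("a single fixed pair lands in exactly one g(r) bin", {
  topo <- atom_gas_topology(2)
  topo$atoms$name <- c("O", "O")
  tr <- mk_traj(list(rbind(c(0, 0, 0), c(2.87, 0, 0))), topo, radius = 10)
  r <- rdf_npbc(tr, c("O", "O"), r_sel = 4.5, r_max = 4, bin_width = 0.05)
  nz <- which(r$g > 0)
  expect_length(nz, 1L)
  expect_lt(abs(r$r[nz] - 2.87), 0.05)
})

test_that("geometry violations are rejected", {
  topo <- atom_gas_topology(2)
  topo$atoms$name <- c("O", "O")
  tr <- mk_traj(list(rbind(c(0, 0, 0), c(2, 0, 0))), topo, radius = 8)
  expect_error(rdf_npbc(tr, c("O", "O"), r_sel = 4.5, r_max = 4),
               "cross the boundary")
})

test_that("uniform ideal gas gives a flat g(r) and correct normalization", {
  set.seed(8)
  n <- 300; R <- 12
  topo <- atom_gas_topology(n)
  topo$atoms$name <- rep("O", n)
  frames <- lapply(1:40, function(i) {
    # uniform in the ball by radius inversion
    u <- runit(n) * R * runif(n)^(1 / 3)
    u
  })
  tr <- mk_traj(frames, topo, radius = R)
  r <- rdf_npbc(tr, c("O", "O"), r_sel = 4, r_max = 6, bin_width = 0.25)
  # flatness: all bins beyond the first few within 3 sigma of 1
  sel <- r$r > 1.5
  expect_lt(max(abs(r$g[sel] - 1)), 0.25)
  expect_lt(abs(mean(r$g[sel]) - 1), 0.03)
  # normalization invariant: integral of g * 4 pi r^2 rho equals the mean
  # neighbor count within r_max
  rho <- n / (4 / 3 * pi * R^3)
  pred <- sum(r$g * 4 * pi * r$r^2 * rho) * r$bin_width
  cnt <- 0; nfr <- 0
  for (k in seq_along(frames)) {
    x <- frames[[k]]
    cen <- which(rowSums(x^2) <= 16)
    for (i in cen) {
      d2 <- colSums((t(x) - x[i, ])^2)
      cnt <- cnt + sum(d2 > 0 & d2 <= 36)
      nfr <- nfr + 1
    }
  }
  expect_rel_equal(pred, cnt / nfr, 0.005)
})

test_that("an FCC ball shows peaks at the lattice neighbor shells", {
  a <- 3.6
  g <- expand.grid(i = -4:4, j = -4:4, k = -4:4)
  base <- as.matrix(g)
  fcc <- rbind(base, sweep(base, 2, c(0.5, 0.5, 0), "+"),
               sweep(base, 2, c(0.5, 0, 0.5), "+"),
               sweep(base, 2, c(0, 0.5, 0.5), "+")) * a
  R <- 12
  fcc <- fcc[rowSums(fcc^2) < R^2, ]
  n <- nrow(fcc)
  topo <- atom_gas_topology(n)
  topo$atoms$name <- rep("O", n)
  tr <- mk_traj(list(fcc), topo, radius = R)
  r <- rdf_npbc(tr, c("O", "O"), r_sel = 4, r_max = 7, bin_width = 0.05)
  d1 <- a / sqrt(2)
  for (d in c(d1, a, d1 * sqrt(3))) {
    near <- which(abs(r$r - d) <= 0.051)
    expect_gt(max(r$g[near]), 1)
  }
  # depletion between shells
  expect_equal(max(r$g[r$r > d1 * 1.1 & r$r < a * 0.9]), 0)
})

test_that("HWHM recovers analytic widths for synthetic peaks", {
  rr <- seq(0.025, 6, by = 0.05)
  # Gaussian bump of width sigma on a flat baseline
  sigma <- 0.3
  gg <- 1 + 2 * exp(-(rr - 3)^2 / (2 * sigma^2))
  p <- hwhm_first_peak(list(r = rr, g = gg, bin_width = 0.05))
  expect_equal(p$hwhm, sigma * sqrt(2 * log(2)), tolerance = 0.05)
  expect_equal(p$position, 3, tolerance = 0.03)
  pl <- hwhm_first_peak(list(r = rr, g = gg, bin_width = 0.05), side = "left")
  expect_equal(pl$hwhm, p$hwhm, tolerance = 0.06)  # symmetric peak
  # symmetric triangle of half-base w: HWHM = w/2
  w <- 1.0
  gt <- pmax(1 - abs(rr - 3) / w, 0) * 2
  pt <- hwhm_first_peak(list(r = rr, g = gt, bin_width = 0.05))
  expect_equal(pt$hwhm, w / 2, tolerance = 0.06)
  # flat profile: no peak
  expect_error(hwhm_first_peak(list(r = rr, g = rep(1, length(rr)),
                                    bin_width = 0.05)),
               "no resolvable")
})

test_that("equal-volume shell edges follow the cube-root law", {
  topo <- atom_gas_topology(4)
  x <- rbind(c(0, 0, 1), c(0, 0, 3), c(0, 5, 0), c(9, 0, 0))
  tr <- mk_traj(list(x), topo, radius = 20)
  sd10 <- shell_density(tr, 10)
  expect_equal(sd10$r_outer[1], 20 * 0.1^(1 / 3), tolerance = 1e-10)
  expect_equal(sd10$r_outer[10], 20, tolerance = 1e-10)
})

test_that("shell densities: occupancy, uniformity, rotation invariance", {
  # all molecules in the innermost shell -> outer shells exactly zero
  topo <- atom_gas_topology(5, mass = 18)
  x <- matrix(rnorm(15, sd = 0.5), 5, 3)
  tr <- mk_traj(list(x), topo, radius = 30)
  sd5 <- shell_density(tr, 5)
  expect_true(all(sd5$mean_density[-1] == 0))
  expect_gt(sd5$mean_density[1], 0)
  # uniform configurations: all shells equal within 3 standard errors
  set.seed(14)
  n <- 400; R <- 10
  topo2 <- atom_gas_topology(n, mass = 18)
  frames <- lapply(1:30, function(i) runit(n) * R * runif(n)^(1 / 3))
  tr2 <- mk_traj(frames, topo2, radius = R)
  s <- shell_density(tr2, 5)
  se <- s$sd_density / sqrt(30)
  expect_true(all(abs(s$mean_density - mean(s$mean_density)) <= 3.5 * se))
  # global rotation leaves shell densities unchanged
  th <- 0.8
  Rm <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tr3 <- mk_traj(lapply(frames, function(f) f %*% Rm), topo2, radius = R)
  expect_equal(shell_density(tr3, 5)$mean_density, s$mean_density,
               tolerance = 1e-10)
})

test_that("hydrogen-bond strength switches behave as designed", {
  p <- hbond_params()
  wm <- water_model("SPC")
  # two waters: donor H of molecule 1 pointing at the acceptor O of molecule 2
  mk <- function(roo) {
    g <- npbcmd:::water_geometry("SPC")
    m1 <- g
    m2 <- sweep(g, 2, c(0, 0, roo))      # acceptor O below the donor
    # orient donor H1 toward the acceptor: place H1 along -z
    m1[2, ] <- c(0, 0, -1)
    rbind(m1, m2)
  }
  topo <- npbcmd:::water_topology("SPC", 2)
  # ideal geometry (r << r0, theta = 180): the pair term saturates; with a
  # sharp angular switch it reaches 1 within 1e-3
  sharp <- hbond_params(b = 0.3)
  f1 <- f_hb(mk(2.6), topo, sharp)  # H at -1, acceptor O at -2.6: r_HA = 1.6
  expect_gt(max(f1$pairs$strength), 1 - 1e-3)
  # under the default angular steepness the same geometry gives the logistic
  # product exactly
  f1d <- f_hb(mk(2.6), topo, p)
  expect_equal(max(f1d$pairs$strength),
               1 / (1 + exp(p$a * (1.6 - p$r0))) /
                 (1 + exp(-p$b * (180 - p$theta0))),
               tolerance = 1e-6)
  # no acceptor within 2 r0 -> total ~ 0
  f2 <- f_hb(mk(9), topo, p)
  expect_lt(f2$total, 1e-3)
  # both switches at midpoint: pair term 0.25 by construction
  s_r <- function(r) 1 / (1 + exp(p$a * (r - p$r0)))
  s_t <- function(th) 1 / (1 + exp(-p$b * (th - p$theta0)))
  expect_equal(s_r(p$r0) * s_t(p$theta0), 0.25, tolerance = 1e-12)
  # monotone: decreasing in r, increasing in theta
  rs <- seq(1, 5, 0.1)
  expect_true(all(diff(s_r(rs)) < 0))
  ths <- seq(60, 180, 5)
  expect_true(all(diff(s_t(ths)) > 0))
})
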