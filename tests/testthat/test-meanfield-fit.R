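# Shell-potential updates, ridge polynomial fitting and the evolutionary
# shrinkage search.

test_that("shell updates damp density deviations with the right sign", {
  pr <- shell_profile(10, n_shells = 8, target_density = 1)
  # converged fixed point: uniform density leaves the potential unchanged
  pr2 <- update_shell_potential(pr, rep(1, 8))
  expect_equal(pr2$correction, numeric(8))
  # one overdense shell becomes more repulsive (positive increment)
  dens <- rep(1, 8); dens[3] <- 1.3
  pr3 <- update_shell_potential(pr, dens, delta = 0.01, delta_max = 0.05)
  expect_equal(pr3$correction[3], 0.01 * 0.3, tolerance = 1e-12)
  expect_equal(pr3$correction[-3], numeric(7))
  # increments are capped
  dens[3] <- 100
  pr4 <- update_shell_potential(pr, dens, delta = 0.01, delta_max = 0.05)
  expect_equal(pr4$correction[3], 0.05)
})

test_that("closed-loop updates converge on a linear-response toy model", {
  # density responds linearly to the local potential: rho = rho0 (1 + d0 - chi U)
  pr <- shell_profile(10, n_shells = 6, target_density = 1)
  d0 <- c(0.2, -0.1, 0.15, 0, -0.25, 0.05)
  chi <- 40
  dev <- numeric(0)
  for (it in 1:300) {
    dens <- 1 * (1 + d0 - chi * pr$correction)
    dev <- c(dev, max(abs(dens - 1)))
    pr <- update_shell_potential(pr, dens, delta = 0.01, delta_max = 0.05)
  }
  expect_lt(dev[length(dev)], 0.01)
  # deviations decay (monotone over coarse windows)
  wm <- sapply(split(dev, cut(seq_along(dev), 6)), max)
  expect_true(all(diff(wm) <= 1e-12))
})

test_that("ridge at lambda -> 0 equals OLS and recovers exact polynomials", {
  set.seed(10)
  x <- seq(0, 5, length.out = 40)
  y <- 2 - 1.5 * x + 0.3 * x^3
  cf <- npbcmd:::ridge_poly(x, y, 3, 0)
  ols <- unname(coef(lm(y ~ poly(x, 3, raw = TRUE))))
  expect_lt(max(abs(cf - ols)), 1e-8)
  expect_lt(max(abs(cf - c(2, -1.5, 0, 0.3))), 1e-6)
  # Horner-stable evaluation
  xs <- seq(0, 5, 0.01)
  direct <- sapply(xs, function(xi) sum(cf * xi^(0:3)))
  expect_lt(max(abs(npbcmd:::polyval(cf, xs) - direct)), 1e-10)
})

test_that("evolutionary search minimizes a convex objective reproducibly", {
  obj <- function(l) (l - 2.345)^2 + 0.7
  set.seed(20)
  es <- evolutionary_search(obj, c(0, 10), ea_params(iterations = 80))
  expect_lt(abs(es$par - 2.345), 1e-3)
  expect_equal(es$value, obj(es$par))
  # flat objective: any feasible point, value equals the constant
  set.seed(21)
  ef <- evolutionary_search(function(l) 3.3, c(0, 1),
                            ea_params(iterations = 10))
  expect_equal(ef$value, 3.3)
  expect_gte(ef$par, 0); expect_lte(ef$par, 1)
  # determinism under seed
  set.seed(22); a <- evolutionary_search(obj, c(0, 10),
                                         ea_params(iterations = 30))
  set.seed(22); b <- evolutionary_search(obj, c(0, 10),
                                         ea_params(iterations = 30))
  expect_identical(a$par, b$par)
})

test_that("polynomial fitting selects the degree by test error", {
  ea <- ea_params(population = 30, n_parents = 8, iterations = 25)
  # noiseless cubic: selected degree >= 3, near-exact test error
  x <- seq(0.1, 6, length.out = 60)
  y <- 1.2 - 0.8 * x + 0.05 * x^3
  set.seed(30)
  fit <- fit_polynomial(x, y, degrees = 0:6, truncate_at = NULL, params = ea)
  expect_gte(fit$degree, 3)
  expect_lt(fit$curves$rmse_test[fit$curves$degree == fit$degree], 1e-6)
  pred <- npbcmd:::polyval(fit$potential$coefficients, x)
  expect_lt(max(abs(pred - y)), 1e-4)
  # constant data: degree 0, a_0 = mean
  set.seed(31)
  fc <- fit_polynomial(x, rep(4.2, 60), degrees = 0:4, truncate_at = NULL,
                       params = ea)
  expect_equal(fc$degree, 0)
  expect_equal(fc$potential$coefficients[1], 4.2, tolerance = 1e-6)
  # degrees with too few points are excluded
  set.seed(32)
  f2 <- fit_polynomial(x[1:8], y[1:8], degrees = 0:12, truncate_at = NULL,
                       params = ea)
  expect_lte(max(f2$curves$degree), 3)  # 4 train points -> degree <= 3
})

test_that("EA-selected shrinkage never loses to the interval endpoints", {
  set.seed(33)
  x <- seq(0, 4, length.out = 50)
  y <- sin(x) + rnorm(50, sd = 0.3)
  itr <- seq_along(x) %% 2 == 1
  obj <- function(l) {
    cf <- npbcmd:::ridge_poly(x[itr], y[itr], 8, l)
    sqrt(mean((y[!itr] - npbcmd:::polyval(cf, x[!itr]))^2))
  }
  bounds <- c(1e-8, 10)
  es <- evolutionary_search(obj, bounds, ea_params(population = 40,
                                                   n_parents = 10,
                                                   iterations = 40))
  expect_lte(es$value, obj(bounds[1]) + 1e-12)
  expect_lte(es$value, obj(bounds[2]) + 1e-12)
})

test_that("packaged reference fit reproduces its own polynomial from samples", {
  # sampling the packaged boundary polynomial and refitting at matching
  # abscissae returns the same predictions (fit-of-a-polynomial identity)
  tp <- tip3pfb_meanfield()
  x <- seq(0.05, 7.95, by = 0.1)    # 80 points at 0.1 A resolution
  y <- eval_meanfield(tp, x)
  set.seed(34)
  fit <- fit_polynomial(x, y, degrees = 0:12, truncate_at = NULL,
                        params = ea_params(population = 30, n_parents = 8,
                                           iterations = 25))
  pred <- npbcmd:::polyval(fit$potential$coefficients, x)
  expect_lt(max(abs(pred - y)), 1e-3)
  expect_gte(fit$degree, 10)
})

test_that("the optimization loop drives MD and accumulates shell corrections", {
  sys <- small_water(0.7, radius = 8.5, seed = 9)
  cfg <- simulation_config("NVT", dt = 0.002, n_steps = 500, tau_t = 0.4,
                           traj_stride = 25, log_stride = 100, seed = 10)
  prof <- shell_profile(8.5, n_shells = 6, target_density = 0.7)
  res <- optimize_meanfield(sys, cfg, n_updates = 3, profile = prof,
                            delta = 0.5, delta_max = 0.3)
  expect_length(res$history, 3L)
  expect_true(all(is.finite(res$history)))
  # corrections accumulated somewhere and stayed within the per-update caps
  expect_gt(max(abs(res$profile$correction)), 0)
  expect_lte(max(abs(res$profile$correction)), 3 * 0.3 + 1e-12)
  # the observed densities feed the constant-width shell profile estimator
  dens <- shell_density_profile(
    run_simulation(sys, cfg)$trajectory, prof)
  expect_length(dens, 6L)
  expect_true(all(dens >= 0))
})

test_that("profile tables round-trip through the two-column text format", {
  f <- tempfile(fileext = ".dat")
  x <- seq(0, 5, 0.5); y <- sin(x)
  write_profile_table(x, y, f)
  df <- read_profile_table(f)
  expect_equal(df$x, x)
  expect_equal(df$y, y, tolerance = 1e-12)
})
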