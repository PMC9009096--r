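# Adaptive optimization of the boundary mean-field potential: a tabulated
# per-shell correction is nudged against past density fluctuations until the
# profile is flat, then the converged profile is fitted by ridge-regularized
# polynomials whose shrinkage is tuned by a (mu, lambda) evolutionary search.

#' Shell profile for mean-field optimization
#'
#' @param radius Cavity radius (A).
#' @param n_shells Number of constant-width radial shells (default 80).
#' @param target_density Target density (same units as the running
#'   estimates fed to [update_shell_potential()]).
#' @return A `ShellProfile` with shell `edges`, `centers`, zeroed `correction`
#'   energies (kJ/mol) and the target.
#' @export
shell_profile <- function(radius, n_shells = 80L, target_density = 0.997) {
  stopifnot(n_shells >= 2L, radius > 0, target_density > 0)
  edges <- seq(0, radius, length.out = n_shells + 1L)
  structure(list(radius = radius, n_shells = as.integer(n_shells),
                 edges = edges,
                 centers = (edges[-1] + edges[-(n_shells + 1)]) / 2,
                 target_density = target_density,
                 correction = numeric(n_shells)),
            class = "ShellProfile")
}

#' Update the tabulated shell potential against observed densities
#'
#' Adds, per shell, a tiny repulsive (overdense) or attractive (underdense)
#' increment proportional to the relative density deviation observed since
#' the last update, capped at `delta_max`, so that fluctuations are damped
#' over successive updates.
#'
#' @param profile A [shell_profile()].
#' @param densities Per-shell mean densities over the update window (vector
#'   of length `n_shells`, same units as the target).
#' @param delta Increment scale (kJ/mol per unit relative deviation).
#' @param delta_max Per-update increment cap (kJ/mol).
#' @return The updated profile.
#' @export
update_shell_potential <- function(profile, densities, delta = 0.01,
                                   delta_max = 0.05) {
  stopifnot(length(densities) == profile$n_shells)
  rel <- (densities - profile$target_density) / profile$target_density
  inc <- pmin(pmax(delta * rel, -delta_max), delta_max)
  profile$correction <- profile$correction + inc
  profile
}

#' Per-shell molecule densities of a trajectory on a constant-width grid
#'
#' Counts molecule centres of mass per constant-width radial shell and
#' converts to mass density (g/cm^3), averaged over the frames.  Companion
#' of [update_shell_potential()] (constant-width shells, unlike the
#' constant-volume shells of [shell_density()]).
#'
#' @param traj An `npbc_trajectory`.
#' @param profile A [shell_profile()].
#' @return Vector of per-shell densities.
#' @export
shell_density_profile <- function(traj, profile) {
  topo <- traj$topology
  mol <- topo$atoms$mol
  nmol <- max(mol)
  mm <- topo$atoms$mass
  mass <- vapply(seq_len(nmol), function(m) sum(mm[mol == m]), 0)
  nf <- dim(traj$positions)[3]
  acc <- numeric(profile$n_shells)
  vol <- 4 / 3 * pi * diff(profile$edges^3)
  for (k in seq_len(nf)) {
    x <- traj$positions[, , k]
    com <- vapply(seq_len(nmol), function(m) {
      idx <- mol == m
      sqrt(sum((colSums(x[idx, , drop = FALSE] * mm[idx]) / mass[m])^2))
    }, 0)
    sh <- pmin(findInterval(com, profile$edges[-1]) + 1L, profile$n_shells)
    for (s in seq_len(profile$n_shells))
      acc[s] <- acc[s] + sum(mass[sh == s])
  }
  acc / nf / vol / 0.602214076
}

#' Adaptive mean-field optimization loop
#'
#' Alternates MD runs with shell-potential updates: the tabulated correction
#' is applied as a radial potential during the next chunk, the per-shell
#' densities observed in the chunk drive the next update.
#'
#' @param sys An `npbc_system`.
#' @param config A [simulation_config()]; `n_steps` is the update interval
#'   (50000 steps in the reference protocol; scale down at desk scale).
#' @param n_updates Number of update cycles.
#' @param profile A [shell_profile()]; defaults to 80 shells at the system
#'   density target.
#' @param delta,delta_max Update increments, see [update_shell_potential()].
#' @return List with the final `profile`, the `system`, and the per-cycle
#'   maximum relative density deviation `history`.
#' @export
optimize_meanfield <- function(sys, config, n_updates = 5L,
                               profile = shell_profile(sys$radius),
                               delta = 0.01, delta_max = 0.05) {
  history <- numeric(n_updates)
  for (u in seq_len(n_updates)) {
    config$tabulated <- profile$correction
    config$seed <- config$seed + 1L
    run <- run_simulation(sys, config, init_velocities = all(sys$vel == 0))
    sys <- run$final
    dens <- shell_density_profile(run$trajectory, profile)
    history[u] <- max(abs(dens - profile$target_density) /
                        profile$target_density)
    profile <- update_shell_potential(profile, dens, delta, delta_max)
  }
  list(profile = profile, system = sys, history = history)
}

# ---------------------------------------------------------------------------
# Ridge regression + evolutionary shrinkage search
# ---------------------------------------------------------------------------

# ridge fit of a degree-d polynomial, returned as raw-power coefficients.
# The fit runs on an orthogonal polynomial basis (unit-norm columns), where
# ridge has the closed form beta = P'y / (1 + lambda) with the intercept
# unpenalized, so lambda -> 0 recovers OLS exactly and the penalty is
# scale-meaningful at any degree (raw-power bases would give standardized
# coefficients of order 1e4+ and make even tiny penalties biasing).
# Monomial coefficients are recovered by interpolation at Chebyshev nodes.
ridge_poly <- function(x, y, degree, lambda) {
  s <- max(abs(x), 1)
  t <- x / s
  if (degree == 0L) return(mean(y))
  P <- stats::poly(t, degree)
  beta <- drop(crossprod(P, y)) / (1 + lambda)
  b0 <- mean(y)
  # fitted polynomial evaluated at Chebyshev nodes of the data range
  cheb <- mean(range(t)) + diff(range(t)) / 2 *
    cos(pi * (2 * seq_len(degree + 1L) - 1) / (2 * (degree + 1L)))
  pv <- b0 + drop(predict(P, cheb) %*% beta)
  coef_t <- solve(outer(cheb, 0:degree, `^`), pv)
  coef_t / s^(0:degree)
}

polyval <- function(coef, x) {
  p <- rep(0, length(x))
  for (i in rev(seq_along(coef))) p <- p * x + coef[i]
  p
}

#' Evolutionary-algorithm configuration for the shrinkage search
#'
#' @param population Offspring population size (default 100).
#' @param n_parents Truncation-selected parents per generation.
#' @param mut_parent,mut_child Mutation probabilities for parent-derived and
#'   crossover-derived genes (defaults 0.3 and 0.5).
#' @param crossover Crossover rate (default 0.5).
#' @param iterations Generations (default 500).
#' @param sigma_anneal Gaussian mutation width decay per generation.
#' @return An `ea_params` list.
#' @export
ea_params <- function(population = 100L, n_parents = 25L, mut_parent = 0.3,
                      mut_child = 0.5, crossover = 0.5, iterations = 500L,
                      sigma_anneal = 0.99) {
  stopifnot(population > 1, n_parents >= 1, n_parents <= population,
            mut_parent >= 0, mut_parent <= 1, mut_child >= 0, mut_child <= 1,
            crossover >= 0, crossover <= 1)
  structure(list(population = as.integer(population),
                 n_parents = as.integer(n_parents),
                 mut_parent = mut_parent, mut_child = mut_child,
                 crossover = crossover, iterations = as.integer(iterations),
                 sigma_anneal = sigma_anneal), class = "ea_params")
}

#' (mu, lambda) evolutionary search of a scalar parameter
#'
#' Comma-selection evolutionary minimization on a bounded interval: each
#' generation builds `population` offspring from the truncation-selected
#' parents by arithmetic crossover (rate `crossover`) and Gaussian mutation
#' (rates `mut_parent` / `mut_child`, width annealed by `sigma_anneal`), and
#' returns the best point ever evaluated (the incumbent).
#'
#' @param objective Function of one scalar, to minimize.
#' @param bounds Length-2 interval searched.
#' @param params An [ea_params()].
#' @return List with `par`, `value` and `trace` (incumbent value per
#'   generation).
#' @export
evolutionary_search <- function(objective, bounds, params = ea_params()) {
  lo <- bounds[1]; hi <- bounds[2]
  stopifnot(hi > lo)
  pop <- runif(params$population, lo, hi)
  val <- vapply(pop, objective, 0)
  best_par <- pop[which.min(val)]
  best_val <- min(val)
  sigma <- (hi - lo) / 10
  trace <- numeric(params$iterations)
  for (g in seq_len(params$iterations)) {
    ord <- order(val)
    parents <- pop[ord[seq_len(params$n_parents)]]
    child <- numeric(params$population)
    from_cross <- runif(params$population) < params$crossover
    p1 <- parents[sample.int(params$n_parents, params$population, TRUE)]
    p2 <- parents[sample.int(params$n_parents, params$population, TRUE)]
    child <- ifelse(from_cross, (p1 + p2) / 2, p1)
    mrate <- ifelse(from_cross, params$mut_child, params$mut_parent)
    mut <- runif(params$population) < mrate
    child[mut] <- child[mut] + rnorm(sum(mut), sd = sigma)
    child <- pmin(pmax(child, lo), hi)
    pop <- child
    val <- vapply(pop, objective, 0)
    if (min(val) < best_val) {
      best_val <- min(val)
      best_par <- pop[which.min(val)]
    }
    trace[g] <- best_val
    sigma <- sigma * params$sigma_anneal
  }
  list(par = best_par, value = best_val, trace = trace)
}

#' Fit the mean-field profile by ridge-regularized polynomials
#'
#' Truncates the profile where the correction energy first stays below
#' `truncate_at`, splits the remaining points into alternating train/test
#' halves, and for each polynomial degree in `degrees` fits a ridge
#' regression whose shrinkage is optimized by [evolutionary_search()] on the
#' test RMSE.  The returned degree minimizes the test RMSE (ties broken by
#' highest test R^2, then lowest degree).
#'
#' @param x Boundary distances (A) of the profile points.
#' @param y Correction energies (kJ/mol).
#' @param degrees Candidate polynomial degrees (default 0:12).
#' @param lambda_bounds Shrinkage search interval.
#' @param truncate_at Truncation threshold (kJ/mol, default 0.1); set to
#'   `NULL` to fit the full profile.
#' @param params An [ea_params()].
#' @return List with the selected [meanfield_potential()] (`potential`), the
#'   chosen `degree` and `lambda`, and the learning `curves` data frame
#'   (degree, train/test RMSE and R^2).
#' @export
fit_polynomial <- function(x, y, degrees = 0:12,
                           lambda_bounds = c(1e-8, 10), truncate_at = 0.1,
                           params = ea_params()) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  if (!is.null(truncate_at)) {
    # the potential acts near the boundary: walking away from the wall,
    # drop everything from the first point where it falls below threshold
    below <- which(abs(y) < truncate_at)
    if (length(below) && below[1] > 1L) {
      x <- x[seq_len(below[1] - 1L)]
      y <- y[seq_len(below[1] - 1L)]
    }
  }
  itr <- seq_along(x) %% 2L == 1L           # alternating split, equal sizes
  xtr <- x[itr]; ytr <- y[itr]
  xte <- x[!itr]; yte <- y[!itr]
  rows <- list()
  fits <- list()
  for (d in degrees) {
    if (length(xtr) < d + 1L) next
    # shrinkage is scale-free: search on log10(lambda) so small penalties
    # are reachable
    obj <- function(u) {
      cf <- ridge_poly(xtr, ytr, d, 10^u)
      sqrt(mean((yte - polyval(cf, xte))^2))
    }
    es <- evolutionary_search(obj, log10(lambda_bounds), params)
    es$par <- 10^es$par
    cf <- ridge_poly(xtr, ytr, d, es$par)
    rtr <- ytr - polyval(cf, xtr)
    rte <- yte - polyval(cf, xte)
    r2 <- function(res, yy) 1 - sum(res^2) / sum((yy - mean(yy))^2)
    rows[[length(rows) + 1L]] <-
      data.frame(degree = d, lambda = es$par,
                 rmse_train = sqrt(mean(rtr^2)), rmse_test = sqrt(mean(rte^2)),
                 r2_train = r2(rtr, ytr), r2_test = r2(rte, yte))
    fits[[as.character(d)]] <- cf
  }
  curves <- do.call(rbind, rows)
  ix <- order(curves$rmse_test, -curves$r2_test, curves$degree)[1]
  best <- curves[ix, ]
  list(potential = meanfield_potential(fits[[as.character(best$degree)]],
                                       cutoff_start = max(x)),
       degree = best$degree, lambda = best$lambda, curves = curves)
}

#' Write / read a mean-field profile table
#'
#' Two-column plain text: boundary distance (A) and energy (kJ/mol).
#'
#' @param x,y Profile points.
#' @param file Path.
#' @return `read_profile_table` returns a data frame with `x`, `y`.
#' @export
write_profile_table <- function(x, y, file) {
  write.table(data.frame(x = x, y = y), file, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' @rdname write_profile_table
#' @export
read_profile_table <- function(file) {
  df <- read.table(file, col.names = c("x", "y"))
  df
}
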