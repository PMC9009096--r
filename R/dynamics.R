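# Time propagation: velocity Verlet with RATTLE for flexible molecules,
# quaternion velocity Verlet for rigid bodies, the stochastic
# velocity-rescaling (canonical sampling) thermostat, the Clausius-virial
# pressure, the weak-coupling barostat with a breathing cavity, and the
# NVT/NPT simulation driver (compiled core).

#' RATTLE projection of positions and velocities onto the constraint manifold
#'
#' Iterative (Gauss-Seidel) correction so that every constraint satisfies
#' `|r_i - r_j| = d` and `(r_i - r_j) . (v_i - v_j) = 0` within `tol`
#' (relative).  Mass-weighted corrections conserve linear momentum.
#'
#' @param positions,velocities n x 3 matrices.
#' @param constraints Matrix with columns `(i, j, dist)`.
#' @param masses Per-atom masses (amu).
#' @param tol Relative tolerance (default 1e-10).
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return List with corrected `positions` and `velocities`.
#' @export
rattle_project <- function(positions, velocities, constraints, masses,
                           tol = 1e-10, max_iter = 500L) {
  cons <- matrix(as.numeric(constraints), ncol = 3L)
  im <- 1 / masses
  for (it in seq_len(max_iter)) {
    worst <- 0
    for (k in seq_len(nrow(cons))) {
      i <- cons[k, 1]; j <- cons[k, 2]; d <- cons[k, 3]
      r <- positions[i, ] - positions[j, ]
      r2 <- sum(r^2)
      diff <- r2 - d^2
      worst <- max(worst, abs(sqrt(r2) - d) / d)
      g <- diff / (2 * (im[i] + im[j]) * r2)
      positions[i, ] <- positions[i, ] - g * im[i] * r
      positions[j, ] <- positions[j, ] + g * im[j] * r
    }
    if (worst < tol) break
    if (it == max_iter)
      stop(sprintf("RATTLE position iteration did not converge (residual %.3g)",
                   worst))
  }
  for (it in seq_len(max_iter)) {
    worst <- 0
    for (k in seq_len(nrow(cons))) {
      i <- cons[k, 1]; j <- cons[k, 2]
      r <- positions[i, ] - positions[j, ]
      rv <- sum(r * (velocities[i, ] - velocities[j, ]))
      worst <- max(worst, abs(rv) / sum(r^2))
      kk <- rv / ((im[i] + im[j]) * sum(r^2))
      velocities[i, ] <- velocities[i, ] - kk * im[i] * r
      velocities[j, ] <- velocities[j, ] + kk * im[j] * r
    }
    if (worst < tol) break
    if (it == max_iter)
      stop("RATTLE velocity iteration did not converge")
  }
  list(positions = positions, velocities = velocities)
}

#' One velocity-Verlet step for point particles (optionally with RATTLE)
#'
#' Standard half-kick / drift / half-kick update.  When the topology carries
#' constraints, positions and velocities are projected by [rattle_project()]
#' after the drift and after the second kick.
#'
#' @param state List with `positions`, `velocities` (n x 3) and `time` (ps);
#'   optionally `forces` from the previous step.
#' @param topo A [topology()] (masses, constraints).
#' @param force_fn Function `positions -> n x 3` forces in kJ/mol/A.
#' @param dt Time step (ps).
#' @param tol RATTLE tolerance.
#' @return Updated state (with `forces` cached).
#' @export
velocity_verlet_step <- function(state, topo, force_fn, dt, tol = 1e-10) {
  m <- topo$atoms$mass
  acc <- function(f) f * npbc_constants$ke_conv^-1 / m  # kJ/mol/A -> A/ps^2
  if (is.null(state$forces)) state$forces <- force_fn(state$positions)
  v <- state$velocities + 0.5 * dt * acc(state$forces)
  x <- state$positions + dt * v
  if (!is.null(topo$constraints)) {
    pr <- rattle_project(x, v, topo$constraints, m, tol)
    x <- pr$positions
    # velocity consistent with the constrained move
    v <- (x - state$positions) / dt
  }
  f2 <- force_fn(x)
  v <- v + 0.5 * dt * acc(f2)
  if (!is.null(topo$constraints))
    v <- rattle_project(x, v, topo$constraints, m, tol)$velocities
  list(positions = x, velocities = v, forces = f2, time = state$time + dt)
}

# quaternion time derivative given lab angular momentum and principal inertia
.quat_dot <- function(q, L_lab, inertia) {
  Rm <- quat_to_mat(q)
  lb <- crossprod(Rm, L_lab)
  om <- ifelse(inertia > 0, lb / pmax(inertia, 1e-300), 0)
  0.5 * quat_mul(q, c(0, om))
}

#' One rigid-body velocity-Verlet step
#'
#' COM translation by velocity Verlet; orientation by the implicit-midpoint
#' quaternion update with self-consistent iteration on the quaternion time
#' derivative, converged to `eps`, and renormalization each step.
#'
#' @param sys An `npbc_system`.
#' @param force_fn Function `positions -> n x 3 forces` (kJ/mol/A).
#' @param dt Time step (ps).
#' @param eps Convergence criterion for the quaternion derivative iteration.
#' @return Updated system (forces cached in `sys$forces`).
#' @export
rigid_body_step <- function(sys, force_fn, dt, eps = 1e-9) {
  en2md <- 1 / npbc_constants$ke_conv
  mol <- sys$topology$atoms$mol
  if (is.null(sys$forces)) sys$forces <- force_fn(sys$positions)
  ft <- .body_force_torque(sys, sys$forces)
  for (m in seq_len(nrow(sys$com))) {
    if (!sys$free[m]) next
    sys$vel[m, ] <- sys$vel[m, ] + 0.5 * dt * en2md * ft$force[m, ] / sys$molmass[m]
    sys$angmom[m, ] <- sys$angmom[m, ] + 0.5 * dt * en2md * ft$torque[m, ]
    sys$com[m, ] <- sys$com[m, ] + dt * sys$vel[m, ]
    if (any(sys$inertia[m, ] > 0)) {
      # adaptive substeps keep dt*omega small so the fixed-point iteration
      # on the quaternion derivative contracts
      lb <- crossprod(quat_to_mat(sys$quat[m, ]), sys$angmom[m, ])
      om <- sqrt(sum(ifelse(sys$inertia[m, ] > 0,
                            (lb / pmax(sys$inertia[m, ], 1e-300))^2, 0)))
      nsub <- max(1L, ceiling(dt * om / 0.1))
      dts <- dt / nsub
      for (ss in seq_len(nsub)) {
        q0 <- sys$quat[m, ]
        qd <- .quat_dot(q0, sys$angmom[m, ], sys$inertia[m, ])
        qn <- q0 + dts * qd
        ok <- FALSE
        for (it in 1:200) {
          qmid <- (q0 + qn) / 2
          qmid <- qmid / sqrt(sum(qmid^2))
          qd <- .quat_dot(qmid, sys$angmom[m, ], sys$inertia[m, ])
          qv <- q0 + dts * qd
          if (max(abs(qv - qn)) < eps) { qn <- qv; ok <- TRUE; break }
          qn <- qv
        }
        if (!ok)
          stop(sprintf("quaternion iteration did not converge (molecule %d)",
                       m))
        sys$quat[m, ] <- qn / sqrt(sum(qn^2))
      }
    }
  }
  sys <- rebuild_positions(sys)
  sys$forces <- force_fn(sys$positions)
  ft <- .body_force_torque(sys, sys$forces)
  for (m in seq_len(nrow(sys$com))) {
    if (!sys$free[m]) next
    sys$vel[m, ] <- sys$vel[m, ] + 0.5 * dt * en2md * ft$force[m, ] / sys$molmass[m]
    sys$angmom[m, ] <- sys$angmom[m, ] + 0.5 * dt * en2md * ft$torque[m, ]
  }
  sys$time <- sys$time + dt
  sys
}

.body_force_torque <- function(sys, forces) {
  mol <- sys$topology$atoms$mol
  nmol <- nrow(sys$com)
  Fm <- matrix(0, nmol, 3); Tq <- matrix(0, nmol, 3)
  for (m in seq_len(nmol)) {
    idx <- which(mol == m)
    fs <- forces[idx, , drop = FALSE]
    Fm[m, ] <- colSums(fs)
    d <- sweep(sys$positions[idx, , drop = FALSE], 2L, sys$com[m, ])
    Tq[m, ] <- c(sum(d[, 2] * fs[, 3] - d[, 3] * fs[, 2]),
                 sum(d[, 3] * fs[, 1] - d[, 1] * fs[, 3]),
                 sum(d[, 1] * fs[, 2] - d[, 2] * fs[, 1]))
  }
  list(force = Fm, torque = Tq)
}

#' Stochastic velocity-rescaling (canonical sampling) thermostat factor
#'
#' The closed-form global rescaling factor of the canonical-sampling
#' velocity-rescaling thermostat: with `c = exp(-dt/tau)`,
#' `alpha^2 = c + (Kbar/(N_f K))(1-c)(R1^2 + S) + 2 R1 sqrt(c(1-c)Kbar/(N_f K))`
#' where `R1` is standard normal and `S ~ chi^2(N_f - 1)`.  The factor is
#' applied to both translational velocities and angular momenta by the
#' driver.
#'
#' @param kinetic_energy Current kinetic energy (kJ/mol).
#' @param n_dof Number of coupled degrees of freedom.
#' @param temperature Target temperature (K).
#' @param tau_t Coupling time (ps); `Inf` decouples (factor 1).
#' @param dt Time step (ps).
#' @param r1,chisq Optional overrides of the random variates (testing /
#'   deterministic limits).
#' @return The velocity scaling factor `alpha`.
#' @export
bussi_thermostat <- function(kinetic_energy, n_dof, temperature, tau_t, dt,
                             r1 = NULL, chisq = NULL) {
  stopifnot(kinetic_energy > 0, n_dof >= 1)
  if (!is.finite(tau_t)) return(1)
  kbar <- 0.5 * n_dof * npbc_constants$k_B * temperature
  cc <- exp(-dt / tau_t)
  if (is.null(r1)) r1 <- rnorm(1)
  if (is.null(chisq)) chisq <- if (n_dof > 1) rchisq(1, n_dof - 1) else 0
  a2 <- cc + (kbar / (n_dof * kinetic_energy)) * (1 - cc) * (r1^2 + chisq) +
    2 * r1 * sqrt(cc * (1 - cc) * kbar / (n_dof * kinetic_energy))
  sqrt(max(a2, 0))
}

#' Instantaneous isotropic pressure from the Clausius virial
#'
#' `P = (2 E_kin + W) / (3V) - dE_dV`, converted to bar, with `E_kin` the
#' translational kinetic energy (kJ/mol), `W = sum r . F` the virial
#' (kJ/mol), `V = 4/3 pi R^3` and `dE_dV` any explicit volume derivative
#' (e.g. the reaction-field term), in kJ/mol/A^3.
#'
#' @param kinetic_energy Translational kinetic energy (kJ/mol).
#' @param virial Clausius virial (kJ/mol).
#' @param volume Cavity volume (A^3), > 0.
#' @param dEdV Explicit volume derivative of boundary energies (kJ/mol/A^3).
#' @return Pressure in bar.
#' @export
pressure <- function(kinetic_energy, virial, volume, dEdV = 0) {
  if (volume <= 0) stop("volume must be positive")
  ((2 * kinetic_energy + virial) / (3 * volume) - dEdV) * npbc_constants$p_bar
}

#' Weak-coupling barostat scaling factor
#'
#' `mu = (1 - alpha * beta * (dt/tau_p) * (P0 - P))^(1/3)`; coordinates and
#' the cavity radius are multiplied by `mu` in the same step.  Values outside
#' `[0.95, 1.05]` are clamped (runaway protection) with a warning.
#'
#' @param p_inst Instantaneous pressure (bar).
#' @param p0 Target pressure (bar).
#' @param tau_p Coupling time (ps).
#' @param dt Time step (ps).
#' @param beta Isothermal compressibility (1/bar).
#' @param alpha Box-type factor (1 for the spherical cavity).
#' @return Scaling factor `mu`.
#' @export
berendsen_scale <- function(p_inst, p0, tau_p, dt, beta = 4.5e-5, alpha = 1) {
  stopifnot(dt > 0, tau_p > 0)
  mu <- (1 - alpha * beta * (dt / tau_p) * (p0 - p_inst))^(1 / 3)
  if (mu < 0.95 || mu > 1.05) {
    warning(sprintf("barostat scaling mu = %.4f clamped to [0.95, 1.05]", mu))
    mu <- min(max(mu, 0.95), 1.05)
  }
  mu
}

#' Simulation configuration
#'
#' @param ensemble `"NVE"`, `"NVT"` or `"NPT"`.
#' @param dt Time step (ps).
#' @param n_steps Number of steps.
#' @param temperature Thermostat / wall temperature (K).
#' @param tau_t Thermostat coupling time (ps); ignored for NVE.
#' @param pressure Barostat set-point (bar, NPT).
#' @param tau_p Barostat coupling time (ps, NPT).
#' @param beta Isothermal compressibility (1/bar).
#' @param alpha_box Box-type factor of the weak-coupling barostat (1 for the
#'   spherical cavity).
#' @param reaction_field `NULL`, or `list(l_max =, grid =, f_eps =, offset =,
#'   in_pressure =)` enabling the conductor-like boundary reaction field.
#'   `offset` (default 1.4 A, one solvent radius) displaces the dielectric
#'   boundary outward from the confining wall: the continuum stands for the
#'   missing solvent, whose closest molecular centers lie about one solvent
#'   radius beyond the wall.  Reaction-field forces always enter the virial
#'   (they are real forces on the atoms; with them the virial estimator
#'   matches the mechanical wall pressure); `in_pressure = TRUE` additionally
#'   subtracts the explicit cavity-volume derivative dE/dV -- a
#'   dielectric-boundary free-energy term that the momentum balance does not
#'   see, off by default and available as a diagnostic.
#' @param meanfield `NULL` or a [meanfield_potential()].
#' @param tabulated `NULL` or a numeric vector of per-shell correction
#'   energies (kJ/mol) on `n` equal-width radial shells of the starting
#'   cavity (used during mean-field optimization, NVT only).
#' @param wall Enable the stochastic rough wall.
#' @param lj,coulomb Enable the pair terms.
#' @param traj_stride,log_stride Output strides in steps.
#' @param seed Integer seed (full trajectory reproducibility).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(ensemble = c("NVT", "NVE", "NPT"), dt = 0.002,
                              n_steps = 1000L, temperature = 298.15,
                              tau_t = 0.4, pressure = 1.0, tau_p = 4.0,
                              beta = 4.5e-5, alpha_box = 1,
                              reaction_field = NULL, meanfield = NULL,
                              tabulated = NULL, wall = TRUE, lj = TRUE,
                              coulomb = TRUE, traj_stride = 50L,
                              log_stride = 10L, seed = 1L) {
  ensemble <- match.arg(ensemble)
  stopifnot(dt > 0, n_steps >= 1)
  if (!is.null(reaction_field)) {
    reaction_field <- modifyList(list(l_max = 10L, grid = 302L, f_eps = 1.0,
                                      offset = 1.4, in_pressure = FALSE),
                                 reaction_field)
  }
  structure(list(ensemble = ensemble, dt = dt, n_steps = as.integer(n_steps),
                 temperature = temperature, tau_t = tau_t,
                 pressure = pressure, tau_p = tau_p, beta = beta,
                 alpha_box = alpha_box, reaction_field = reaction_field,
                 meanfield = meanfield, tabulated = tabulated, wall = wall,
                 lj = lj, coulomb = coulomb,
                 traj_stride = as.integer(traj_stride),
                 log_stride = as.integer(log_stride), seed = seed),
            class = "simulation_config")
}

#' Run a rigid-body NVT/NPT/NVE simulation
#'
#' The driver loop per step: half-kick, drift (COM + quaternion), forces
#' (pairs + mean field + reaction field), half-kick, rough-wall events,
#' thermostat, and -- for NPT -- instantaneous pressure and weak-coupling
#' scaling of molecular COMs and the cavity radius.  Fully reproducible from
#' the configured seed.
#'
#' @param sys An `npbc_system` (see [make_rigid_system()],
#'   [build_water_sphere()]).
#' @param config A [simulation_config()].
#' @param init_velocities Draw Maxwell-Boltzmann velocities at the configured
#'   temperature before the run (default: only if all velocities are zero).
#' @return An `npbc_run` with `trajectory` (an `npbc_trajectory`: positions
#'   `[atoms, 3, frames]`, per-frame `radius` and `time`, the topology), a
#'   `log` data frame (one row per log stride: time, T, P, energy terms, R,
#'   wall events) and `final`, the end-of-run system.
#' @export
run_simulation <- function(sys, config,
                           init_velocities = all(sys$vel == 0)) {
  stopifnot(inherits(sys, "npbc_system"), inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (init_velocities) sys <- init_velocities(sys, config$temperature)
  topo <- sys$topology
  rf <- config$reaction_field
  grid <- if (!is.null(rf)) build_lebedev_grid(rf$grid) else build_lebedev_grid(6)
  mfc <- if (!is.null(config$meanfield)) config$meanfield$coefficients else numeric(0)
  mfcut <- if (!is.null(config$meanfield)) config$meanfield$cutoff_start else 0
  tab <- if (!is.null(config$tabulated)) as.numeric(config$tabulated) else numeric(0)
  out <- cpp_run_md(sys$bodyref, topo$atoms$mol - 1L, topo$atoms$mass,
                    topo$atoms$charge, topo$atoms$sigma, topo$atoms$epsilon,
                    sys$inertia, sys$molmass, sys$free,
                    sys$com, sys$vel, sys$quat, sys$angmom, sys$radius,
                    config$dt, config$n_steps, config$temperature,
                    if (config$ensemble == "NVE") 0 else config$tau_t,
                    config$ensemble == "NPT", config$pressure, config$tau_p,
                    config$beta, config$alpha_box,
                    !is.null(rf), if (!is.null(rf)) rf$l_max else 0L,
                    grid$points, grid$weights,
                    if (!is.null(rf)) rf$f_eps else 1.0,
                    if (!is.null(rf)) rf$offset else 0.0,
                    if (!is.null(rf)) isTRUE(rf$in_pressure) else FALSE,
                    length(mfc) > 0, mfc, mfcut,
                    length(tab) > 0, tab,
                    config$wall, config$lj, config$coulomb,
                    config$traj_stride, config$log_stride, sys$time)
  final <- sys
  final$com <- out$com; final$vel <- out$vel; final$quat <- out$quat
  final$angmom <- out$angmom; final$positions <- out$positions
  final$radius <- out$radius
  final$time <- sys$time + config$n_steps * config$dt
  traj <- structure(list(positions = out$traj, radius = out$traj_R,
                         time = out$traj_time, topology = topo),
                    class = "npbc_trajectory")
  structure(list(trajectory = traj, log = as.data.frame(out$log),
                 final = final, config = config, n_dof = out$ndf),
            class = "npbc_run")
}

#' @export
print.npbc_run <- function(x, ...) {
  lg <- x$log
  cat(sprintf("npbc_run: %d steps (%.4g ps), ensemble %s\n", x$config$n_steps,
              x$config$n_steps * x$config$dt, x$config$ensemble))
  if (nrow(lg))
    cat(sprintf("  <T> = %.2f K, <P> = %.1f bar, final R = %.3f A\n",
                mean(lg$T), mean(lg$P), lg$R[nrow(lg)]))
  invisible(x)
}

#' Write an `npbc_trajectory` as multi-frame XYZ
#'
#' @param traj An `npbc_trajectory`.
#' @param file Path.
#' @return The path, invisibly.
#' @export
write_trajectory_xyz <- function(traj, file) {
  el <- traj$topology$atoms$name
  nf <- dim(traj$positions)[3]
  for (k in seq_len(nf))
    write_xyz(traj$positions[, , k], el, file,
              meta = list(time = traj$time[k], radius = traj$radius[k]),
              append = k > 1L)
  invisible(file)
}
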