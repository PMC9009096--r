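# Rigid-body representation: each molecule is described by its centre of mass,
# a unit quaternion (body -> lab, scalar first), the lab-frame angular
# momentum, and per-molecule reference coordinates in the principal-axis body
# frame.  Virtual sites are carried in the body frame like ordinary (massless)
# sites, so they ride rigidly with the molecule.

quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

mat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

#' Build a rigid-body system from a topology and coordinates
#'
#' Computes, per molecule, the centre of mass, the principal-axis inertia
#' tensor and body-frame reference coordinates, and initializes quaternions
#' from the principal axes.  Molecules listed in `topo$frozen` keep zero
#' velocity and are excluded from integration and thermostatting.
#'
#' @param topo A [topology()].
#' @param positions n x 3 coordinates (A); virtual sites are projected first.
#' @param radius Cavity radius (A).
#' @param time Simulation time origin (ps).
#' @return An `npbc_system` object.
#' @export
make_rigid_system <- function(topo, positions, radius, time = 0) {
  positions <- project_virtual_sites(positions, topo)
  mol <- topo$atoms$mol
  nmol <- max(mol)
  mass <- topo$atoms$mass
  com <- matrix(0, nmol, 3)
  inertia <- matrix(0, nmol, 3)
  quat <- matrix(rep(c(1, 0, 0, 0), each = nmol), nmol, 4)
  bodyref <- matrix(0, nrow(positions), 3)
  molmass <- numeric(nmol)
  for (m in seq_len(nmol)) {
    idx <- which(mol == m)
    w <- mass[idx]
    molmass[m] <- sum(w)
    com[m, ] <- colSums(positions[idx, , drop = FALSE] * w) / sum(w)
    d <- sweep(positions[idx, , drop = FALSE], 2L, com[m, ])
    if (length(idx) == 1L || sum(w > 0) == 1L) {
      bodyref[idx, ] <- d
      next
    }
    Imat <- matrix(0, 3, 3)
    for (a in seq_along(idx)) {
      r <- d[a, ]
      Imat <- Imat + w[a] * (sum(r^2) * diag(3) - tcrossprod(r))
    }
    ev <- eigen(Imat, symmetric = TRUE)
    E <- ev$vectors
    if (det(E) < 0) E[, 3] <- -E[, 3]
    vals <- ev$values
    # linear molecules: zero the vanishing principal moment so no angular
    # velocity builds up about the molecular axis
    vals[vals < 1e-8 * max(vals)] <- 0
    inertia[m, ] <- vals
    quat[m, ] <- mat_to_quat(E)
    bodyref[idx, ] <- d %*% E   # body coords: E^T d, row-wise
  }
  structure(list(topology = topo,
                 positions = positions,
                 com = com, vel = matrix(0, nmol, 3), quat = quat,
                 angmom = matrix(0, nmol, 3),
                 inertia = inertia, bodyref = bodyref, molmass = molmass,
                 free = !(seq_len(nmol) %in% topo$frozen),
                 radius = radius, time = time),
            class = "npbc_system")
}

#' @export
print.npbc_system <- function(x, ...) {
  cat(sprintf("npbc_system: %d atoms in %d molecules, cavity R = %.3f A, t = %.4g ps\n",
              nrow(x$positions), nrow(x$com), x$radius, x$time))
  invisible(x)
}

# rebuild atom positions from body variables
rebuild_positions <- function(sys) {
  mol <- sys$topology$atoms$mol
  for (m in seq_len(nrow(sys$com))) {
    idx <- which(mol == m)
    R <- quat_to_mat(sys$quat[m, ])
    sys$positions[idx, ] <- sweep(sys$bodyref[idx, , drop = FALSE] %*% t(R),
                                  2L, sys$com[m, ], "+")
  }
  sys
}

#' Draw initial velocities and angular momenta from the Maxwell distribution
#'
#' COM velocities are drawn per molecule from the Maxwell-Boltzmann
#' distribution at `temperature`; angular momenta are drawn per principal
#' axis from equipartition (`<L_a^2> = I_a k_B T`).  Frozen molecules stay at
#' rest.  Uses the current RNG state (call `set.seed()` for reproducibility).
#'
#' @param sys An `npbc_system`.
#' @param temperature Target temperature (K).
#' @return The system with velocities and angular momenta set.
#' @export
init_velocities <- function(sys, temperature) {
  kT_md <- npbc_constants$k_B * temperature / npbc_constants$ke_conv
  nmol <- nrow(sys$com)
  for (m in seq_len(nmol)) {
    if (!sys$free[m]) next
    sys$vel[m, ] <- rnorm(3, sd = sqrt(kT_md / sys$molmass[m]))
    Ia <- sys$inertia[m, ]
    Lb <- ifelse(Ia > 0, rnorm(3) * sqrt(pmax(Ia, 0) * kT_md), 0)
    sys$angmom[m, ] <- as.numeric(quat_to_mat(sys$quat[m, ]) %*% Lb)
  }
  sys
}

#' Kinetic energy and instantaneous temperature of a rigid system
#'
#' @param sys An `npbc_system`.
#' @return List with `translational`, `rotational` (kJ/mol), `n_dof` and
#'   `temperature` (K).
#' @export
kinetic_info <- function(sys) {
  kt <- 0; kr <- 0; ndf <- 0L
  for (m in seq_len(nrow(sys$com))) {
    if (!sys$free[m]) next
    kt <- kt + 0.5 * sys$molmass[m] * sum(sys$vel[m, ]^2)
    rot <- any(sys$inertia[m, ] > 0)
    ndf <- ndf + 3L + if (rot) 3L else 0L
    if (rot) {
      Lb <- crossprod(quat_to_mat(sys$quat[m, ]), sys$angmom[m, ])
      kr <- kr + 0.5 * sum(ifelse(sys$inertia[m, ] > 0,
                                  Lb^2 / pmax(sys$inertia[m, ], 1e-300), 0))
    }
  }
  kt <- kt * npbc_constants$ke_conv
  kr <- kr * npbc_constants$ke_conv
  list(translational = kt, rotational = kr, n_dof = ndf,
       temperature = if (ndf > 0) 2 * (kt + kr) / (ndf * npbc_constants$k_B)
                     else 0)
}
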