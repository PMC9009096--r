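# Classical nonbonded interactions and the boundary terms of the nonperiodic
# (spherical) model: all-pairs Lennard-Jones + Coulomb (no cutoff -- the
# system is finite, so the full sum is exact), the polynomial mean-field
# potential anchored to the cavity boundary, and the stochastic "rough wall"
# that re-injects escaped molecules with thermal speed.

#' Pairwise Lennard-Jones + Coulomb energy, forces and virial
#'
#' All-pairs sum over atoms of different molecules (intramolecular pairs are
#' excluded).  LJ uses 12-6 with Lorentz-Berthelot combination; sites with
#' `epsilon = 0` have no LJ.  The virial is returned in the
#' origin-independent molecular form `sum_{pairs} r_com_ij . F_ij`.
#'
#' @param positions n x 3 coordinates (A).
#' @param topo A [topology()].
#' @param lj,coulomb Switch individual terms (for ideal-gas reference runs).
#' @return List with `energy`, `e_lj`, `e_coul` (kJ/mol), `forces`
#'   (kJ/mol/A) and `virial` (kJ/mol).
#' @export
pair_energy_forces <- function(positions, topo, lj = TRUE, coulomb = TRUE) {
  a <- topo$atoms
  cpp_pair_forces(positions, a$charge, a$sigma, a$epsilon, a$mol - 1L,
                  pmax(a$mass, 1e-12), lj, coulomb)
}

#' Boundary mean-field potential
#'
#' A polynomial `U(x) = sum_i a_i x^i` in the distance `x = R - |r_com|`
#' from the cavity boundary, active for `x < cutoff_start` and zero beyond.
#' Because the argument is boundary-relative, the potential translates
#' rigidly with the wall when the cavity breathes under pressure coupling.
#'
#' @param coefficients Coefficients `a_0..a_d` (kJ/mol per A^i), degree <= 12.
#' @param cutoff_start Activation distance from the boundary (A).
#' @return A `MeanFieldPotential` object.
#' @export
meanfield_potential <- function(coefficients, cutoff_start) {
  stopifnot(length(coefficients) >= 1L, length(coefficients) <= 13L,
            cutoff_start > 0)
  structure(list(coefficients = as.numeric(coefficients),
                 cutoff_start = cutoff_start, anchor = "boundary"),
            class = "MeanFieldPotential")
}

#' Evaluate a mean-field potential (Horner scheme)
#'
#' @param potential A [meanfield_potential()].
#' @param x Boundary distances (A); clamped at 0 from below.
#' @param derivative Return `dU/dx` as well.
#' @return Values in kJ/mol (list with `value`, `deriv` if requested).
#' @export
eval_meanfield <- function(potential, x, derivative = FALSE) {
  x <- pmax(x, 0)
  a <- potential$coefficients
  v <- rep(0, length(x)); d <- rep(0, length(x))
  act <- x < potential$cutoff_start
  xa <- x[act]
  p <- rep(0, length(xa)); dp <- rep(0, length(xa))
  for (i in rev(seq_along(a))) {
    dp <- dp * xa + p
    p <- p * xa + a[i]
  }
  v[act] <- p; d[act] <- dp
  if (derivative) list(value = v, deriv = d) else v
}

#' Mean-field energy and forces on a rigid system
#'
#' The potential acts on each free molecule's centre of mass at boundary
#' distance `R - |r_com|`; the radial force is distributed to the molecule's
#' atoms by mass fraction.  Molecules beyond the boundary are clamped to
#' boundary distance 0 (the wall takes over there).
#'
#' @param sys An `npbc_system`.
#' @param potential A [meanfield_potential()].
#' @return List with `energy` (kJ/mol), `forces` (per atom, kJ/mol/A) and
#'   `virial` (kJ/mol, `sum r_com . F_mol`).
#' @export
meanfield_energy_forces <- function(sys, potential) {
  topo <- sys$topology
  f <- matrix(0, nrow(sys$positions), 3)
  e <- 0; vir <- 0
  for (m in seq_len(nrow(sys$com))) {
    s <- sqrt(sum(sys$com[m, ]^2))
    barg <- max(sys$radius - s, 0)
    if (barg >= potential$cutoff_start) next
    ev <- eval_meanfield(potential, barg, derivative = TRUE)
    e <- e + ev$value
    # U depends on |r_com| through R - s: F = + U'(x) r_hat
    if (s > 1e-9) {
      fr <- ev$deriv
      u <- sys$com[m, ] / s
      idx <- which(topo$atoms$mol == m)
      wfrac <- topo$atoms$mass[idx] / sys$molmass[m]
      f[idx, ] <- f[idx, ] + outer(wfrac, fr * u)
      vir <- vir + fr * s
    }
  }
  list(energy = e, forces = f, virial = vir)
}

#' Stochastic rough-wall boundary
#'
#' For each free molecule whose centre of mass lies outside the cavity, the
#' COM velocity direction is resampled uniformly on the sphere (flipped
#' inward if pointing outward) with magnitude equal to the Maxwell mean speed
#' `sqrt(8 k_B T / (pi M))`, and the angular momentum direction is resampled
#' the same way with magnitude set to the equipartition r.m.s.
#' `sqrt(sum_a I_a k_B T)`.  Uses the current RNG state.
#'
#' @param sys An `npbc_system`.
#' @param temperature Wall temperature (K).
#' @return List with the updated system and `events`, the number of reset
#'   molecules.
#' @export
rough_wall <- function(sys, temperature) {
  kT_md <- npbc_constants$k_B * temperature / npbc_constants$ke_conv
  events <- 0L
  for (m in seq_len(nrow(sys$com))) {
    if (!sys$free[m]) next
    if (sum(sys$com[m, ]^2) <= sys$radius^2) next
    events <- events + 1L
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    if (sum(u * sys$com[m, ]) > 0) u <- -u
    sys$vel[m, ] <- u * sqrt(8 * kT_md / (pi * sys$molmass[m]))
    if (any(sys$inertia[m, ] > 0)) {
      w <- rnorm(3); w <- w / sqrt(sum(w^2))
      sys$angmom[m, ] <- w * sqrt(sum(sys$inertia[m, ]) * kT_md)
    }
  }
  list(system = sys, events = events)
}
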