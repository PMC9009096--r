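# Conductor-like reaction field of a single spherical cavity.  The apparent
# surface charge (ASC) is expanded in real spherical harmonics; on a single
# sphere the COSMO integral equation is diagonal per (l, m), so the solve is a
# per-coefficient scaling.  Energies, atomic forces and the derivative of the
# solvation energy with respect to the cavity volume share one consistent
# Lebedev discretization of the surface charge, so force / dE/dV identities
# against finite differences hold at fixed grid.

#' Spherical cavity description
#'
#' @param radius Cavity radius R in Angstrom (> 0).
#' @param center Cavity center (3-vector, Angstrom).
#' @param dielectric_mode `"conductor"` (f = 1) or `"scaled"` with
#'   `epsilon > 1`, applying the factor f = (eps - 1)/eps to the ASC.
#' @param epsilon Dielectric constant, used in `"scaled"` mode.
#' @return A `SphericalCavity` object.
#' @export
spherical_cavity <- function(radius, center = c(0, 0, 0),
                             dielectric_mode = c("conductor", "scaled"),
                             epsilon = Inf) {
  dielectric_mode <- match.arg(dielectric_mode)
  stopifnot(length(radius) == 1L, radius > 0, length(center) == 3L)
  if (dielectric_mode == "scaled" && !(epsilon > 1))
    stop("scaled mode requires epsilon > 1")
  f <- if (dielectric_mode == "conductor") 1.0 else (epsilon - 1) / epsilon
  structure(list(radius = radius, center = as.numeric(center),
                 dielectric_mode = dielectric_mode, epsilon = epsilon,
                 f_eps = f),
            class = "SphericalCavity")
}

#' Point-charge distribution inside a cavity
#'
#' @param charges Charges q_k in elementary charges.
#' @param positions n x 3 matrix of positions (Angstrom).
#' @param cavity Optional [spherical_cavity()]; when given, all charges must
#'   lie strictly inside the cavity.
#' @return A `ChargeDistribution` object.
#' @export
charge_distribution <- function(charges, positions, cavity = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3L)
  stopifnot(length(charges) == nrow(positions), all(is.finite(charges)),
            all(is.finite(positions)))
  if (!is.null(cavity)) .check_inside(positions, cavity)
  structure(list(charges = as.numeric(charges), positions = positions),
            class = "ChargeDistribution")
}

.check_inside <- function(positions, cavity) {
  r <- sqrt(rowSums(sweep(positions, 2L, cavity$center)^2))
  bad <- which(r >= cavity$radius)
  if (length(bad))
    stop(sprintf(paste0("charge %d lies on or outside the cavity boundary ",
                        "(|r - center| = %.6g >= R = %.6g); the boundary ",
                        "potential is singular there"),
                 bad[1], r[bad[1]], cavity$radius))
  invisible(TRUE)
}

.rf_call <- function(dist, cavity, grid, basis, want_forces = TRUE) {
  .check_inside(dist$positions, cavity)
  if (grid$precision < 2 * basis$l_max)
    warning(sprintf(paste0("grid precision %d < 2*l_max = %d: harmonic ",
                           "projections are not quadrature-exact"),
                    grid$precision, 2L * basis$l_max))
  cpp_reaction_field(dist$positions, dist$charges, cavity$radius,
                     cavity$center, grid$points, grid$weights, basis$l_max,
                     cavity$f_eps, want_forces)
}

#' Spherical-harmonic coefficients of the boundary potential
#'
#' Projects the molecular electrostatic potential of a charge distribution on
#' the cavity surface onto real spherical harmonics using Lebedev quadrature:
#' `phi_lm = 4*pi * sum_n w_n Phi(R*s_n + center) Y_lm(s_n)` (in kJ/mol/e).
#'
#' @param dist A [charge_distribution()].
#' @param cavity A [spherical_cavity()].
#' @param grid A [build_lebedev_grid()]; its precision should be at least
#'   `2 * l_max`.
#' @param basis A [harmonic_basis()].
#' @return Numeric vector `phi_lm` of length `(l_max+1)^2`.
#' @export
potential_coeffs <- function(dist, cavity, grid, basis) {
  .rf_call(dist, cavity, grid, basis, want_forces = FALSE)$phi_lm
}

#' Solve the single-sphere COSMO equation for the apparent surface charge
#'
#' The single-sphere conductor operator is diagonal in spherical harmonics:
#' `sigma_lm = -f(eps) * (2l+1) / (4*pi*k_e*R) * phi_lm`, with f = 1 in
#' conductor mode.  `sigma_lm` are coefficients of the surface charge density
#' (e/A^2).
#'
#' @param phi_lm Boundary-potential coefficients from [potential_coeffs()].
#' @param cavity A [spherical_cavity()].
#' @return Numeric vector `sigma_lm`.
#' @export
solve_asc <- function(phi_lm, cavity) {
  stopifnot(all(is.finite(phi_lm)))
  n <- length(phi_lm)
  l_max <- as.integer(round(sqrt(n))) - 1L
  if ((l_max + 1L)^2 != n)
    stop("length(phi_lm) is not a perfect square (l_max+1)^2")
  l_of <- rep(0:l_max, times = 2 * (0:l_max) + 1)
  -cavity$f_eps * (2 * l_of + 1) / (4 * pi * npbc_constants$k_e *
                                      cavity$radius) * phi_lm
}

#' Reaction-field solvation energy, forces and volume derivative
#'
#' Computes the conductor-like reaction field of a charge distribution in a
#' spherical cavity: the solvation energy (kJ/mol), per-atom forces
#' (kJ/mol/A) from the field of the discretized surface charge, and the
#' derivative of the energy with respect to the cavity volume (kJ/mol/A^3).
#'
#' @inheritParams potential_coeffs
#' @return A `ReactionFieldResult` list with `energy`, `forces`, `dE_dV`,
#'   `phi_lm`, `sigma_lm`.
#' @examples
#' cav <- spherical_cavity(10)
#' d <- charge_distribution(1, matrix(0, 1, 3))
#' rf <- reaction_field(d, cav, build_lebedev_grid(110), harmonic_basis(6))
#' rf$energy   # Born conductor energy -k_e/(2R)
#' @export
reaction_field <- function(dist, cavity, grid = build_lebedev_grid(302),
                           basis = harmonic_basis(10)) {
  out <- .rf_call(dist, cavity, grid, basis, want_forces = TRUE)
  structure(list(energy = out$energy, forces = out$forces, dE_dV = out$dEdV,
                 phi_lm = out$phi_lm, sigma_lm = out$sigma_lm),
            class = "ReactionFieldResult")
}

#' Solvation energy from a solved surface charge
#'
#' Half the interaction of the apparent surface charge with the solute
#' potential over the boundary, evaluated by Lebedev quadrature.  In conductor
#' mode the result is strictly negative for any nonzero distribution.
#'
#' @inheritParams potential_coeffs
#' @param sigma_lm ASC coefficients from [solve_asc()] for this distribution.
#' @return Energy in kJ/mol.
#' @export
solvation_energy <- function(dist, sigma_lm, cavity, grid) {
  phi_lm <- potential_coeffs(dist, cavity, grid,
                             harmonic_basis(sqrt(length(sigma_lm)) - 1))
  if (length(phi_lm) != length(sigma_lm))
    stop("basis size mismatch between phi_lm and sigma_lm")
  0.5 * cavity$radius^2 * sum(sigma_lm * phi_lm)
}

#' Reaction-field forces on the solute atoms
#'
#' Force on atom k is its charge times the electric field of the discretized
#' node charges `Q_n = 4*pi*w_n*R^2*sigma(s_n)` at `r_k`.  The same
#' discretization enters the energy, so forces match `-dE/dr_k` by central
#' finite differences at fixed grid.
#'
#' @inheritParams potential_coeffs
#' @param sigma_lm ASC coefficients solved for this distribution.
#' @return n x 3 matrix of forces (kJ/mol/A).
#' @export
rf_forces <- function(dist, sigma_lm, cavity, grid) {
  basis <- harmonic_basis(sqrt(length(sigma_lm)) - 1)
  .rf_call(dist, cavity, grid, basis, want_forces = TRUE)$forces
}

#' Derivative of the solvation energy with respect to cavity volume
#'
#' Analytic derivative `dE/dV = (E/R + sum_n Q_n s_n . grad Phi(R s_n)) /
#' (4 pi R^2)`, the boundary-field form of the volume coupling used by the
#' constant-pressure driver.
#'
#' @inheritParams potential_coeffs
#' @param sigma_lm ASC coefficients solved for this distribution.
#' @return dE/dV in kJ/mol/A^3.
#' @export
energy_volume_derivative <- function(dist, sigma_lm, cavity, grid) {
  basis <- harmonic_basis(sqrt(length(sigma_lm)) - 1)
  .rf_call(dist, cavity, grid, basis, want_forces = FALSE)$dEdV
}

#' Closed-form conductor energy of a single off-center charge
#'
#' The exact large-`l_max` limit used as an oracle: a point charge q at
#' distance r from the center of a conductor-bounded sphere of radius R has
#' solvation energy `-k_e q^2 R / (2 (R^2 - r^2))` (the summed Kirkwood
#' series in the conductor limit).
#'
#' @param q Charge (e).
#' @param r Offset from the center (A).
#' @param radius Cavity radius (A).
#' @return Energy in kJ/mol.
#' @export
born_offcenter_energy <- function(q, r, radius) {
  -npbc_constants$k_e * q^2 * radius / (2 * (radius^2 - r^2))
}
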