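# Unit system: length in Angstrom, time in ps, mass in amu, energy in kJ/mol,
# charge in elementary charges, temperature in K.  With these choices
# 1 amu A^2 ps^-2 = 0.01 kJ/mol exactly (N_A * u = 1 g/mol), so kinetic
# energies convert with a single factor and no unit juggling is needed in the
# integrators.

#' Physical constants used throughout the package
#'
#' A named list with the constants of the internal unit system
#' (Angstrom / ps / amu / kJ mol^-1 / elementary charge / K):
#' \describe{
#'   \item{k_e}{Coulomb constant, 1389.35458 kJ mol^-1 A e^-2.}
#'   \item{k_B}{Boltzmann constant, 0.008314462618 kJ mol^-1 K^-1.}
#'   \item{ke_conv}{kinetic-energy conversion, kJ/mol per amu A^2 ps^-2 (0.01).}
#'   \item{p_bar}{pressure conversion, bar per kJ mol^-1 A^-3 (16605.39).}
#'   \item{debye_per_eA}{dipole conversion, Debye per e Angstrom.}
#' }
#' @export
npbc_constants <- list(
  k_e          = 1389.35458,      # Coulomb constant, kJ/mol * A / e^2
  k_B          = 0.008314462618,  # kJ/mol/K
  ke_conv      = 0.01,            # kJ/mol per (amu A^2/ps^2)
  p_bar        = 16605.390671738, # bar per (kJ/mol/A^3)
  debye_per_eA = 4.80320425       # Debye per e*Angstrom
)

# Registry of Lebedev-Laikov node tables; filled by R/lebedev-data-*.R at
# package load (collation order: this file sorts first).
.lebedev_raw <- list()

#' Packaged rigid three-site water models
#'
#' Parameter sets for the SPC and TIP3P-FB rigid water models: partial
#' charges (e), O-H bond length (A), H-O-H angle (degrees) and Lennard-Jones
#' parameters on the oxygen site (sigma in A, epsilon in kJ/mol).
#'
#' @param model `"SPC"` or `"TIP3P-FB"`.
#' @return A list with elements `name`, `q_O`, `q_H`, `r_OH`, `theta_deg`,
#'   `sigma_O`, `eps_O`, `mass_O`, `mass_H`.
#' @examples
#' water_model("SPC")$q_O
#' @export
water_model <- function(model = c("SPC", "TIP3P-FB")) {
  model <- match.arg(model)
  if (model == "SPC") {
    list(name = "SPC",
         q_O = -0.82, q_H = 0.41,
         r_OH = 1.0, theta_deg = 109.47,
         sigma_O = 3.165558, eps_O = 0.650194,
         mass_O = 15.9994, mass_H = 1.008)
  } else {
    list(name = "TIP3P-FB",
         q_O = -0.848448690103, q_H = 0.848448690103 / 2,
         r_OH = 1.01181082494, theta_deg = 108.14844252,
         sigma_O = 3.17796456355, eps_O = 0.652143528104,
         mass_O = 15.9994, mass_H = 1.008)
  }
}

#' Dipole moment of a packaged water model
#'
#' Computes the gas-phase model dipole from the rigid geometry and the point
#' charges: mu = 2 q_H r_OH cos(theta/2), reported in Debye.
#'
#' @inheritParams water_model
#' @return Dipole moment in Debye.
#' @examples
#' water_model_dipole("TIP3P-FB")
#' @export
water_model_dipole <- function(model = c("SPC", "TIP3P-FB")) {
  wm <- water_model(model)
  mu_eA <- 2 * wm$q_H * wm$r_OH * cos(wm$theta_deg / 2 * pi / 180)
  mu_eA * npbc_constants$debye_per_eA
}

#' Packaged boundary mean-field polynomial for SPC water (desk scale)
#'
#' Polynomial boundary mean-field potential for SPC water in an 8.5 A cavity
#' with the conductor-like reaction field active, derived with this package's
#' adaptive shell-optimization and ridge/evolutionary fitting pipeline
#' (see the methods vignette).  Argument is the distance from the cavity
#' boundary (A).
#'
#' @return A `MeanFieldPotential` (degree 4, activation 5.75 A).
#' @export
spc_meanfield <- function() {
  meanfield_potential(
    coefficients = c(4.155100990, -7.313101887, 3.302749316,
                     -0.564199456, 0.032926225),
    cutoff_start = 5.75)
}

#' Packaged boundary mean-field polynomial for TIP3P-FB water
#'
#' The polynomial coefficients (kJ/mol per A^i, i = 0..10) of the fitted
#' boundary mean-field potential for TIP3P-FB water, evaluated on the distance
#' from the cavity boundary.  See [meanfield_potential()].
#'
#' @return A `MeanFieldPotential` object (degree 10, activation 8 A from the
#'   boundary).
#' @export
tip3pfb_meanfield <- function() {
  meanfield_potential(
    coefficients = c(6.958446e+00, -1.381768e+01, -7.095241e+00,
                     2.678593e+01, -2.224122e+01, 9.410601e+00,
                     -2.343013e+00, 3.571387e-01, -3.280733e-02,
                     1.669372e-03, -3.616741e-05),
    cutoff_start = 8.0)
}
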