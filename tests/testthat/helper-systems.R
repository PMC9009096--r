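# Shared in-code fixtures for the test suite.

# random unit vectors
runit <- function(n = 1) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# a topology of n_mol monatomic "molecules" (for ideal-gas and pair tests)
atom_gas_topology <- function(n, mass = 20, charge = 0, sigma = 0, eps = 0) {
  topology(mass = rep_len(mass, n), charge = rep_len(charge, n),
           sigma = rep_len(sigma, n), epsilon = rep_len(eps, n),
           mol = seq_len(n), name = rep("Ar", n))
}

monatomic_system <- function(positions, radius, mass = 20, charge = 0,
                             sigma = 0, eps = 0) {
  n <- nrow(positions)
  make_rigid_system(atom_gas_topology(n, mass, charge, sigma, eps),
                    positions, radius)
}

# small rigid water system helper
small_water <- function(n_target_density = 0.30, radius = 8.5, seed = 4) {
  build_water_sphere(build_spec("SPC", radius, n_target_density, seed = seed))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps),
            tol)
}
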