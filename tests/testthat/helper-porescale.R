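# shared fixtures for the test suite (all generated in code, reduced scale)

# desk-scale translocation parameters
quick_params <- function(Z = 1, E = 8, Nm = 16, seed = 3, ...) {
  sim_params_reduced(Z = Z, E = E, Nm = Nm, seed = seed, ...)
}

# non-interacting (ideal) chain: harmonic bonds only
ideal_params <- function(Nm = 24, seed = 2, ...) {
  sim_params_reduced(Z = 1, E = 0, Nm = Nm, n_salt = 0, eps_pp = 0,
                     lambda_B = 0, seed = seed, ...)
}

# a minimal hand-built system of free beads (no wall geometry assumed)
bead_system <- function(positions, charges, box,
                        species = "salt_cation", bonds = NULL) {
  n <- nrow(positions)
  particle_system(positions, matrix(0, n, 3), charges,
                  rep(species, length.out = n), bonds, box)
}

# Table-1 style theory parameter set assembled from observed exponents
observed_theory_params <- function(Z) {
  obs <- observed_exponents(Z)
  inv <- invert_observed(obs$alpha_UB, obs$alpha_SDT, obs$alpha_SDI,
                         obs$delta_SDT, obs$gamma_p)
  theory_params(nu_s = inv$nu_s, gamma_p = obs$gamma_p, z_p = inv$z_p,
                q = inv$q, p_z = obs$delta_SDT / (1 - inv$q),
                rho = inv$rho, eta = inv$eta)
}
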