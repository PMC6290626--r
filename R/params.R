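#' Simulation parameters for a translocation system
#'
#' Full physical and numerical configuration of one coarse-grained
#' translocation system: a bead-spring polyelectrolyte of `Nm` monomers
#' (each carrying charge -e and dissociating one monovalent counterion),
#' `n_salt` molecules of (Z:1) salt, a slab wall pierced by a cylindrical
#' pore along x, and a uniform driving field `E` applied inside the pore.
#' Reduced units: length sigma, energy kBT, charge e, mass m, time
#' `tu = sigma * sqrt(m/kBT)`; all of m, kBT and the mobile-bead mass are 1.
#'
#' @param Z salt valence, 1 or 2 (required, no default).
#' @param E driving field strength in kBT/(e sigma) (required; the study
#'   sweeps 0.001 to 64).
#' @param Nm number of chain monomers (integer >= 6; the first five span the
#'   pore initially, so N = Nm - 5 are transported).
#' @param box box lengths `(Lx, Ly, Lz)` in sigma.
#' @param wall_thickness slab thickness in sigma.
#' @param pore_radius pore radius in sigma (must be < min(Ly, Lz)/2).
#' @param lambda_B Bjerrum length in sigma.
#' @param eps_pp,sigma_pp WCA parameters between mobile particles (kBT,
#'   sigma).
#' @param eps_pw,sigma_pw WCA parameters between mobile particles and the
#'   wall (kBT, sigma).
#' @param k_bond,b0 harmonic-bond spring constant (kBT/sigma^2) and
#'   equilibrium length (sigma).
#' @param n_salt number of salt molecules.
#' @param damping_time Langevin thermostat damping time in tu (friction
#'   gamma = m/damping_time).
#' @param dt integration step in tu; default 0.005 (the bond oscillation
#'   period is about `2*pi*sqrt(m/k_bond)` = 0.26 tu, giving > 50 steps per
#'   period).
#' @param seed integer seed for initialization and dynamics.
#' @param electrostatics_mode `"dsf"` (damped shifted-force real-space
#'   Coulomb, the working solver) or `"ewald"` (classical Ewald summation,
#'   reference, available for energy evaluation).
#' @param coulomb_cutoff real-space cutoff of the DSF solver in sigma
#'   (must be <= half the smallest box length).
#' @param dsf_alpha DSF damping parameter in 1/sigma.
#' @param barrier_sigma range parameter of the one-sided head-monomer
#'   barrier at the pore exit, in sigma.
#' @return An object of class `sim_params` (named list).
#' @export
#' @examples
#' p <- sim_params(Z = 1, E = 0.5, Nm = 64)
sim_params <- function(Z, E, Nm = 128,
                       box = c(200.0, 48.0, 49.4),
                       wall_thickness = 4.5, pore_radius = 2.25,
                       lambda_B = 3.0,
                       eps_pp = 1.2, sigma_pp = 1.0,
                       eps_pw = 2.5, sigma_pw = 1.5,
                       k_bond = 600.0, b0 = 1.0,
                       n_salt = 256, damping_time = 1.0, dt = 0.005,
                       seed = 1L,
                       electrostatics_mode = c("dsf", "ewald"),
                       coulomb_cutoff = 10.0, dsf_alpha = 0.2,
                       barrier_sigma = 0.3) {
  if (missing(Z)) stop("`Z` must be stated explicitly (1 or 2); there is no default",
                       call. = FALSE)
  if (missing(E)) stop("`E` must be stated explicitly", call. = FALSE)
  electrostatics_mode <- match.arg(electrostatics_mode)
  p <- list(Z = as.integer(Z), Nm = as.integer(Nm), E = as.numeric(E),
            box = as.numeric(box), wall_thickness = wall_thickness,
            pore_radius = pore_radius, lambda_B = lambda_B,
            eps_pp = eps_pp, sigma_pp = sigma_pp,
            eps_pw = eps_pw, sigma_pw = sigma_pw,
            k_bond = k_bond, b0 = b0, n_salt = as.integer(n_salt),
            damping_time = damping_time, dt = dt, seed = as.integer(seed),
            electrostatics_mode = electrostatics_mode,
            coulomb_cutoff = coulomb_cutoff, dsf_alpha = dsf_alpha,
            barrier_sigma = barrier_sigma)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(p$Z %in% c(1L, 2L), "`Z` must be 1 or 2")
  chk(p$Nm >= 6L, "`Nm` must be an integer >= 6")
  chk(p$E >= 0, "`E` must be non-negative")
  chk(length(p$box) == 3 && all(p$box > 0), "`box` must be 3 positive lengths")
  for (nm in c("wall_thickness", "pore_radius", "sigma_pp", "sigma_pw",
               "b0", "k_bond", "damping_time", "dt", "coulomb_cutoff",
               "dsf_alpha", "barrier_sigma"))
    chk(p[[nm]] > 0, paste0("`", nm, "` must be strictly positive"))
  for (nm in c("eps_pp", "eps_pw", "lambda_B"))
    chk(p[[nm]] >= 0, paste0("`", nm, "` must be non-negative"))
  chk(p$n_salt >= 0, "`n_salt` must be non-negative")
  chk(p$pore_radius < min(p$box[2:3]) / 2,
      "`pore_radius` must be smaller than min(Ly, Lz)/2")
  chk(p$dt < p$damping_time, "`dt` must be smaller than `damping_time`")
  chk(p$coulomb_cutoff <= min(p$box) / 2,
      "`coulomb_cutoff` must not exceed half the smallest box length")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> Z =", x$Z, " Nm =", x$Nm, " E =", x$E,
      " n_salt =", x$n_salt, "\n  box =", paste(x$box, collapse = " x "),
      "sigma;", x$electrostatics_mode, "electrostatics\n")
  invisible(x)
}

#' Reduced-scale simulation parameters
#'
#' Desk-scale defaults used throughout the tests and examples: a short chain
#' in a 60 x 16 x 16 sigma box with 8 salt molecules, which keeps the salt
#' concentration comparable to the full-scale system (256 molecules in
#' 200 x 48 x 49.4 sigma). All interaction parameters keep their full-scale
#' values.
#'
#' @inheritParams sim_params
#' @param ... further arguments passed to [sim_params()].
#' @return A `sim_params` object.
#' @export
sim_params_reduced <- function(Z, E, Nm = 16, n_salt = 8, ...) {
  sim_params(Z = Z, E = E, Nm = Nm, n_salt = n_salt,
             box = c(60, 16, 16), coulomb_cutoff = 7.0, ...)
}

# geometry helpers -----------------------------------------------------------

wall_center <- function(params) params$box[1] / 2
pore_axis <- function(params) params$box[2:3] / 2
pore_exit <- function(params) wall_center(params) + params$wall_thickness / 2

# parameter list handed to the compiled engine
engine_params <- function(params, wall_on = TRUE, barrier_on = TRUE,
                          field_on = TRUE, tether = NULL) {
  c(unclass(params),
    list(wall_on = wall_on, barrier_on = barrier_on, field_on = field_on,
         x_wall = wall_center(params),
         y0 = pore_axis(params)[1], z0 = pore_axis(params)[2],
         tether = if (is.null(tether)) numeric(0) else as.numeric(tether)))
}
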