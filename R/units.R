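#' Simulation-to-experiment unit system
#'
#' The coarse-grained model maps onto double-stranded DNA in aqueous salt
#' with one bead representing about 0.7 bp, a time unit of about 2.13 ps and
#' an electric-field unit of about 100 mV/nm.
#'
#' @param sigma_bp base pairs per length unit sigma (default 0.7).
#' @param tu_ps picoseconds per time unit tu (default 2.13).
#' @param Eu_mV_per_nm mV/nm per field unit (default 100).
#' @return An object of class `unit_system`.
#' @export
unit_system <- function(sigma_bp = 0.7, tu_ps = 2.13, Eu_mV_per_nm = 100) {
  stopifnot(sigma_bp > 0, tu_ps > 0, Eu_mV_per_nm > 0)
  structure(list(sigma_bp = sigma_bp, tu_ps = tu_ps,
                 Eu_mV_per_nm = Eu_mV_per_nm),
            class = "unit_system")
}

#' @export
print.unit_system <- function(x, ...) {
  cat("<unit_system> 1 sigma =", x$sigma_bp, "bp; 1 tu =", x$tu_ps,
      "ps; 1 Eu =", x$Eu_mV_per_nm, "mV/nm\n")
  invisible(x)
}

#' Experiment records for unit conversion
#'
#' Builds the tidy table of experimental nanopore-translocation records the
#' converter operates on.
#'
#' @param label free-text identifier.
#' @param contour_bp contour length in base pairs.
#' @param tau_s translocation time in seconds.
#' @param field_mV_per_nm transmembrane field in mV/nm.
#' @param salt `"monovalent"` or `"divalent"`.
#' @return A tibble with those columns.
#' @export
#' @examples
#' experiment_records("pBR322 + MgCl2", 4400, 145e-6, 8, "divalent")
experiment_records <- function(label, contour_bp, tau_s, field_mV_per_nm,
                               salt) {
  salt <- match.arg(salt, c("monovalent", "divalent"), several.ok = TRUE)
  stopifnot(all(contour_bp > 0), all(tau_s > 0), all(field_mV_per_nm > 0))
  tibble::tibble(label = label, contour_bp = contour_bp, tau_s = tau_s,
                 field_mV_per_nm = field_mV_per_nm,
                 salt = rep(salt, length.out = length(label)))
}

#' Convert experimental records to simulation units
#'
#' Maps contour length, translocation time and transmembrane field into the
#' simulation's reduced units: `N = round(contour_bp / sigma_bp)`,
#' `tau_sim = tau_ps / tu_ps`, `E_sim = field / Eu`.
#'
#' @param records a tibble as produced by [experiment_records()].
#' @param units a [unit_system()].
#' @return The input tibble with columns `N`, `tau_sim`, `E_sim` appended.
#' @export
#' @examples
#' rec <- experiment_records("pBR322", 4400, 145e-6, 8, "divalent")
#' to_simulation_units(rec)  # N = 6286, tau_sim ~ 6.8e7, E_sim = 0.08
to_simulation_units <- function(records, units = unit_system()) {
  stopifnot(inherits(units, "unit_system"),
            all(c("contour_bp", "tau_s", "field_mV_per_nm") %in%
                  names(records)))
  dplyr::mutate(records,
    N = round(.data$contour_bp / units$sigma_bp),
    tau_sim = .data$tau_s * 1e12 / units$tu_ps,
    E_sim = .data$field_mV_per_nm / units$Eu_mV_per_nm)
}

#' Convert simulation quantities back to experimental units
#'
#' Exact inverse of [to_simulation_units()] up to the integer rounding of N.
#'
#' @param N chain length in monomers.
#' @param tau_sim translocation time in tu.
#' @param E_sim driving field in simulation field units.
#' @param units a [unit_system()].
#' @param label,salt carried through to the output record.
#' @return A tibble in the [experiment_records()] layout.
#' @export
from_simulation_units <- function(N, tau_sim, E_sim, units = unit_system(),
                                  label = NA_character_,
                                  salt = "monovalent") {
  stopifnot(inherits(units, "unit_system"))
  tibble::tibble(label = rep(label, length.out = length(N)),
                 contour_bp = N * units$sigma_bp,
                 tau_s = tau_sim * units$tu_ps * 1e-12,
                 field_mV_per_nm = E_sim * units$Eu_mV_per_nm,
                 salt = rep(salt, length.out = length(N)))
}

#' Merge experimental records and simulated means onto one scaling table
#'
#' Produces one tidy table of (source, salt, N, tau, E), everything in
#' simulation units, suitable for a log-log tau-versus-N overlay of
#' experiments on the simulated scaling curves.
#'
#' @param records experiment tibble ([experiment_records()] layout).
#' @param simulated tibble with columns `Z`, `N`, `tau` (mean translocation
#'   time in tu) and optionally `E`.
#' @param units a [unit_system()].
#' @return A tibble with columns `source` (`"experiment"`/`"simulation"`),
#'   `label`, `salt`, `N`, `tau`, `E`.
#' @export
comparison_table <- function(records, simulated, units = unit_system()) {
  if (is.null(simulated) || nrow(simulated) == 0)
    stop("no simulated points supplied", call. = FALSE)
  if (is.null(records) || nrow(records) == 0)
    stop("no experimental records supplied", call. = FALSE)
  stopifnot(all(c("Z", "N", "tau") %in% names(simulated)))
  exp_tab <- to_simulation_units(records, units)
  exp_out <- tibble::tibble(source = "experiment", label = exp_tab$label,
                            salt = exp_tab$salt, N = exp_tab$N,
                            tau = exp_tab$tau_sim, E = exp_tab$E_sim)
  sim_out <- tibble::tibble(
    source = "simulation",
    label = paste0("Z=", simulated$Z, " N=", simulated$N),
    salt = ifelse(simulated$Z == 2, "divalent", "monovalent"),
    N = simulated$N, tau = simulated$tau,
    E = if ("E" %in% names(simulated)) simulated$E else NA_real_)
  dplyr::bind_rows(exp_out, sim_out)
}
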