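#' Forces and potential energy from the compiled engine
#'
#' Evaluates the full force field (WCA, DSF Coulomb, bonds, analytic wall,
#' head barrier, in-pore driving field) at the current state. Forces are the
#' analytic negative gradients of the potential terms; the driving field is
#' the only non-conservative term and can be switched off to compare against
#' finite differences of [total_energy()].
#'
#' @param system a [particle_system()].
#' @param params a [sim_params()] object.
#' @param wall,barrier,field logical switches for the corresponding terms.
#' @return A list: `forces` (n x 3 matrix, kBT/sigma) and `energy`
#'   (potential energy, kBT, excluding the field).
#' @export
compute_forces <- function(system, params, wall = TRUE, barrier = TRUE,
                           field = TRUE) {
  par <- engine_params(params, wall_on = wall, barrier_on = barrier,
                       field_on = field)
  .ps_forces(system$positions, system$velocities, system$charges, par)
}

#' Advance a system by Langevin dynamics
#'
#' One (or more) BAOAB velocity-Verlet-with-Ornstein-Uhlenbeck steps of the
#' Langevin thermostat at kBT = 1 with friction `gamma = m/damping_time`.
#' The fluctuation-dissipation balance is satisfied exactly by the
#' Ornstein-Uhlenbeck substep; with the thermostat disabled the scheme
#' reduces to plain (symplectic) velocity Verlet.
#'
#' @inheritParams compute_forces
#' @param n_steps number of steps of length `params$dt`.
#' @param seed RNG seed of the noise stream (defaults to `params$seed`).
#' @param thermostat logical; disable for microcanonical integration.
#' @param freeze_head hold monomer 1 fixed (the pre-release constraint)?
#' @return The updated [particle_system()].
#' @export
langevin_step <- function(system, params, n_steps = 1L,
                          seed = params$seed, thermostat = TRUE,
                          freeze_head = FALSE, wall = TRUE, barrier = TRUE,
                          field = FALSE) {
  par <- engine_params(params, wall_on = wall, barrier_on = barrier,
                       field_on = field)
  out <- .ps_run_nvt(system$positions, system$velocities, system$charges,
                     par, time = n_steps * params$dt, sample_every = n_steps,
                     freeze_head = freeze_head, thermostat = thermostat,
                     seed = as.double(seed))
  system$positions <- out$positions
  system$velocities <- out$velocities
  system
}

#' Relax a system under the head constraint
#'
#' Runs thermostatted dynamics with monomer 1 frozen and the driving field
#' off, the preparation stage of every translocation run.
#'
#' @inheritParams langevin_step
#' @param time relaxation time in tu.
#' @return The relaxed [particle_system()].
#' @export
equilibrate <- function(system, params, time, seed = params$seed,
                        freeze_head = TRUE) {
  langevin_step(system, params, n_steps = ceiling(time / params$dt),
                seed = seed, thermostat = TRUE, freeze_head = freeze_head,
                wall = TRUE, barrier = TRUE, field = FALSE)
}

#' Run one translocation event
#'
#' Builds the threaded initial state, relaxes it under the head constraint,
#' then releases the head and switches on the in-pore field, integrating
#' until the chain has definitely left the cis side: the translocation time
#' tau is the last time any monomer occupied the cis region, evaluated once
#' no monomer remains on the cis side or in the pore and the chain centre of
#' mass sits more than one radius of gyration beyond the wall (the head
#' barrier excludes a full retraction). The translocation coordinate n(t)
#' counts the monomers transported out of the cis region
#' (`n = N - cis_count`, clamped to `[0, N]`); N = Nm - 5 monomers start on
#' the cis side since the first five span the pore at t = 0, so a completed
#' run ends at n = N.
#'
#' @param params a [sim_params()] object.
#' @param max_time integration cap in tu; default `1e4 * (Nm - 5)`. Runs
#'   hitting the cap are flagged `max_time_reached` (tau = NA) and excluded
#'   from averages by [mean_tau()], never dropped silently.
#' @param equil_time constrained-relaxation time in tu; default
#'   `50 * (Nm - 5)^1.2`.
#' @param sample_dt sampling stride of the n(t) series in tu.
#' @param seed run seed (defaults to `params$seed`).
#' @return An object of class `translocation_event`: a list with `tau`,
#'   `status`, `N`, `seed`, `n_series` (tibble `t`, `n`, `cis`),
#'   `min_head_gap` (minimum head-monomer distance beyond the exit plane)
#'   and `final_state` (a [particle_system()]).
#' @export
run_translocation <- function(params, max_time = NULL, equil_time = NULL,
                              sample_dt = 0.5, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  N <- params$Nm - 5L
  if (is.null(max_time)) max_time <- 1e4 * N
  if (is.null(equil_time)) equil_time <- 50 * N^1.2
  p2 <- params; p2$seed <- as.integer(seed)
  sys <- build_initial_state(p2)
  par <- engine_params(p2, wall_on = TRUE, barrier_on = TRUE, field_on = TRUE)
  out <- .ps_run_translocation(sys$positions, sys$velocities, sys$charges,
                               par, equil_time = equil_time,
                               max_time = max_time, sample_dt = sample_dt,
                               seed = as.double(seed))
  sys$positions <- out$positions
  sys$velocities <- out$velocities
  structure(list(
    tau = out$tau, status = out$status, N = N, Nm = params$Nm,
    Z = params$Z, E = params$E, seed = as.integer(seed),
    n_series = tibble::tibble(t = out$t, n = out$n, cis = out$cis),
    min_head_gap = out$min_head_gap,
    final_state = sys), class = "translocation_event")
}

#' @export
print.translocation_event <- function(x, ...) {
  cat("<translocation_event> Z =", x$Z, " N =", x$N, " E =", x$E,
      " seed =", x$seed, "\n  status:", x$status, " tau =",
      format(x$tau, digits = 5), "tu\n")
  invisible(x)
}

#' Run a batch of independent translocation events
#'
#' Runs `n_runs` independent events with seeds `seed0, seed0 + 1, ...`
#' (each seed controls both the initial configuration and the noise
#' stream), in stable order.
#'
#' @inheritParams run_translocation
#' @param n_runs number of independent runs (>= 1).
#' @param seed0 first seed.
#' @param keep_series keep the n(t) series (list-column)? Set `FALSE` to
#'   save memory in large sweeps.
#' @return A batch tibble with one row per run: `seed`, `tau`, `status`,
#'   `N`, `Z`, `E` and (optionally) `n_series`.
#' @export
run_batch <- function(params, n_runs, seed0 = params$seed, max_time = NULL,
                      equil_time = NULL, sample_dt = 0.5,
                      keep_series = TRUE) {
  stopifnot(n_runs >= 1)
  events <- purrr::map(seq_len(n_runs) - 1L, function(k)
    run_translocation(params, max_time = max_time, equil_time = equil_time,
                      sample_dt = sample_dt, seed = seed0 + k))
  out <- tibble::tibble(
    seed = purrr::map_int(events, "seed"),
    tau = purrr::map_dbl(events, "tau"),
    status = purrr::map_chr(events, "status"),
    N = purrr::map_int(events, "N"),
    Z = purrr::map_int(events, "Z"),
    E = purrr::map_dbl(events, "E"))
  if (keep_series)
    out$n_series <- purrr::map(events, function(e)
      e$n_series[, c("t", "n")])
  out
}

#' Equilibrium size profile of a wall-tethered chain
#'
#' Anchors monomer 1 by a harmonic bond to a point on the cis face of the
#' wall (off the pore axis), relaxes, then samples the mean distance
#' `<R_m>` of every monomer m to the tethering point. No driving field.
#'
#' @inheritParams run_translocation
#' @param n_samples number of samples entering each `<R_m>`.
#' @param burn_time relaxation time before sampling (tu); default
#'   `20 * Nm`.
#' @param sample_dt time between samples (tu).
#' @return A tibble of class `static_chain_sample` with columns `m`,
#'   `R_mean`; attributes `mode = "tethered"` and `n_samples`.
#' @export
sample_tethered_chain <- function(params, n_samples = 200,
                                  burn_time = NULL, sample_dt = 2,
                                  seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(burn_time)) burn_time <- 20 * params$Nm
  tether <- c(wall_center(params) - params$wall_thickness / 2 - 1.0,
              min(pore_axis(params)[1] + params$box[2] / 4,
                  params$box[2] - 2),
              pore_axis(params)[2])
  sys <- build_static_state(params, start = tether - c(params$b0, 0, 0),
                            wall = TRUE, seed = seed)
  par <- engine_params(params, wall_on = TRUE, barrier_on = FALSE,
                       field_on = FALSE, tether = tether)
  out <- .ps_run_static(sys$positions, sys$velocities, sys$charges, par,
                        mode = 0L, burn_time = burn_time,
                        sample_dt = sample_dt, n_samples = n_samples,
                        seed = as.double(seed))
  res <- tibble::tibble(m = seq_len(params$Nm),
                        R_mean = out$acc / pmax(out$cnt, 1))
  attr(res, "mode") <- "tethered"
  attr(res, "n_samples") <- n_samples
  class(res) <- c("static_chain_sample", class(res))
  res
}

#' Equilibrium pair-distance profile of a free chain
#'
#' Simulates the chain with its counterions and salt in free solution (no
#' wall, no field) and samples the mean distance `<R_ij>` of monomer pairs
#' at bond separation s = |i - j|, averaged over all pairs at fixed s.
#'
#' @inheritParams sample_tethered_chain
#' @return A tibble of class `static_chain_sample` with columns `s`,
#'   `R_mean`; attributes `mode = "free"` and `n_samples`.
#' @export
sample_free_chain <- function(params, n_samples = 200, burn_time = NULL,
                              sample_dt = 2, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(burn_time)) burn_time <- 20 * params$Nm
  start <- c(2, params$box[2] / 2, params$box[3] / 2)
  sys <- build_static_state(params, start = start, wall = FALSE, seed = seed)
  par <- engine_params(params, wall_on = FALSE, barrier_on = FALSE,
                       field_on = FALSE)
  out <- .ps_run_static(sys$positions, sys$velocities, sys$charges, par,
                        mode = 1L, burn_time = burn_time,
                        sample_dt = sample_dt, n_samples = n_samples,
                        seed = as.double(seed))
  res <- tibble::tibble(s = seq_len(params$Nm - 1L),
                        R_mean = out$acc[-1] / pmax(out$cnt[-1], 1))
  attr(res, "mode") <- "free"
  attr(res, "n_samples") <- n_samples
  class(res) <- c("static_chain_sample", class(res))
  res
}

# chain laid out from `start` along -x with serpentine turns, plus ions
build_static_state <- function(params, start, wall, seed = params$seed,
                               max_tries = 2000L) {
  sc <- species_counts(params)
  box <- params$box
  b <- params$b0
  margin <- 1.7
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)

  xmin <- margin
  xmax <- if (wall) wall_center(params) - params$wall_thickness / 2 - margin
          else box[1] - margin
  pos <- matrix(NA_real_, params$Nm, 3)
  x <- start[1]; y <- start[2]; z <- start[3]; dirx <- -1
  for (i in seq_len(params$Nm)) {
    pos[i, ] <- c(x, y, z)
    nx <- x + dirx * b
    if (nx >= xmin && nx <= xmax) x <- nx
    else {
      y <- y + b
      if (y > box[2] - margin) { y <- margin + 0.5; z <- z + b }
      if (z > box[3] - margin)
        stop("packing error: box too small for this chain", call. = FALSE)
      dirx <- -dirx
    }
  }
  n_ions <- sum(sc$count[-1])
  ion_pos <- matrix(NA_real_, n_ions, 3)
  placed <- pos
  for (i in seq_len(n_ions)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- stats::runif(3) * box
      if (wall && wall_gap(cand, params) < margin) next
      d <- sweep(placed, 2, cand)
      d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
      if (min(sqrt(rowSums(d^2))) < 1.0) next
      ok <- TRUE; break
    }
    if (!ok) stop("packing error: could not insert ion ", i, call. = FALSE)
    ion_pos[i, ] <- cand
    placed <- rbind(placed, cand)
  }
  all_pos <- rbind(pos, ion_pos)
  n <- nrow(all_pos)
  particle_system(all_pos, matrix(stats::rnorm(3 * n), n, 3),
                  rep(sc$charge, sc$count), rep(sc$species, sc$count),
                  cbind(seq_len(params$Nm - 1L), 2:params$Nm), box)
}
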