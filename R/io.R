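#' Load a simulation configuration
#'
#' Reads a YAML configuration into a [sim_params()] object plus analysis
#' settings. Every simulation key carries the full-scale default when
#' omitted, except `Z` (and `E`), which must be stated; unknown keys are
#' rejected with the offending name.
#'
#' Recognised top-level keys: every argument of [sim_params()], plus the
#' optional blocks `run` (`n_runs`, `seed0`, `max_time`, `equil_time`,
#' `sample_dt`) and `analysis` (`gamma_window`, a length-2 numeric).
#'
#' @param path path to a YAML file.
#' @return A list: `params` (a `sim_params`), `run` (list), `analysis`
#'   (list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  sim_keys <- names(formals(sim_params))
  extra <- setdiff(names(cfg), c(sim_keys, "run", "analysis"))
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$Z))
    stop("configuration must state `Z` (1 or 2); there is no default",
         call. = FALSE)
  if (is.null(cfg$E))
    stop("configuration must state `E`", call. = FALSE)
  params <- do.call(sim_params, cfg[intersect(names(cfg), sim_keys)])
  run <- cfg$run %||% list()
  run$n_runs <- run$n_runs %||% 10L
  run$seed0 <- run$seed0 %||% params$seed
  analysis <- cfg$analysis %||% list()
  analysis$gamma_window <- analysis$gamma_window %||% c(0.01, 0.1)
  list(params = params, run = run, analysis = analysis)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a batch event table
#'
#' One CSV row per run (`seed`, `tau`, `status`, `N`, `Z`, `E`); the n(t)
#' series travel in a companion long-format CSV (`seed`, `t`, `n`). A header
#' comment records that values are in simulation units.
#'
#' @param events a batch tibble from [run_batch()].
#' @param path output CSV path for the event table.
#' @param series_path optional CSV path for the n(t) series.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, series_path = NULL) {
  flat <- events[setdiff(names(events), "n_series")]
  con <- file(path, "w")
  writeLines("# translocation events; units: tau in tu, E in kBT/(e sigma)",
             con)
  utils::write.csv(flat, con, row.names = FALSE)
  close(con)
  if (!is.null(series_path) && "n_series" %in% names(events)) {
    long <- dplyr::bind_rows(
      purrr::map2(events$n_series, events$seed,
                  function(sr, sd) dplyr::mutate(sr, seed = sd)))
    con <- file(series_path, "w")
    writeLines("# translocation coordinate series; t in tu", con)
    utils::write.csv(long[, c("seed", "t", "n")], con, row.names = FALSE)
    close(con)
  }
  invisible(path)
}

#' @rdname write_events
#' @return `read_events()`: the batch tibble (with `n_series` list-column if
#'   a series file is given).
#' @export
read_events <- function(path, series_path = NULL) {
  flat <- utils::read.csv(path, comment.char = "#")
  out <- tibble::as_tibble(flat)
  out$status <- as.character(out$status)
  if (!is.null(series_path)) {
    long <- tibble::as_tibble(utils::read.csv(series_path,
                                              comment.char = "#"))
    out$n_series <- purrr::map(out$seed, function(sd) {
      sr <- long[long$seed == sd, c("t", "n")]
      tibble::as_tibble(sr)
    })
  }
  out
}

#' Write / read extended-XYZ trajectory frames
#'
#' Plain-text extended-XYZ: per frame an atom count, a comment line with
#' `Lattice` and `Time`, then one line per particle
#' (`species x y z charge`).
#'
#' @param systems a [particle_system()] or list of them (frames).
#' @param path output file.
#' @param times frame times in tu (defaults to frame index).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(systems, path, times = NULL) {
  if (inherits(systems, "particle_system")) systems <- list(systems)
  if (is.null(times)) times <- seq_along(systems) - 1
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(systems)) {
    s <- systems[[k]]
    writeLines(as.character(nrow(s$positions)), con)
    writeLines(sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3:charge:I:1 Time=%g',
      s$box[1], s$box[2], s$box[3], times[k]), con)
    writeLines(sprintf("%s %.10g %.10g %.10g %d", s$species,
                       s$positions[, 1], s$positions[, 2], s$positions[, 3],
                       s$charges), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @return `read_xyz()`: a list of [particle_system()] frames (velocities
#'   zero, bonds reconstructed for the leading block of monomers).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- lines[i + 1]
    lat <- regmatches(hdr, regexpr('Lattice="[^"]*"', hdr))
    nums <- as.numeric(strsplit(sub('Lattice="', '', sub('"$', '', lat)),
                                " ")[[1]])
    box <- nums[c(1, 5, 9)]
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(body, " +")
    species <- vapply(parts, `[[`, character(1), 1)
    pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    charge <- vapply(parts, function(p) as.integer(p[5]), integer(1))
    nm <- sum(species == "monomer")
    bonds <- if (nm >= 2) cbind(seq_len(nm - 1L), 2:nm) else NULL
    frames[[length(frames) + 1]] <-
      particle_system(pos, matrix(0, n, 3), charge, species, bonds, box)
    i <- i + 2 + n
  }
  frames
}

#' Run the simulate-analyze-report pipeline
#'
#' Executes a batch of translocation runs from a configuration, writes the
#' event and series CSVs, computes the mean translocation time and the
#' variance-curve diffusion exponent, and returns a reproducible manifest.
#'
#' @param config a configuration list from [load_config()], or a path to a
#'   YAML file.
#' @param out_dir output directory (created if needed).
#' @param verbose print progress?
#' @return A list of class `run_manifest`: `params`, `seeds`, `files`,
#'   `n_completed`, `n_failed`, `summary` (tibble), `version`, `elapsed_s`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("porescale_"),
                         verbose = FALSE) {
  t0 <- Sys.time()
  if (is.character(config)) config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  if (config$run$n_runs == 0) {        # theory-only configuration: no MD
    return(structure(list(
      params = p, seeds = integer(0), files = character(0),
      n_completed = 0L, n_failed = 0L, summary = NULL,
      version = as.character(utils::packageVersion("porescale")),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      class = "run_manifest"))
  }
  if (verbose) message("batch: ", config$run$n_runs, " runs, Z=", p$Z,
                       " Nm=", p$Nm, " E=", p$E)
  events <- run_batch(p, n_runs = config$run$n_runs,
                      seed0 = config$run$seed0,
                      max_time = config$run$max_time %||% NULL,
                      equil_time = config$run$equil_time %||% NULL,
                      sample_dt = config$run$sample_dt %||% 0.5)
  f_events <- file.path(out_dir, "events.csv")
  f_series <- file.path(out_dir, "n_series.csv")
  write_events(events, f_events, f_series)
  summ <- mean_tau(events)
  gam <- tryCatch({
    v <- translocation_variance(events)
    fit_gamma(v, window = config$analysis$gamma_window)
  }, error = function(e) NULL)
  f_summary <- file.path(out_dir, "summary.csv")
  utils::write.csv(dplyr::bind_cols(
    tibble::tibble(Z = p$Z, Nm = p$Nm, E = p$E), summ,
    tibble::tibble(gamma = if (is.null(gam)) NA_real_ else gam$value)),
    f_summary, row.names = FALSE)
  structure(list(
    params = p,
    seeds = config$run$seed0 + seq_len(config$run$n_runs) - 1L,
    files = c(events = f_events, series = f_series, summary = f_summary),
    n_completed = summ$n_completed, n_failed = summ$n_failed,
    summary = summ,
    version = as.character(utils::packageVersion("porescale")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", length(x$seeds), "runs (", x$n_completed,
      "completed,", x$n_failed, "failed ) in",
      format(x$elapsed_s, digits = 3), "s\n  files:",
      paste(basename(x$files), collapse = ", "), "\n")
  invisible(x)
}
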