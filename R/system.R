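#' Particle system state
#'
#' The evolving state of one simulation: positions (kept unwrapped; the
#' minimum-image convention is applied wherever interactions or regions are
#' evaluated), velocities, signed charges, per-particle species tags, the
#' chain bond topology and the periodic box.
#'
#' @param positions n x 3 numeric matrix (sigma).
#' @param velocities n x 3 numeric matrix (sigma/tu).
#' @param charges integer vector of signed charges (e).
#' @param species character vector: `"monomer"`, `"chain_counterion"`,
#'   `"salt_cation"` or `"salt_anion"`.
#' @param bonds two-column integer matrix of bonded index pairs (i, i+1)
#'   along the chain.
#' @param box length-3 periodic cell (sigma).
#' @param head_index index of monomer 1 (the head).
#' @return An object of class `particle_system`.
#' @export
particle_system <- function(positions, velocities, charges, species, bonds,
                            box, head_index = 1L) {
  positions <- as.matrix(positions); velocities <- as.matrix(velocities)
  stopifnot(ncol(positions) == 3, all(dim(velocities) == dim(positions)),
            length(charges) == nrow(positions),
            length(species) == nrow(positions), length(box) == 3)
  bonds <- if (is.null(bonds)) matrix(integer(0), 0, 2) else as.matrix(bonds)
  structure(list(positions = positions, velocities = velocities,
                 charges = as.integer(charges), species = species,
                 bonds = bonds, box = as.numeric(box),
                 head_index = as.integer(head_index)),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat("<particle_system>", nrow(x$positions), "particles (",
      sum(x$species == "monomer"), "monomers,",
      sum(x$species != "monomer"), "ions ), net charge",
      sum(x$charges), "\n")
  invisible(x)
}

#' Species composition implied by the dissociation rules
#'
#' Each monomer carries -e and releases one monovalent counterion; each salt
#' molecule dissociates into one +Z cation and Z monovalent anions, so any
#' system built by the initializer is exactly charge neutral.
#'
#' @param params a [sim_params()] object.
#' @return A tibble with columns `species`, `count`, `charge`.
#' @export
species_counts <- function(params) {
  tibble::tibble(
    species = c("monomer", "chain_counterion", "salt_cation", "salt_anion"),
    count = c(params$Nm, params$Nm, params$n_salt, params$n_salt * params$Z),
    charge = c(-1L, 1L, params$Z, -1L))
}

#' Build the threaded initial configuration
#'
#' Places the chain through the pore with the head monomer just beyond the
#' pore exit on the trans side and the first five monomers spanning the wall
#' slab, the remaining chain laid into the cis region; scatters the chain
#' counterions and salt ions uniformly (rejection-sampled against overlap
#' and the wall solid); draws Maxwell-Boltzmann velocities; and optionally
#' relaxes the system under the head constraint (field off) before the run.
#'
#' @param params a [sim_params()] object.
#' @param relax_time equilibration time in tu under the head constraint
#'   (0 = geometric placement only).
#' @param max_tries rejection-sampling retries per ion before a packing
#'   error is raised.
#' @return A [particle_system()].
#' @export
build_initial_state <- function(params, relax_time = 0, max_tries = 2000L) {
  stopifnot(inherits(params, "sim_params"))
  sc <- species_counts(params)
  n_ions <- sum(sc$count[-1])
  box <- params$box
  d2 <- params$wall_thickness / 2
  xw <- wall_center(params)
  axis <- pore_axis(params)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(params$seed)

  chain <- chain_path(params)
  pos <- matrix(NA_real_, n_ions, 3)
  placed <- chain
  margin <- 1.7                         # clearance from the wall solid
  for (i in seq_len(n_ions)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- stats::runif(3) * box
      if (wall_gap(cand, params) < margin) next
      d <- sweep(placed, 2, cand)
      d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
      if (min(sqrt(rowSums(d^2))) < 1.0) next
      ok <- TRUE; break
    }
    if (!ok) stop("packing error: could not insert ion ", i,
                  " after ", max_tries, " tries", call. = FALSE)
    pos[i, ] <- cand
    placed <- rbind(placed, cand)
  }

  positions <- rbind(chain, pos)
  n <- nrow(positions)
  charges <- rep(sc$charge, sc$count)
  species <- rep(sc$species, sc$count)
  velocities <- matrix(stats::rnorm(3 * n), n, 3)   # kBT = m = 1
  bonds <- cbind(seq_len(params$Nm - 1L), 2:params$Nm)
  sys <- particle_system(positions, velocities, charges, species, bonds,
                         box, head_index = 1L)
  if (relax_time > 0)
    sys <- equilibrate(sys, params, time = relax_time, freeze_head = TRUE)
  sys
}

# deterministic threaded chain path: head at the pore exit, monomers 1-5
# across the slab on the pore axis, the rest serpentined into the cis region
chain_path <- function(params) {
  box <- params$box
  d2 <- params$wall_thickness / 2
  xw <- wall_center(params)
  axis <- pore_axis(params)
  b <- params$b0
  margin <- 1.7
  x1 <- xw + d2 + 0.4                  # head slightly beyond the exit plane
  pos <- matrix(NA_real_, params$Nm, 3)
  x <- x1; y <- axis[1]; z <- axis[2]
  dirx <- -1
  xmin <- margin; xmax <- xw - d2 - margin
  for (i in seq_len(params$Nm)) {
    pos[i, ] <- c(x, y, z)
    nx <- x + dirx * b
    on_axis <- (y == axis[1] && z == axis[2])
    if (on_axis && nx > xmin) {
      x <- nx                           # straight through the pore shadow
    } else if (!on_axis && nx >= xmin && nx <= xmax) {
      x <- nx
    } else {
      y <- y + b                        # turn: step one row in y
      if (y > box[2] - margin) { y <- axis[1] + b; z <- z + b }
      if (z > box[3] - margin)
        stop("packing error: cis region too small for this chain",
             call. = FALSE)
      dirx <- -dirx
      x <- min(max(x, xmin), xmax)
    }
  }
  pos
}

# region bookkeeping: a monomer is cis if x < xw - d/2, trans if
# x > xw + d/2, else in-pore (minimum-image relative to the wall)
region_counts <- function(system, params) {
  mono <- system$species == "monomer"
  dx <- system$positions[mono, 1] - wall_center(params)
  dx <- dx - params$box[1] * round(dx / params$box[1])
  d2 <- params$wall_thickness / 2
  c(cis = sum(dx < -d2), pore = sum(abs(dx) <= d2), trans = sum(dx > d2))
}
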