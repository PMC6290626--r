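#' Weeks-Chandler-Andersen excluded-volume potential
#'
#' The purely repulsive truncated-and-shifted Lennard-Jones potential,
#' \deqn{U(r) = 4\varepsilon\left[(\sigma/r)^{12} - (\sigma/r)^6\right] +
#'       \varepsilon \quad (r \le 2^{1/6}\sigma),\qquad 0 \ \mathrm{otherwise},}
#' continuous (with continuous force) at the cutoff and monotonically
#' decreasing below it.
#'
#' @param r distance(s) in sigma, strictly positive.
#' @param sigma_ij contact distance in sigma.
#' @param eps_ij interaction strength in kBT.
#' @return Energy in kBT (vectorized over `r`).
#' @export
#' @examples
#' wca_energy(1.0, 1.0, 1.2)          # = eps at r = sigma
#' wca_energy(2^(1/6), 1.0, 1.2)      # 0 at the cutoff
wca_energy <- function(r, sigma_ij = 1.0, eps_ij = 1.0) {
  if (any(r <= 0))
    stop("overlapping particles: WCA energy diverges at r = 0", call. = FALSE)
  rc <- 2^(1 / 6) * sigma_ij
  sr6 <- (sigma_ij / r)^6
  u <- 4 * eps_ij * (sr6^2 - sr6) + eps_ij
  ifelse(r > rc, 0, u)
}

#' @rdname wca_energy
#' @return `wca_force()`: the radial force magnitude `-dU/dr` (positive =
#'   repulsive), zero beyond the cutoff.
#' @export
wca_force <- function(r, sigma_ij = 1.0, eps_ij = 1.0) {
  if (any(r <= 0))
    stop("overlapping particles: WCA force diverges at r = 0", call. = FALSE)
  rc <- 2^(1 / 6) * sigma_ij
  sr6 <- (sigma_ij / r)^6
  f <- 24 * eps_ij * (2 * sr6^2 - sr6) / r
  ifelse(r > rc, 0, f)
}

#' Bare Coulomb pair energy
#'
#' \eqn{U(r) = k_BT\, \lambda_B Z_i Z_j / r}, where the Bjerrum length
#' \eqn{\lambda_B} is the distance at which two unit charges interact with
#' thermal energy.
#'
#' @param r distance(s) in sigma, strictly positive.
#' @param Zi,Zj signed valences.
#' @param lambda_B Bjerrum length in sigma.
#' @return Energy in kBT (vectorized over `r`).
#' @export
#' @examples
#' coulomb_energy(3, -1, -1, 3)   # +1 kBT
coulomb_energy <- function(r, Zi, Zj, lambda_B = 3.0) {
  if (any(r <= 0))
    stop("overlapping charges: Coulomb energy diverges at r = 0",
         call. = FALSE)
  lambda_B * Zi * Zj / r
}

#' Harmonic bond energy
#'
#' \eqn{U(b) = (k/2)(b - b_0)^2}.
#'
#' @param b bond length(s) in sigma (>= 0).
#' @param k spring constant in kBT/sigma^2.
#' @param b0 equilibrium bond length in sigma.
#' @return Energy in kBT (vectorized over `b`).
#' @export
bond_energy <- function(b, k = 600.0, b0 = 1.0) {
  stopifnot(all(b >= 0))
  0.5 * k * (b - b0)^2
}

#' Driving force from the in-pore electric field
#'
#' A uniform field \eqn{\vec{E} = -E\hat{x}} acts on every charged particle
#' inside the pore region — the cylinder of radius `pore_radius` about the
#' pore axis spanning the wall slab. A monomer of charge -e therefore feels
#' `+eE` along +x (toward the trans side); a +Z cation inside the pore is
#' pushed the other way.
#'
#' @param position length-3 position (sigma) or an n x 3 matrix.
#' @param charge signed charge(s) in e.
#' @param params a [sim_params()] object.
#' @return Force vector(s) in kBT/sigma, same shape as `position`.
#' @export
pore_field_force <- function(position, charge, params) {
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 3)
  dxw <- pos[, 1] - wall_center(params)
  dxw <- dxw - params$box[1] * round(dxw / params$box[1])
  dy <- pos[, 2] - pore_axis(params)[1]
  dy <- dy - params$box[2] * round(dy / params$box[2])
  dz <- pos[, 3] - pore_axis(params)[2]
  dz <- dz - params$box[3] * round(dz / params$box[3])
  inside <- abs(dxw) <= params$wall_thickness / 2 &
    sqrt(dy^2 + dz^2) <= params$pore_radius
  fx <- ifelse(inside, charge * (-params$E), 0)
  out <- cbind(fx, 0, 0)
  dimnames(out) <- NULL
  if (is.matrix(position)) out else drop(out)
}

# distance from a point to the wall solid (slab of thickness d minus the
# pore cylinder), with minimum-image wrapping; negative when inside the solid
wall_gap <- function(position, params) {
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 3)
  d2 <- params$wall_thickness / 2
  rp <- params$pore_radius
  dxw <- pos[, 1] - wall_center(params)
  dxw <- abs(dxw - params$box[1] * round(dxw / params$box[1]))
  dy <- pos[, 2] - pore_axis(params)[1]
  dy <- dy - params$box[2] * round(dy / params$box[2])
  dz <- pos[, 3] - pore_axis(params)[2]
  dz <- dz - params$box[3] * round(dz / params$box[3])
  r <- sqrt(dy^2 + dz^2)
  gap <- numeric(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    ax <- max(0, dxw[i] - d2)      # axial gap to the slab
    if (r[i] >= rp) {
      gap[i] <- if (dxw[i] > d2) ax else -min(r[i] - rp, d2 - dxw[i])
    } else {
      a <- rp - r[i]               # radial gap to the channel wall
      gap[i] <- if (dxw[i] > d2) sqrt(a^2 + ax^2) else a
    }
  }
  gap
}

# analytic-wall energy of mobile particles: WCA (sigma_pw, eps_pw) on the
# distance to the wall solid
wall_energy <- function(position, params) {
  g <- wall_gap(position, params)
  if (any(g <= 0)) stop("particle inside the wall solid", call. = FALSE)
  sum(wca_energy(g, params$sigma_pw, params$eps_pw))
}

# one-sided barrier at the pore exit acting on the head monomer only:
# WCA (barrier_sigma, eps_pw) on h = x_head - x_exit
barrier_energy <- function(x_head, params) {
  h <- x_head - pore_exit(params)
  if (h <= 0) stop("head monomer behind the exit barrier", call. = FALSE)
  wca_energy(h, params$barrier_sigma, params$eps_pw)
}

# damped shifted-force Coulomb pair energy (Fennell-Gezelter form), zero
# energy and force at the cutoff
dsf_energy <- function(r, qq, lambda_B, alpha, rc) {
  ec <- erfc_(alpha * rc) / rc
  fc <- ec / rc + 2 * alpha / sqrt(pi) * exp(-alpha^2 * rc^2) / rc
  u <- lambda_B * qq * (erfc_(alpha * r) / r - ec + fc * (r - rc))
  ifelse(r > rc, 0, u)
}

erfc_ <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Classical Ewald summation of the electrostatic energy
#'
#' Reference periodic Coulomb energy
#' \eqn{U = k_BT \lambda_B \sum_{i<j} Z_i Z_j / r_{ij}} (periodically
#' summed), evaluated by classical Ewald summation: a real-space erfc part,
#' a reciprocal-space part and the self term. Used as the reference solver
#' against which the damped shifted-force approximation is checked on small
#' ion clusters; it is far too slow for the dynamics itself.
#'
#' @param positions n x 3 matrix (sigma).
#' @param charges signed valences.
#' @param box length-3 box (sigma).
#' @param lambda_B Bjerrum length (sigma).
#' @param alpha Ewald splitting parameter (1/sigma).
#' @param kmax reciprocal-space cutoff (integer, in units of 2 pi / L).
#' @return Energy in kBT.
#' @export
ewald_energy <- function(positions, charges, box, lambda_B = 3.0,
                         alpha = NULL, kmax = 8L) {
  n <- nrow(positions)
  if (is.null(alpha)) alpha <- 5 / min(box)
  # real-space part (minimum image; alpha must make this converged)
  u_real <- 0
  for (i in seq_len(n - 1)) {
    d <- sweep(positions[(i + 1):n, , drop = FALSE], 2, positions[i, ])
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    r <- sqrt(rowSums(d^2))
    u_real <- u_real + sum(charges[i] * charges[(i + 1):n] *
                             erfc_(alpha * r) / r)
  }
  # reciprocal-space part
  V <- prod(box)
  ks <- expand.grid(kx = -kmax:kmax, ky = -kmax:kmax, kz = -kmax:kmax)
  ks <- ks[rowSums(ks^2) > 0, ]
  kvec <- t(2 * pi * t(ks) / box)
  k2 <- rowSums(kvec^2)
  phase <- kvec %*% t(positions)
  Sk2 <- (cos(phase) %*% charges)^2 + (sin(phase) %*% charges)^2
  u_rec <- 2 * pi / V * sum(exp(-k2 / (4 * alpha^2)) / k2 * Sk2)
  u_self <- -alpha / sqrt(pi) * sum(charges^2)
  lambda_B * (u_real + u_rec + u_self)
}

#' Total potential energy of a particle system
#'
#' Sum of the pairwise WCA excluded volume (mobile-mobile parameters), the
#' electrostatic energy under the selected solver (`"dsf"` damped
#' shifted-force, or `"ewald"` reference), the harmonic bond terms, the
#' analytic-wall WCA (mobile-wall parameters) and the head barrier.
#' Deterministic given the state; the in-pore driving field is a
#' non-conservative external force and is not part of the potential energy.
#'
#' @param system a [particle_system()].
#' @param params a [sim_params()] object.
#' @param wall include the wall and head-barrier terms (default `TRUE`)?
#' @return Energy in kBT.
#' @export
total_energy <- function(system, params, wall = TRUE) {
  pos <- system$positions
  q <- system$charges
  n <- nrow(pos)
  box <- params$box
  u_wca <- 0; u_el <- 0
  rc <- params$coulomb_cutoff
  bonded <- rep(FALSE, n)    # bonded[j] marks (i, j) excluded for current i
  for (i in seq_len(max(n - 1, 0))) {
    js <- (i + 1):n
    d <- sweep(pos[js, , drop = FALSE], 2, pos[i, ])
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    r <- sqrt(rowSums(d^2))
    if (nrow(system$bonds) > 0) {
      excl <- system$bonds[system$bonds[, 1] == i, 2]
      keep <- !(js %in% excl)            # 1-2 exclusion along the chain
      r <- r[keep]; js <- js[keep]
    }
    if (length(r) == 0) next
    if (any(r <= 0)) stop("overlapping particles", call. = FALSE)
    u_wca <- u_wca + sum(wca_energy(r, params$sigma_pp, params$eps_pp))
    if (params$lambda_B > 0 && params$electrostatics_mode == "dsf") {
      qq <- q[i] * q[js]
      u_el <- u_el + sum(dsf_energy(r, qq, params$lambda_B,
                                    params$dsf_alpha, rc))
    }
  }
  if (params$lambda_B > 0 && params$electrostatics_mode == "ewald")
    u_el <- ewald_energy(pos, q, box, params$lambda_B)
  u_bond <- 0
  if (!is.null(system$bonds) && nrow(system$bonds) > 0) {
    d <- pos[system$bonds[, 2], , drop = FALSE] -
      pos[system$bonds[, 1], , drop = FALSE]
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    u_bond <- sum(bond_energy(sqrt(rowSums(d^2)), params$k_bond, params$b0))
  }
  u_wall <- 0
  if (wall) {
    u_wall <- wall_energy(pos, params) +
      barrier_energy(pos[system$head_index, 1], params)
  }
  u_wca + u_el + u_bond + u_wall
}
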