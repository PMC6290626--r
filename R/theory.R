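#' Theory parameter set for the four-regime translocation scaling picture
#'
#' Bundles the exponents that drive every closed-form prediction of the
#' tension-propagation scaling theory of driven translocation:
#' \describe{
#'   \item{nu_s}{size exponent of a wall-tethered chain, \eqn{R_m \sim m^{\nu_s}}.}
#'   \item{nu_b}{size exponent of a chain blob in free solution,
#'     \eqn{\xi \sim g^{\nu_b}}.}
#'   \item{gamma_p}{subdiffusion exponent of the translocation coordinate in
#'     the tension-propagation stage, \eqn{\langle\Delta n^2\rangle \sim t^{\gamma_p}}.}
#'   \item{z_p}{dynamical exponent of tension propagation, \eqn{t \sim R_p^{z_p}}.}
#'   \item{z}{dynamical exponent of blob diffusion, \eqn{\tau_\xi \sim \xi^z};
#'     in Rouse dynamics \eqn{z - 2 = 1/\nu_b}.}
#'   \item{p_z}{exponent of the velocity-extension-force relation
#'     \eqn{v_p R_p \sim f^{p_z}}; equals \eqn{z - 2}.}
#'   \item{q}{density-velocity exponent, \eqn{\sigma_x \sim v_x^{-q}} with
#'     \eqn{q = (1-\nu_b)/(1+\nu_b)}.}
#'   \item{rho, eta}{boundary exponents of the force-regime demarcations,
#'     \eqn{f_2^* \sim N^{-\nu_s\rho}} and \eqn{f_3^* \sim N^{-\nu_s\eta}}.}
#' }
#'
#' Missing members may be supplied as `NA` and later completed with
#' [derived_relations()].
#'
#' @param nu_s,nu_b,gamma_p,z_p,z,p_z,q,rho,eta numeric scalars (or `NA`).
#' @return An object of class `theory_params` (a named list).
#' @seealso [derived_relations()], [regime_exponents()], [regime_boundaries()]
#' @export
#' @examples
#' theory_params(nu_s = 0.35, gamma_p = 0.78, z_p = 5.06, q = 0.86)
theory_params <- function(nu_s = NA_real_, nu_b = NA_real_,
                          gamma_p = NA_real_, z_p = NA_real_,
                          z = NA_real_, p_z = NA_real_, q = NA_real_,
                          rho = NA_real_, eta = NA_real_) {
  tp <- list(nu_s = nu_s, nu_b = nu_b, gamma_p = gamma_p, z_p = z_p,
             z = z, p_z = p_z, q = q, rho = rho, eta = eta)
  tp <- lapply(tp, as.numeric)
  for (nm in names(tp)) {
    v <- tp[[nm]]
    if (length(v) != 1L) stop("`", nm, "` must be a scalar", call. = FALSE)
    if (!is.na(v) && v <= 0 && nm != "rho" && nm != "eta")
      stop("`", nm, "` must be positive, got ", v, call. = FALSE)
  }
  structure(tp, class = "theory_params")
}

#' @export
print.theory_params <- function(x, ...) {
  cat("<theory_params>\n")
  vals <- vapply(unclass(x), function(v) format(v, digits = 4), character(1))
  cat(paste0("  ", format(names(x), width = 8), " = ", vals, collapse = "\n"), "\n")
  invisible(x)
}

# half-up rounding to two decimals, the convention used by the published
# exponent table (base round() is round-half-even)
round2 <- function(x) floor(x * 100 + 0.5) / 100

need <- function(tp, syms, what) {
  miss <- syms[vapply(syms, function(s) is.na(tp[[s]]), logical(1))]
  if (length(miss))
    stop("missing theory parameter(s) for ", what, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
}

#' Scaling exponents (alpha, delta) of the mean translocation time per regime
#'
#' The mean translocation time obeys
#' \eqn{\langle\tau\rangle \sim N^{\alpha} f^{-\delta}} with regime-dependent
#' exponents:
#' \itemize{
#'   \item UB (unbiased): \eqn{\alpha = 2 + \nu_s z_p(1-\gamma_p)}, \eqn{\delta = 0}
#'   \item WD (weakly driven): \eqn{\alpha = 1 + \nu_s z_p(1-\gamma_p)}, \eqn{\delta = 1}
#'   \item SD(T) (strongly driven, trumpet): \eqn{\alpha = 1 + \nu_s(1-q)},
#'     \eqn{\delta = p_z(1-q)}
#'   \item SD(I) (strongly driven, isoflux): \eqn{\alpha = 1 + \nu_s}, \eqn{\delta = 1}
#' }
#'
#' @param params a [theory_params()] object.
#' @param regime character vector among `"UB"`, `"WD"`, `"SD(T)"`, `"SD(I)"`;
#'   defaults to all four.
#' @return A tibble with columns `regime`, `alpha`, `delta`.
#' @export
#' @examples
#' tp <- theory_params(nu_s = 0.4, z_p = 1.4 / (0.4 * (1 - 0.5)), gamma_p = 0.5,
#'                     q = 0.25, p_z = 1.67 / 0.75)
#' regime_exponents(tp)
regime_exponents <- function(params,
                             regime = c("UB", "WD", "SD(T)", "SD(I)")) {
  stopifnot(inherits(params, "theory_params"))
  regime <- match.arg(regime, several.ok = TRUE)
  one <- function(r) {
    switch(r,
      "UB" = {
        need(params, c("nu_s", "z_p", "gamma_p"), "UB")
        c(2 + params$nu_s * params$z_p * (1 - params$gamma_p), 0)
      },
      "WD" = {
        need(params, c("nu_s", "z_p", "gamma_p"), "WD")
        c(1 + params$nu_s * params$z_p * (1 - params$gamma_p), 1)
      },
      "SD(T)" = {
        need(params, c("nu_s", "q", "p_z"), "SD(T)")
        c(1 + params$nu_s * (1 - params$q), params$p_z * (1 - params$q))
      },
      "SD(I)" = {
        need(params, "nu_s", "SD(I)")
        c(1 + params$nu_s, 1)
      })
  }
  m <- vapply(regime, one, numeric(2))
  tibble::tibble(regime = regime, alpha = unname(m[1, ]),
                 delta = unname(m[2, ]))
}

#' Force-regime boundary exponents
#'
#' At fixed chain length the four force regimes are demarcated by three
#' crossover forces, \eqn{f_1^* \sim N^{-1}}, \eqn{f_2^* \sim N^{-\nu_s\rho}}
#' and \eqn{f_3^* \sim N^{-\nu_s\eta}}; at fixed force the corresponding
#' crossover chain lengths are \eqn{N_1^* \sim f^{-1}},
#' \eqn{N_2^* \sim f^{-1/(\nu_s\rho)}} and \eqn{N_3^* \sim f^{-1/(\nu_s\eta)}}.
#' The N-boundary exponents are exact reciprocals of the f-boundary exponents.
#'
#' @inheritParams regime_exponents
#' @return A tibble with columns `boundary` (`"f1*"`, `"f2*"`, `"f3*"`),
#'   `f_exponent` (exponent of N in the crossover force) and `N_exponent`
#'   (exponent of f in the crossover length).
#' @export
regime_boundaries <- function(params) {
  stopifnot(inherits(params, "theory_params"))
  need(params, c("nu_s", "rho", "eta"), "regime boundaries")
  fe <- c(-1, -params$nu_s * params$rho, -params$nu_s * params$eta)
  if (any(fe == 0)) stop("singular boundary exponent (rho or eta is zero)",
                         call. = FALSE)
  tibble::tibble(boundary = c("f1*", "f2*", "f3*"),
                 f_exponent = fe, N_exponent = 1 / fe)
}

#' Slopes of the regime-demarcation lines
#'
#' In the log-log plot of \eqn{\tau} against f the three demarcation lines
#' fall off as \eqn{\tau_{Fi} \sim f^{-X_i}}; against N they rise as
#' \eqn{\tau_{Ni} \sim N^{Y_i}}, with
#' \eqn{X_1 = 2 + \nu_s z_p(1-\gamma_p)},
#' \eqn{X_2 = (\nu_s^{-1} + 1 - q)/\rho + p_z(1-q)},
#' \eqn{X_3 = (\nu_s^{-1} + 1 - q)/\eta + p_z(1-q)},
#' \eqn{Y_1 = 2 + \nu_s z_p(1-\gamma_p)},
#' \eqn{Y_2 = 1 + \nu_s z_p(1-\gamma_p) + \nu_s\rho},
#' \eqn{Y_3 = 1 + \nu_s + \nu_s\eta}.
#' A well-ordered regime diagram requires \eqn{X_1 < X_2 < X_3} and
#' \eqn{Y_1 > Y_2 > Y_3}, which holds whenever the consistency inequalities
#' of [check_inequalities()] do.
#'
#' @inheritParams regime_exponents
#' @return A tibble with columns `line` (`"1"`,`"2"`,`"3"`), `X`, `Y`.
#' @export
boundary_slopes <- function(params) {
  stopifnot(inherits(params, "theory_params"))
  need(params, c("nu_s", "z_p", "gamma_p", "q", "p_z", "rho", "eta"),
       "boundary slopes")
  a_ub <- 2 + params$nu_s * params$z_p * (1 - params$gamma_p)
  core <- 1 / params$nu_s + 1 - params$q
  pz1q <- params$p_z * (1 - params$q)
  tibble::tibble(
    line = c("1", "2", "3"),
    X = c(a_ub, core / params$rho + pz1q, core / params$eta + pz1q),
    Y = c(a_ub,
          1 + params$nu_s * params$z_p * (1 - params$gamma_p) +
            params$nu_s * params$rho,
          1 + params$nu_s + params$nu_s * params$eta))
}

#' Full regime prediction (exponents, boundaries, slopes)
#'
#' Convenience wrapper returning everything [regime_exponents()],
#' [regime_boundaries()] and [boundary_slopes()] compute, as one object.
#'
#' @inheritParams regime_exponents
#' @return A list of class `regime_prediction` with elements `exponents`,
#'   `boundaries`, `slopes` (tibbles).
#' @export
regime_prediction <- function(params) {
  structure(list(exponents = regime_exponents(params),
                 boundaries = regime_boundaries(params),
                 slopes = boundary_slopes(params),
                 params = params),
            class = "regime_prediction")
}

#' @export
print.regime_prediction <- function(x, ...) {
  cat("<regime_prediction>\n$exponents\n"); print(x$exponents)
  cat("$boundaries\n"); print(x$boundaries)
  cat("$slopes\n"); print(x$slopes)
  invisible(x)
}

#' Complete a theory parameter set via the inter-exponent relations
#'
#' Closes the exponent system using the relations
#' \eqn{\gamma_p = (1+\nu_s)/(z_p\nu_s)},
#' \eqn{q = (1-\nu_b)/(1+\nu_b)},
#' \eqn{p_z = z - 2} and (Rouse dynamics) \eqn{z - 2 = 1/\nu_b},
#' plus the boundary-exponent definitions
#' \eqn{\rho = (z_p(1-\gamma_p) - 1 + q)/(p_z(1-q) - 1)} and
#' \eqn{\eta = q/(p_z(1-q) - 1)}.
#' Relations are applied repeatedly until no further member can be filled.
#' Members supplied by the caller are never overwritten; if the inputs
#' over-determine a relation, the residual is reported in the
#' `"residuals"` attribute rather than silently reconciled.
#'
#' @inheritParams regime_exponents
#' @param tol tolerance above which an over-determined relation is flagged
#'   as inconsistent (an error listing all residuals).
#' @param rouse apply the Rouse-dynamics closure `z = 2 + 1/nu_b`? Set
#'   `FALSE` when `p_z` (or `z`) is supplied independently of the blob
#'   exponent — e.g. for parameter sets where the measured `q` is known not
#'   to satisfy the quasi-equilibrium blob relation.
#' @return The completed `theory_params` object, with attribute
#'   `"residuals"` (named numeric, possibly empty).
#' @export
#' @examples
#' derived_relations(theory_params(nu_b = 0.68))$q        # 0.19...
#' derived_relations(theory_params(nu_s = 0.35, gamma_p = 0.78))$z_p  # 4.95
derived_relations <- function(params, tol = 1e-6, rouse = TRUE) {
  stopifnot(inherits(params, "theory_params"))
  tp <- unclass(params)
  given <- names(tp)[!vapply(tp, is.na, logical(1))]
  res <- numeric(0)

  # each relation: if all inputs known, compute the target; if the target is
  # also known, record the residual instead of overwriting
  set <- function(tp, name, value, label) {
    if (is.na(tp[[name]])) {
      tp[[name]] <- value
    } else {
      res[[label]] <<- tp[[name]] - value
    }
    tp
  }
  for (pass in 1:5) {
    before <- tp
    if (!is.na(tp$nu_b))
      tp <- set(tp, "q", (1 - tp$nu_b) / (1 + tp$nu_b), "q=(1-nu_b)/(1+nu_b)")
    if (!is.na(tp$q) && tp$q < 1 && is.na(tp$nu_b))
      tp$nu_b <- (1 - tp$q) / (1 + tp$q)
    if (rouse && !is.na(tp$nu_b))
      tp <- set(tp, "z", 2 + 1 / tp$nu_b, "z=2+1/nu_b")
    if (!is.na(tp$z))
      tp <- set(tp, "p_z", tp$z - 2, "p_z=z-2")
    if (!is.na(tp$p_z) && is.na(tp$z)) tp$z <- tp$p_z + 2
    if (!is.na(tp$nu_s) && !is.na(tp$z_p))
      tp <- set(tp, "gamma_p", (1 + tp$nu_s) / (tp$z_p * tp$nu_s),
                "gamma_p=(1+nu_s)/(z_p nu_s)")
    if (!is.na(tp$nu_s) && !is.na(tp$gamma_p) && is.na(tp$z_p))
      tp$z_p <- (1 + tp$nu_s) / (tp$gamma_p * tp$nu_s)
    if (!is.na(tp$p_z) && !is.na(tp$q) && !is.na(tp$z_p) &&
        !is.na(tp$gamma_p)) {
      den <- tp$p_z * (1 - tp$q) - 1
      if (abs(den) < 1e-12)
        stop("singular parameter set: p_z*(1-q) = 1", call. = FALSE)
      tp <- set(tp, "rho", (tp$z_p * (1 - tp$gamma_p) - 1 + tp$q) / den,
                "rho definition")
    }
    if (!is.na(tp$p_z) && !is.na(tp$q)) {
      den <- tp$p_z * (1 - tp$q) - 1
      if (abs(den) >= 1e-12)
        tp <- set(tp, "eta", tp$q / den, "eta definition")
    }
    if (identical(before, tp)) break
  }
  if (length(res) && any(abs(res) > tol))
    stop("inconsistent over-determined inputs; residuals: ",
         paste(names(res), "=", signif(res, 3), collapse = "; "),
         call. = FALSE)
  out <- structure(tp, class = "theory_params")
  attr(out, "residuals") <- res
  out
}

#' Published extracted exponents of the translocation study
#'
#' The exponents measured from the full-scale simulation study (least-squares
#' and pairwise fits on the mean-translocation-time and variance curves, and
#' static tethered-/free-chain runs) for the monovalent (Z = 1) and divalent
#' (Z = 2) salt solutions: the unbiased, trumpet and isoflux alpha values,
#' the peak trumpet delta, the static size exponents nu_s0 and nu_b0, and the
#' subdiffusion exponent gamma_p. These are the measured inputs from which
#' the derived exponent chain (nu_s, q, z_p, rho, eta) is obtained with
#' [invert_observed()].
#'
#' @param Z salt valence, 1 or 2.
#' @return A named list: `alpha_UB`, `alpha_SDT`, `alpha_SDI`, `delta_SDT`,
#'   `nu_s0`, `nu_b0`, `gamma_p`.
#' @export
#' @examples
#' observed_exponents(1)$alpha_UB  # 2.39
observed_exponents <- function(Z) {
  Z <- as.integer(Z)
  if (!Z %in% c(1L, 2L)) stop("Z must be 1 or 2", call. = FALSE)
  if (Z == 1L) {
    list(alpha_UB = 2.39, alpha_SDT = 1.05, alpha_SDI = 1.35,
         delta_SDT = 1.65, nu_s0 = 0.71, nu_b0 = 0.68, gamma_p = 0.78)
  } else {
    list(alpha_UB = 2.61, alpha_SDT = 1.06, alpha_SDI = 1.50,
         delta_SDT = 1.77, nu_s0 = 0.57, nu_b0 = 0.55, gamma_p = 0.75)
  }
}

#' Invert observed translocation exponents into the theory exponents
#'
#' Solves the regime scaling forms for the underlying exponents from the
#' measured quantities:
#' \deqn{\nu_s = \alpha_{SD(I)} - 1,\quad
#'       q = 1 - (\alpha_{SD(T)} - 1)/\nu_s,\quad
#'       z_p = (\alpha_{UB} - 2) / (\nu_s (1 - \gamma_p)),}
#' then the boundary exponents
#' \deqn{\rho = (z_p(1-\gamma_p) - 1 + q)/(\delta_{SD(T)} - 1),\quad
#'       \eta = q/(\delta_{SD(T)} - 1).}
#'
#' `nu_s`, `q` and `z_p` are carried at full precision. `rho` and `eta` are
#' computed from the two-decimal (half-up) reported values of `z_p` and `q`,
#' mirroring how the published exponent table chains its "calculated from
#' items" entries; note the `rho` formula also needs `gamma_p` even though
#' the table's note lists only the delta/q/z_p items. Set
#' `from_reported = FALSE` to propagate full precision throughout.
#'
#' @param alpha_UB,alpha_SDT,alpha_SDI measured alpha in the UB, SD(T) and
#'   SD(I) regimes.
#' @param delta_SDT measured peak delta in the SD(T) regime
#'   (\eqn{= p_z(1-q)}).
#' @param gamma_p measured subdiffusion exponent.
#' @param from_reported logical; compute `rho`/`eta` from two-decimal-rounded
#'   intermediates (default) or from full-precision ones.
#' @return A tibble with one row: `nu_s`, `q`, `z_p`, `rho`, `eta` at full
#'   precision, plus their `*_2dp` reporting-precision versions (half-up,
#'   two decimals).
#' @export
#' @examples
#' obs <- observed_exponents(1)
#' invert_observed(obs$alpha_UB, obs$alpha_SDT, obs$alpha_SDI,
#'                 obs$delta_SDT, obs$gamma_p)
invert_observed <- function(alpha_UB, alpha_SDT, alpha_SDI, delta_SDT,
                            gamma_p, from_reported = TRUE) {
  stopifnot(is.finite(alpha_UB), is.finite(alpha_SDT), is.finite(alpha_SDI),
            is.finite(delta_SDT), is.finite(gamma_p))
  if (alpha_SDI <= 1) stop("alpha_SDI must exceed 1 (nu_s > 0)", call. = FALSE)
  if (gamma_p == 1) stop("gamma_p = 1 makes z_p singular", call. = FALSE)
  if (delta_SDT == 1) stop("delta_SDT = 1 makes rho and eta singular",
                           call. = FALSE)
  nu_s <- alpha_SDI - 1
  q <- 1 - (alpha_SDT - 1) / nu_s
  z_p <- (alpha_UB - 2) / (nu_s * (1 - gamma_p))
  zp_in <- if (from_reported) round2(z_p) else z_p
  q_in <- if (from_reported) round2(q) else q
  rho <- (zp_in * (1 - gamma_p) - 1 + q_in) / (delta_SDT - 1)
  eta <- q_in / (delta_SDT - 1)
  tibble::tibble(
    nu_s = nu_s, q = q, z_p = z_p, rho = rho, eta = eta,
    nu_s_2dp = round2(nu_s), q_2dp = round2(q), z_p_2dp = round2(z_p),
    rho_2dp = round2(rho), eta_2dp = round2(eta))
}

#' Consistency inequalities of the scaling theory
#'
#' A well-defined four-regime diagram in the long-chain limit requires
#' \eqn{\nu_s z_p \gamma_p < 2}, \eqn{\nu_s\rho < 1}, \eqn{\rho > \eta},
#' \eqn{p_z(1-q) > 1} and \eqn{z_p(1-\gamma_p) > 1}.
#'
#' @inheritParams regime_exponents
#' @return A tibble with columns `inequality`, `satisfied` (logical) and
#'   `margin` (positive when satisfied; the signed distance to the bound).
#' @export
check_inequalities <- function(params) {
  stopifnot(inherits(params, "theory_params"))
  need(params, c("nu_s", "z_p", "gamma_p", "q", "p_z", "rho", "eta"),
       "consistency inequalities")
  margins <- c(
    "nu_s*z_p*gamma_p < 2" = 2 - params$nu_s * params$z_p * params$gamma_p,
    "nu_s*rho < 1"         = 1 - params$nu_s * params$rho,
    "rho > eta"            = params$rho - params$eta,
    "p_z*(1-q) > 1"        = params$p_z * (1 - params$q) - 1,
    "z_p*(1-gamma_p) > 1"  = params$z_p * (1 - params$gamma_p) - 1)
  tibble::tibble(inequality = names(margins),
                 satisfied = unname(margins > 0),
                 margin = unname(margins))
}

#' Tension-propagation exponent of a pulled free chain
#'
#' For a linear chain pulled from one end in free solution the tension front
#' advances as \eqn{m_p \sim t^{1/2}}, giving the dynamical exponent
#' \eqn{z_p = 2/\nu_{s0}}.
#'
#' @param nu_s0 static size exponent of the tethered chain (> 0).
#' @return `z_p` as a numeric scalar.
#' @export
#' @examples
#' pulled_chain_zp(0.71)  # 2.82 at reporting precision
pulled_chain_zp <- function(nu_s0) {
  stopifnot(is.numeric(nu_s0))
  if (any(nu_s0 <= 0)) stop("nu_s0 must be positive", call. = FALSE)
  2 / nu_s0
}

#' Piecewise power-law theory curve for the mean translocation time
#'
#' Builds the log-log piecewise power law of \eqn{\tau} against the driving
#' force f (at fixed N) or against N (at fixed f), with the four regime
#' exponents and prefactors fixed by continuity at each regime boundary.
#' Scaling relations carry undetermined prefactors, so the curve is defined
#' up to one global scale set by `anchor`: the unbiased-regime plateau is
#' `anchor * N^alpha_UB` (force-independent), and every other segment
#' follows by continuity. Doubling N therefore shifts the whole
#' tau-versus-f curve upward.
#'
#' @inheritParams regime_exponents
#' @param grid positive numeric vector of f values (`mode = "tau_vs_f"`) or
#'   N values (`mode = "tau_vs_N"`).
#' @param mode `"tau_vs_f"` or `"tau_vs_N"`.
#' @param N chain length at which the f-sweep is evaluated.
#' @param f driving force at which the N-sweep is evaluated.
#' @param anchor global scale of the unbiased plateau, default 1.
#' @return A tibble with columns `x`, `tau`, `regime`; class
#'   `pore_theory_curve`.
#' @export
theory_curve <- function(params, grid, mode = c("tau_vs_f", "tau_vs_N"),
                         N = 128, f = 1, anchor = 1) {
  stopifnot(inherits(params, "theory_params"))
  mode <- match.arg(mode)
  if (any(!is.finite(grid)) || any(grid <= 0))
    stop("grid must be positive and finite", call. = FALSE)
  grid <- sort(grid)
  ex <- regime_exponents(params)
  bd <- regime_boundaries(params)
  if (mode == "tau_vs_f") {
    cuts <- N^bd$f_exponent            # f1*, f2*, f3* at this N
    slopes <- -ex$delta                # d log tau / d log f per regime
  } else {
    cuts <- f^bd$N_exponent            # N1*, N2*, N3* at this f
    slopes <- ex$alpha
  }
  if (is.unsorted(cuts))
    stop("regime boundaries are not ordered for these parameters",
         call. = FALSE)
  if (any(!is.finite(cuts)))
    stop("grid crosses a singular boundary", call. = FALSE)
  regime_of <- findInterval(grid, cuts) + 1L   # 1..4 = UB, WD, SD(T), SD(I)
  # continuity anchoring: in the UB regime tau = anchor * N^alpha_UB (no
  # force dependence); the other segments follow by continuity at each
  # boundary, so log tau is piecewise linear in log x with breaks at cuts
  ref <- min(grid[1], cuts[1]) / 2             # a point inside the UB regime
  base <- log(anchor) +
    if (mode == "tau_vs_f") ex$alpha[1] * log(N) else ex$alpha[1] * log(ref)
  logtau_at <- function(x) {
    lx <- log(x); lref <- log(ref)
    brk <- log(cuts)
    pts <- sort(c(lref, lx, brk[brk > lref & brk < lx]))
    val <- 0; lo <- lref
    for (p in pts[pts > lref]) {
      s <- findInterval(exp((lo + p) / 2), cuts) + 1L
      val <- val + slopes[s] * (p - lo)
      lo <- p
    }
    val
  }
  logtau <- vapply(grid, logtau_at, numeric(1)) + base
  out <- tibble::tibble(x = grid, tau = exp(logtau),
                        regime = ex$regime[regime_of])
  attr(out, "mode") <- mode
  attr(out, "boundaries") <- cuts
  class(out) <- c("pore_theory_curve", class(out))
  out
}

#' Numerically integrate the tension-propagation equation
#'
#' Integrates the reduced propagation law for the tension-front position
#' \eqn{R_p(t)} in the strongly driven trumpet regime,
#' \deqn{R_p^{1/\nu_s - q + 1} - R_p^2 f^{-p_z q} \sim t f^{p_z(1-q)},}
#' in differential form
#' \deqn{\left[(1/\nu_s - q + 1) R_p^{1/\nu_s - q} - 2 R_p f^{-p_z q}\right]
#'       \frac{dR_p}{dt} = f^{p_z(1-q)},}
#' from \eqn{R_p = R_0} until \eqn{R_p = N^{\nu_s}} (the tension front reaches
#' the chain end), returning the propagation time \eqn{\tau_p}. In the
#' isoflux variant the law is \eqn{R_p^{1/\nu_s + 1} - R_p^2 \sim f t}.
#' In the large-f, large-N limit the fitted log-log slopes of \eqn{\tau_p}
#' approach \eqn{1 + \nu_s(1-q)} in N and \eqn{-p_z(1-q)} in f (trumpet), or
#' \eqn{1 + \nu_s} and \eqn{-1} (isoflux).
#'
#' @inheritParams regime_exponents
#' @param f driving force (> 0); may be a vector.
#' @param N chain length; may be a vector.
#' @param variant `"trumpet"` or `"isoflux"`.
#' @param R0 initial front position (default 1, one monomer).
#' @param drop_subleading if `TRUE`, drop the subleading \eqn{R_p^2} term
#'   (used to audit its size).
#' @return A tibble with columns `N`, `f`, `tau_p`.
#' @export
solve_tension_ode <- function(params, f, N,
                              variant = c("trumpet", "isoflux"),
                              R0 = 1, drop_subleading = FALSE) {
  stopifnot(inherits(params, "theory_params"))
  variant <- match.arg(variant)
  if (variant == "trumpet") need(params, c("nu_s", "q", "p_z"), "tension ODE")
  else need(params, "nu_s", "isoflux ODE")
  if (any(f <= 0)) stop("f must be positive", call. = FALSE)
  grid <- tidyr::expand_grid(N = as.numeric(N), f = as.numeric(f))
  nu_s <- params$nu_s
  one <- function(N1, f1) {
    Rend <- N1^nu_s
    if (Rend <= R0) return(0)
    if (variant == "trumpet") {
      a <- 1 / nu_s - params$q + 1
      cf <- if (drop_subleading) 0 else f1^(-params$p_z * params$q)
      rhs <- f1^(params$p_z * (1 - params$q))
    } else {
      a <- 1 / nu_s + 1
      cf <- if (drop_subleading) 0 else 1
      rhs <- f1
    }
    deriv <- function(t, y, p) {
      g <- a * y[1]^(a - 1) - 2 * cf * y[1]
      if (g <= 0) stop("non-convergence: propagation law not monotone here",
                       call. = FALSE)
      list(rhs / g)
    }
    root <- function(t, y, p) y[1] - Rend
    # crude upper bound on tau_p from the leading term, with headroom
    tmax <- 10 * Rend^a / rhs + 1e3 / rhs
    sol <- deSolve::lsodar(c(R = R0), times = c(0, tmax), func = deriv,
                           rootfunc = root, rtol = 1e-10, atol = 1e-12)
    troot <- attr(sol, "troot")
    if (is.null(troot) || length(troot) == 0)
      stop("non-convergence: tension front never reached the chain end",
           call. = FALSE)
    troot[1]
  }
  grid$tau_p <- mapply(one, grid$N, grid$f)
  grid
}
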