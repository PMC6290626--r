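#' Mean translocation time of a batch
#'
#' Arithmetic mean of tau over completed runs only; failed runs
#' (`max_time_reached`) are counted and reported, never silently dropped
#' into the average.
#'
#' @param events a batch tibble (as returned by [run_batch()] or
#'   [generate_synthetic_trajectories()]) with columns `tau` and `status`.
#' @return A one-row tibble: `mean_tau`, `stderr` (`NA` for a single run),
#'   `n_completed`, `n_failed`.
#' @export
mean_tau <- function(events) {
  stopifnot(all(c("tau", "status") %in% names(events)))
  done <- events$status == "completed"
  if (!any(done)) stop("no completed translocation events", call. = FALSE)
  taus <- events$tau[done]
  tibble::tibble(
    mean_tau = mean(taus),
    stderr = if (length(taus) > 1) stats::sd(taus) / sqrt(length(taus))
             else NA_real_,
    n_completed = sum(done),
    n_failed = sum(!done))
}

#' Scaling exponent from one pair of adjacent data points
#'
#' The local log-log slope between two points of a scaling curve,
#' `sign * log(y2/y1) / log(x2/x1)`, attached to the geometric mean
#' `sqrt(x1*x2)` of the pair. With `sign = "-"` on (E, tau) pairs this is the
#' force exponent delta; with `sign = "+"` on (N, tau) pairs it is alpha.
#'
#' @param x_pair,y_pair length-2 positive numeric vectors.
#' @param sign `"+"` or `"-"`.
#' @param kind label carried into the output (e.g. `"alpha"`, `"delta"`).
#' @return A one-row tibble: `kind`, `value`, `abscissa`.
#' @export
#' @examples
#' pairwise_exponent(c(1, 2), c(10, 5), sign = "-", kind = "delta")
pairwise_exponent <- function(x_pair, y_pair, sign = c("+", "-"),
                              kind = NA_character_) {
  sign <- match.arg(sign)
  stopifnot(length(x_pair) == 2, length(y_pair) == 2)
  if (any(x_pair <= 0) || any(y_pair <= 0))
    stop("pairwise_exponent needs strictly positive inputs", call. = FALSE)
  if (x_pair[1] == x_pair[2])
    stop("x values of the pair must differ", call. = FALSE)
  s <- if (sign == "+") 1 else -1
  tibble::tibble(
    kind = kind,
    value = s * log(y_pair[2] / y_pair[1]) / log(x_pair[2] / x_pair[1]),
    abscissa = sqrt(x_pair[1] * x_pair[2]))
}

#' Exponent profile from adjacent pairs along a scaling curve
#'
#' Applies [pairwise_exponent()] to every adjacent pair of a sorted (x, y)
#' series, the construction used to map alpha(E, N) and delta(E, N) across a
#' simulation grid; each estimate is reported at the geometric mean of its
#' pair.
#'
#' @param data a data frame.
#' @param x,y column names (strings) of the abscissa and ordinate.
#' @inheritParams pairwise_exponent
#' @return A tibble of pairwise estimates, one row per adjacent pair.
#' @export
exponent_profile <- function(data, x, y, sign = c("+", "-"),
                             kind = NA_character_) {
  sign <- match.arg(sign)
  data <- dplyr::arrange(data, .data[[x]])
  xv <- data[[x]]; yv <- data[[y]]
  if (length(xv) < 2) stop("need at least two points", call. = FALSE)
  purrr::map_dfr(seq_len(length(xv) - 1), function(i)
    pairwise_exponent(xv[i:(i + 1)], yv[i:(i + 1)], sign, kind))
}

#' Scaling exponent by least squares on log-log axes
#'
#' Ordinary least-squares slope of log(y) on log(x); the estimator used for
#' asymptotic exponents fitted over several chain lengths.
#'
#' @param x,y positive numeric vectors (same length, >= 2 points).
#' @param kind label carried into the output.
#' @return A one-row tibble: `kind`, `value`, `stderr` (`NA` with two
#'   points), `n`.
#' @export
#' @examples
#' least_squares_exponent(c(27, 59, 123), 3 * c(27, 59, 123)^2.39)
least_squares_exponent <- function(x, y, kind = NA_character_) {
  if (length(x) < 2 || length(y) != length(x))
    stop("need >= 2 (x, y) points", call. = FALSE)
  if (any(x <= 0) || any(y <= 0))
    stop("log-log fit needs strictly positive data", call. = FALSE)
  fit <- stats::lm(log(y) ~ log(x))
  se <- if (length(x) > 2)
    suppressWarnings(summary(fit)$coefficients[2, 2]) else NA_real_
  tibble::tibble(kind = kind,
                 value = unname(stats::coef(fit)[2]),
                 stderr = se, n = length(x))
}

#' Static tethered-chain size exponent profile
#'
#' From the mean distance of monomer m to the tethering point,
#' `nu_s0(m) = log(<R_m>/<R_1>) / log(m)` for every m >= 2 (m = 1 is the
#' normalization point and is excluded since log 1 = 0).
#'
#' @param sample a tethered-chain sample, a tibble with columns `m` and
#'   `R_mean` (see [sample_tethered_chain()]).
#' @return A tibble: `kind = "nu_s0"`, `abscissa` (= m), `value`.
#' @export
nu_s0_profile <- function(sample) {
  stopifnot(all(c("m", "R_mean") %in% names(sample)))
  if (!1 %in% sample$m)
    stop("sample lacks the m = 1 reference distance <R_1>", call. = FALSE)
  r1 <- sample$R_mean[match(1, sample$m)]
  rest <- sample[sample$m >= 2, ]
  tibble::tibble(kind = "nu_s0", abscissa = as.numeric(rest$m),
                 value = log(rest$R_mean / r1) / log(rest$m))
}

#' Static blob size exponent profile of a free chain
#'
#' From the mean distance of monomer pairs at bond separation s = |i - j|,
#' `nu_b0(s) = log(<R_s>/<R_1>) / log(s)` for s >= 2, normalized by the
#' nearest-neighbour distance (s = 1).
#'
#' @param sample a free-chain sample, a tibble with columns `s` and `R_mean`
#'   (see [sample_free_chain()]).
#' @return A tibble: `kind = "nu_b0"`, `abscissa` (= s), `value`.
#' @export
nu_b0_profile <- function(sample) {
  stopifnot(all(c("s", "R_mean") %in% names(sample)))
  if (!1 %in% sample$s)
    stop("sample lacks the s = 1 reference distance", call. = FALSE)
  r1 <- sample$R_mean[match(1, sample$s)]
  rest <- sample[sample$s >= 2, ]
  tibble::tibble(kind = "nu_b0", abscissa = as.numeric(rest$s),
                 value = log(rest$R_mean / r1) / log(rest$s))
}

# last-observation-carried-forward lookup of a step-function series n(t)
locf <- function(t_query, t_obs, n_obs) {
  idx <- findInterval(t_query, t_obs)
  out <- ifelse(idx == 0, n_obs[1] * 0, n_obs[pmax(idx, 1)])
  out
}

#' Ensemble variance of the translocation coordinate
#'
#' Resamples every run's translocation coordinate n(t) onto a common grid of
#' normalized time t/<tau> (step-function interpolation, last observation
#' carried forward) and returns the across-run variance
#' `<dn^2> = <n^2> - <n>^2` at each grid point. Once every run has
#' completed, all trajectories sit at n = N and the variance is exactly
#' zero.
#'
#' @param events batch tibble with columns `tau`, `status` and a list-column
#'   `n_series` of tibbles with columns `t`, `n`.
#' @param grid normalized-time grid t/<tau>; default 200 log-spaced points
#'   in [1e-3, 5].
#' @return A tibble: `t_norm`, `mean_n`, `var_n`, `n_runs`.
#' @export
translocation_variance <- function(events,
                                   grid = exp(seq(log(1e-3), log(5),
                                                  length.out = 200))) {
  stopifnot("n_series" %in% names(events))
  done <- events[events$status == "completed", ]
  if (nrow(done) < 2)
    stop("variance needs at least two completed runs", call. = FALSE)
  tau_bar <- mean(done$tau)
  t_abs <- grid * tau_bar
  mat <- vapply(done$n_series, function(sr) locf(t_abs, sr$t, sr$n),
                numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  m1 <- rowMeans(mat)
  v <- rowMeans(mat^2) - m1^2
  v[v < 0] <- 0  # guard fp round-off
  tibble::tibble(t_norm = grid, mean_n = m1, var_n = v, n_runs = nrow(done))
}

#' Fit the diffusion exponent gamma of the translocation coordinate
#'
#' Log-log slope of the variance curve `<dn^2> ~ t^gamma` over a window of
#' normalized time. The early-time window estimate (default t/<tau> in
#' [0.01, 0.1]) is the subdiffusion exponent gamma_p of the
#' tension-propagation stage; gamma = 1 is normal diffusion, gamma = 2
#' ballistic drift.
#'
#' @param variance a tibble from [translocation_variance()] (columns
#'   `t_norm`, `var_n`), or any tibble with those columns.
#' @param window length-2 numeric, the normalized-time interval of the fit.
#' @return A one-row tibble: `kind = "gamma"`, `value`, `stderr`,
#'   `window_lo`, `window_hi`, `n_points`.
#' @export
fit_gamma <- function(variance, window = c(0.01, 0.1)) {
  stopifnot(all(c("t_norm", "var_n") %in% names(variance)),
            length(window) == 2, window[1] < window[2])
  sel <- variance$t_norm >= window[1] & variance$t_norm <= window[2]
  pts <- variance[sel, ]
  if (nrow(pts) < 3)
    stop("need at least 3 grid points inside the fit window", call. = FALSE)
  if (any(pts$var_n <= 0))
    stop("variance must be strictly positive inside the fit window",
         call. = FALSE)
  fit <- least_squares_exponent(pts$t_norm, pts$var_n, kind = "gamma")
  fit$window_lo <- window[1]; fit$window_hi <- window[2]
  fit$n_points <- nrow(pts)
  fit[, c("kind", "value", "stderr", "window_lo", "window_hi", "n_points")]
}

#' Synthetic drift-diffusion translocation trajectories
#'
#' Generates integer-valued biased-walk trajectories of the translocation
#' coordinate on n in [0, N] whose ensemble variance grows as t^gamma
#' (a time-rescaled random walk: the k-th +/-1 step occurs at
#' `t_k = dt0 * k^(1/gamma)`, so the step count — and hence the variance —
#' grows as `(t/dt0)^gamma`), superposed on a deterministic drift
#' `floor(drift * t)`. n = N absorbs (the chain has fully translocated);
#' n < 0 is clamped to 0 (reflecting pore entrance). Used to validate every
#' estimator in this module without molecular dynamics.
#'
#' @param n_runs number of independent trajectories.
#' @param N number of monomers to transport.
#' @param drift deterministic drift rate in monomers per tu (0 for unbiased).
#' @param gamma anomalous-diffusion exponent of the noise (> 0); ignored
#'   when `noise = FALSE`.
#' @param noise logical; add the +/-1 random-walk component?
#' @param noise_steps number of walk steps laid down per drift time scale
#'   N/drift (controls dt0); default `1e4`. For `drift = 0` the walk is a
#'   plain unit-rate reflected random walk and this is ignored.
#' @param seed integer seed; run r uses `seed + r - 1`.
#' @param max_steps safety cap on walk steps per run.
#' @return A batch tibble with columns `seed`, `tau`, `status`, `N`, `Z`,
#'   `E`, `n_series` (list-column of tibbles `t`, `n`), matching the layout
#'   of [run_batch()].
#' @export
generate_synthetic_trajectories <- function(n_runs, N, drift = 0, gamma = 1,
                                            noise = TRUE, noise_steps = 1e4,
                                            seed = 1, max_steps = NULL) {
  stopifnot(n_runs >= 1, N >= 1)
  if (drift < 0) stop("drift must be >= 0", call. = FALSE)
  if (noise && gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (!noise && drift == 0)
    stop("invalid spec: neither drift nor noise", call. = FALSE)

  one <- function(r) {
    set.seed(seed + r - 1L)
    if (!noise) {                      # pure drift: tau = N / drift exactly
      ts <- (0:N) / drift
      return(list(tau = N / drift, status = "completed",
                  n_series = tibble::tibble(t = ts, n = 0:N)))
    }
    if (drift == 0) {
      # reflected (at 0) unit-rate walk, absorbed at N; Lindley construction
      K <- if (is.null(max_steps)) max(1000L, 50L * N^2) else max_steps
      steps <- sample(c(-1L, 1L), K, replace = TRUE)
      S <- cumsum(steps)
      n_path <- S - pmin(0L, cummin(S))
      hit <- match(N, n_path)
      tk <- seq_len(K)^(1 / gamma)     # dt0 = 1
      if (is.na(hit)) {
        keep <- thin_idx(K)
        return(list(tau = NA_real_, status = "max_time_reached",
                    n_series = tibble::tibble(t = tk[keep],
                                              n = n_path[keep])))
      }
      keep <- thin_idx(hit)
      return(list(tau = tk[hit], status = "completed",
                  n_series = tibble::tibble(t = c(0, tk[keep]),
                                            n = c(0L, n_path[keep]))))
    }
    # drift + rescaled noise
    tau_d <- N / drift
    dt0 <- tau_d / noise_steps^(1 / gamma)
    K <- if (is.null(max_steps)) as.integer(ceiling(4 * noise_steps))
         else max_steps
    steps <- sample(c(-1L, 1L), K, replace = TRUE)
    S <- c(0L, cumsum(steps))
    tk <- c(0, dt0 * seq_len(K)^(1 / gamma))
    # event times: walk steps plus drift unit-crossings
    tdrift <- (1:N) / drift
    ev <- sort(unique(c(tk, tdrift)))
    nw <- S[findInterval(ev, tk)]
    n_ev <- pmax(0L, pmin(N, floor(drift * ev + 1e-9) + nw))
    hit <- match(N, n_ev)
    if (is.na(hit)) {
      keep <- thin_idx(length(ev))
      return(list(tau = NA_real_, status = "max_time_reached",
                  n_series = tibble::tibble(t = ev[keep], n = n_ev[keep])))
    }
    keep <- thin_idx(hit)
    list(tau = ev[hit], status = "completed",
         n_series = tibble::tibble(t = ev[keep], n = n_ev[keep]))
  }

  runs <- purrr::map(seq_len(n_runs), one)
  tibble::tibble(
    seed = seed + seq_len(n_runs) - 1L,
    tau = purrr::map_dbl(runs, "tau"),
    status = purrr::map_chr(runs, "status"),
    N = N, Z = NA_integer_, E = NA_real_,
    n_series = purrr::map(runs, "n_series"))
}

# thin an index range 1..k to at most ~800 recording points, geometrically
# spaced early (resolving the subdiffusive window) and linear late, always
# keeping the final point
thin_idx <- function(k) {
  if (k <= 800) return(seq_len(k))
  geo <- unique(round(exp(seq(log(1), log(k), length.out = 400))))
  lin <- unique(round(seq(1, k, length.out = 400)))
  sort(unique(c(geo, lin, k)))
}
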