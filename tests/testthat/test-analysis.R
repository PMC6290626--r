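test_that("mean translocation time averages completed runs only", {
  ev <- tibble::tibble(tau = c(10, 20, 30), status = "completed")
  expect_equal(mean_tau(ev)$mean_tau, 20)

  ev2 <- tibble::tibble(tau = c(10, 20, NA),
                        status = c("completed", "completed",
                                   "max_time_reached"))
  mt <- mean_tau(ev2)
  expect_equal(mt$mean_tau, 15)
  expect_equal(mt$n_completed, 2)
  expect_equal(mt$n_failed, 1)

  single <- mean_tau(tibble::tibble(tau = 5, status = "completed"))
  expect_true(is.na(single$stderr))
  expect_error(mean_tau(tibble::tibble(tau = NA_real_,
                                       status = "max_time_reached")),
               "completed")
})

test_that("pairwise exponents are exact on power laws", {
  # exact power law recovered at any pair, abscissa at the geometric mean
  d <- pairwise_exponent(c(2, 3), 7 * c(2, 3)^1.65, sign = "+")
  expect_equal(d$value, 1.65)
  expect_equal(d$abscissa, sqrt(6))

  # doubling E halving tau gives delta = 1 at abscissa E1*sqrt(2)
  E1 <- 0.4
  d2 <- pairwise_exponent(c(E1, 2 * E1), c(100, 50), sign = "-")
  expect_equal(d2$value, 1)
  expect_equal(d2$abscissa, E1 * sqrt(2))

  # a flat pair is the unbiased-regime signature
  expect_equal(pairwise_exponent(c(1, 2), c(9, 9), sign = "-")$value, 0)

  # swapping the pair changes neither the exponent nor the abscissa
  a <- pairwise_exponent(c(2, 5), c(3, 11), sign = "+")
  b <- pairwise_exponent(c(5, 2), c(11, 3), sign = "+")
  expect_equal(a$value, b$value)
  expect_equal(a$abscissa, b$abscissa)

  expect_error(pairwise_exponent(c(1, 1), c(2, 3)), "differ")
  expect_error(pairwise_exponent(c(-1, 1), c(2, 3)), "positive")
})

test_that("exponent profiles map adjacent pairs along a curve", {
  df <- tibble::tibble(E = 2^(0:4), tau = 50 * (2^(0:4))^-1.2)
  prof <- exponent_profile(df, "E", "tau", sign = "-", kind = "delta")
  expect_equal(nrow(prof), 4)
  expect_equal(prof$value, rep(1.2, 4))
  expect_equal(prof$abscissa, sqrt(df$E[-5] * df$E[-1]))
})

test_that("least-squares exponent is exact on noiseless power laws", {
  x <- c(27, 59, 123)
  fit <- least_squares_exponent(x, 3 * x^2.39)
  expect_equal(fit$value, 2.39, tolerance = 1e-10)
  # two points reduce to the pairwise estimator
  expect_equal(least_squares_exponent(c(2, 8), c(5, 20))$value,
               pairwise_exponent(c(2, 8), c(5, 20), "+")$value)
  expect_equal(least_squares_exponent(1:10, rep(4, 10))$value, 0)
  expect_error(least_squares_exponent(3, 5), ">= 2")
})

test_that("static exponent profiles recover planted exponents exactly", {
  m <- 1:50
  teth <- tibble::tibble(m = m, R_mean = 1.3 * m^0.71)
  prof <- nu_s0_profile(teth)
  expect_equal(prof$value, rep(0.71, 49), tolerance = 1e-10)
  expect_false(1 %in% prof$abscissa)        # m = 1 excluded (log 1 = 0)
  # constant profile gives zero exponent
  expect_equal(nu_s0_profile(tibble::tibble(m = 1:10, R_mean = 2))$value,
               rep(0, 9))
  expect_error(nu_s0_profile(tibble::tibble(m = 2:10, R_mean = 2)), "R_1")

  s <- 1:40
  free <- tibble::tibble(s = s, R_mean = 0.97 * s^0.55)
  pb <- nu_b0_profile(free)
  expect_equal(pb$value, rep(0.55, 39), tolerance = 1e-10)
  expect_false(1 %in% pb$abscissa)
  expect_error(nu_b0_profile(tibble::tibble(s = 2:10, R_mean = 1)), "s = 1")
})

test_that("variance of the translocation coordinate behaves as an ensemble variance", {
  mk <- function(ns, tau) tibble::tibble(
    tau = tau, status = "completed", n_series = ns)
  sr <- tibble::tibble(t = c(0, 1, 2, 3), n = c(0, 2, 5, 10))
  # identical runs: variance identically zero
  b <- mk(list(sr, sr, sr), c(3, 3, 3))
  v <- translocation_variance(b, grid = c(0.1, 0.5, 1))
  expect_equal(v$var_n, rep(0, 3))

  # two runs differing by 2 at a grid point: variance 1 there
  sr2 <- dplyr::mutate(sr, n = n + c(0, 2, 2, 0))
  b2 <- mk(list(sr, sr2), c(3, 3))
  v2 <- translocation_variance(b2, grid = c(1 / 3))  # t = 1
  expect_equal(v2$var_n, 1)

  # late tail: all runs completed and parked at n = N, variance zero
  v3 <- translocation_variance(b2, grid = c(2))      # t = 6 > all tau
  expect_equal(v3$var_n, 0)

  expect_error(translocation_variance(mk(list(sr), 3)), "two completed")
})

test_that("gamma fits recover planted diffusion exponents", {
  grid <- exp(seq(log(1e-3), log(1), length.out = 120))
  for (g in c(0.78, 1, 2)) {
    v <- tibble::tibble(t_norm = grid, var_n = 2.7 * grid^g)
    fit <- fit_gamma(v, window = c(0.01, 0.1))
    expect_equal(fit$value, g, tolerance = 1e-10)
  }
  v <- tibble::tibble(t_norm = grid, var_n = 0 * grid)
  expect_error(fit_gamma(v), "positive")
  expect_error(fit_gamma(tibble::tibble(t_norm = c(0.02, 0.05),
                                        var_n = c(1, 2)),
                         window = c(0.01, 0.1)), "3 grid points")
})

test_that("synthetic generator: pure drift is exact and reproducible", {
  b <- generate_synthetic_trajectories(3, N = 20, drift = 2, noise = FALSE,
                                       seed = 1)
  expect_equal(b$tau, rep(10, 3))
  expect_equal(b$status, rep("completed", 3))
  v <- translocation_variance(b, grid = c(0.2, 0.5, 0.9))
  expect_equal(v$var_n, rep(0, 3))
  b2 <- generate_synthetic_trajectories(3, N = 20, drift = 2, noise = FALSE,
                                        seed = 1)
  expect_identical(b$tau, b2$tau)
  expect_error(generate_synthetic_trajectories(3, 20, drift = 0,
                                               noise = FALSE), "invalid")
})

test_that("unbiased generator matches the discrete first-passage oracle", {
  N <- 12
  b <- generate_synthetic_trajectories(400, N = N, drift = 0, gamma = 1,
                                       seed = 2)
  mt <- mean_tau(b)
  # oracle: mean absorption time of the lazily reflected +/-1 walk on 0..N,
  # E[T_n] = 1 + (E[T_max(n-1,0)] + E[T_n+1])/2, E[T_N] = 0, solved exactly
  A <- matrix(0, N, N)
  for (n in 0:(N - 1)) {
    i <- n + 1
    A[i, i] <- A[i, i] + 1
    down <- max(n - 1, 0) + 1
    A[i, down] <- A[i, down] - 0.5
    if (n + 1 < N) A[i, n + 2] <- A[i, n + 2] - 0.5
  }
  ET <- solve(A, rep(1, N))[1]
  expect_equal(ET, 156)                       # frozen oracle value, N = 12
  expect_lt(abs(mt$mean_tau - ET), 3 * mt$stderr)
})

test_that("planted drift and anomalous-diffusion exponent are recovered", {
  b <- generate_synthetic_trajectories(500, N = 20000, drift = 5,
                                       gamma = 0.75, noise_steps = 3e4,
                                       seed = 11)
  # drift from the mean absorption time
  mt <- mean_tau(b)
  expect_lt(abs(20000 / mt$mean_tau - 5), 3 * 5 * mt$stderr / mt$mean_tau)
  # gamma from the ensemble variance (wide window for slope leverage)
  fit <- fit_gamma(translocation_variance(b), window = c(0.003, 0.3))
  expect_equal(fit$value, 0.75, tolerance = 0.03)
  # honest uncertainty: group-wise refits bracket the planted value
  gs <- vapply(split(seq_len(500), rep(1:10, each = 50)), function(ix)
    fit_gamma(translocation_variance(b[ix, ]),
              window = c(0.003, 0.3))$value, numeric(1))
  se <- stats::sd(gs) / sqrt(length(gs))
  expect_lt(abs(mean(gs) - 0.75), 3 * se)
})
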