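test_that("a fixed seed reproduces the trajectory exactly", {
  p <- quick_params(E = 8, seed = 3)
  e1 <- run_translocation(p, equil_time = 5, seed = 3)
  e2 <- run_translocation(p, equil_time = 5, seed = 3)
  expect_identical(e1$tau, e2$tau)
  expect_identical(e1$n_series, e2$n_series)
  expect_identical(e1$final_state$positions, e2$final_state$positions)
  e3 <- run_translocation(p, equil_time = 5, seed = 4)
  expect_false(identical(e1$tau, e3$tau))
})

test_that("completed runs transport exactly N = Nm - 5 monomers", {
  p <- quick_params(E = 8, Nm = 16, seed = 5)
  ev <- run_translocation(p, equil_time = 10, seed = 5)
  expect_equal(ev$status, "completed")
  expect_equal(ev$N, 11)
  expect_equal(dplyr::last(ev$n_series$n), ev$N)
  expect_true(all(ev$n_series$n >= 0 & ev$n_series$n <= ev$N))
  expect_equal(dplyr::last(ev$n_series$cis), 0)
  # tau is the last time the cis side was occupied
  expect_gte(ev$tau, max(ev$n_series$t[ev$n_series$cis > 0]))
  # glance/tidy expose the event tidily
  expect_equal(glance(ev)$tau, ev$tau)
  expect_equal(nrow(tidy(ev)), nrow(ev$n_series))
})

test_that("the head barrier keeps monomer 1 beyond the pore exit", {
  # weak field: the chain jiggles for a while, the head must never re-enter
  p <- quick_params(E = 0.5, Nm = 12, seed = 8)
  ev <- run_translocation(p, equil_time = 15, max_time = 2e3, seed = 8)
  expect_gte(ev$min_head_gap, 0)
})

test_that("translocation completes by random walk in zero field", {
  p <- quick_params(E = 0, Nm = 8, seed = 5)
  ev <- run_translocation(p, equil_time = 10, max_time = 2e4, seed = 5)
  expect_equal(ev$status, "completed")
  expect_true(is.finite(ev$tau) && ev$tau > 0)
})

test_that("batches use distinct sequential seeds and are reproducible", {
  p <- quick_params(E = 16, Nm = 12, seed = 30)
  b1 <- run_batch(p, n_runs = 3, seed0 = 30, equil_time = 5)
  expect_equal(b1$seed, 30:32)
  expect_equal(length(unique(b1$tau)), 3)
  b2 <- run_batch(p, n_runs = 3, seed0 = 30, equil_time = 5)
  expect_identical(b1$tau, b2$tau)
  expect_identical(b1$n_series, b2$n_series)

  # runs cut off by max_time are flagged, kept, and excluded from the mean
  b3 <- run_batch(p, n_runs = 3, seed0 = 30, equil_time = 5, max_time = 0.2)
  expect_equal(b3$status, rep("max_time_reached", 3))
  expect_error(mean_tau(b3), "completed")
  b4 <- dplyr::bind_rows(b1, b3)
  mt <- mean_tau(b4)
  expect_equal(mt$n_completed, 3)
  expect_equal(mt$n_failed, 3)
  expect_equal(mt$mean_tau, mean(b1$tau))
})

test_that("single Langevin steps are deterministic and advance the state", {
  p <- quick_params(Z = 1, E = 0, Nm = 8, seed = 2)
  sys <- build_initial_state(p)
  s1 <- langevin_step(sys, p, n_steps = 200, seed = 9)
  s2 <- langevin_step(sys, p, n_steps = 200, seed = 9)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$velocities, s2$velocities)
  expect_false(identical(s1$positions, sys$positions))
  # the state container survives the round trip
  expect_s3_class(s1, "particle_system")
  expect_identical(s1$charges, sys$charges)
})

test_that("the thermostat reproduces the target temperature and equipartition", {
  p <- ideal_params(Nm = 12, seed = 6)
  sys <- porescale:::build_static_state(p, start = c(20, 8, 8), wall = FALSE,
                                        seed = 6)
  par <- porescale:::engine_params(p, wall_on = FALSE, barrier_on = FALSE,
                                   field_on = FALSE)
  out <- porescale:::.ps_run_nvt(sys$positions, sys$velocities, sys$charges,
                                 par, time = 100, sample_every = 4,
                                 freeze_head = FALSE, thermostat = TRUE,
                                 seed = 6)
  n <- nrow(sys$positions)
  kT <- mean(out$kinetic) / (1.5 * n)
  expect_equal(kT, 1, tolerance = 0.02)     # kinetic temperature within 2%
  # equipartition: per-component velocity variance = kBT/m on particle 1
  expect_equal(unname(apply(out$v1, 2, stats::var)), rep(1, 3),
               tolerance = 0.1)
})

test_that("without the thermostat the integrator conserves energy", {
  p <- ideal_params(Nm = 8, seed = 6, dt = 0.002)
  p$eps_pp <- 1.2                              # WCA back on: full test system
  sys <- porescale:::build_static_state(p, start = c(20, 8, 8), wall = FALSE,
                                        seed = 6)
  par <- porescale:::engine_params(p, wall_on = FALSE, barrier_on = FALSE,
                                   field_on = FALSE)
  out <- porescale:::.ps_run_nvt(sys$positions, sys$velocities, sys$charges,
                                 par, time = 50, sample_every = 10,
                                 freeze_head = FALSE, thermostat = FALSE,
                                 seed = 6)
  etot <- out$kinetic + out$potential
  drift <- abs(unname(stats::coef(stats::lm(etot ~ out$t))[2]))
  expect_lt(drift, 1e-3)                       # kBT per tu
})

test_that("trajectories are invariant under translation by a lattice vector", {
  p <- quick_params(Z = 2, Nm = 8, n_salt = 4, seed = 9)
  sys <- build_initial_state(p)
  par <- porescale:::engine_params(p, wall_on = TRUE, barrier_on = TRUE,
                                   field_on = TRUE)
  o1 <- porescale:::.ps_run_nvt(sys$positions, sys$velocities, sys$charges,
                                par, time = 1, sample_every = 200,
                                freeze_head = FALSE, thermostat = TRUE,
                                seed = 5)
  shifted <- sweep(sys$positions, 2, p$box, "+")
  o2 <- porescale:::.ps_run_nvt(shifted, sys$velocities, sys$charges,
                                par, time = 1, sample_every = 200,
                                freeze_head = FALSE, thermostat = TRUE,
                                seed = 5)
  expect_equal(o2$positions - rep(p$box, each = nrow(shifted)),
               o1$positions, tolerance = 1e-8)
})

test_that("tethered-chain sampling recovers the ideal-chain size exponent", {
  # non-interacting control: <R_m> ~ m^(1/2) for a harmonic (ideal) chain
  p <- ideal_params(Nm = 24, seed = 2)
  s <- sample_tethered_chain(p, n_samples = 3000, burn_time = 200,
                             sample_dt = 10, seed = 7)
  expect_equal(attr(s, "mode"), "tethered")
  expect_true(all(s$R_mean > 0))
  expect_gt(s$R_mean[1], 0)                     # <R_1> positive and finite
  fit <- least_squares_exponent(s$m[4:24], s$R_mean[4:24])
  expect_lt(abs(fit$value - 0.5), 0.05)
  # the exponent profile heads the same way (the tether bond biases small m)
  prof <- nu_s0_profile(s)
  expect_lt(abs(mean(prof$value[prof$abscissa >= 8]) - 0.5), 0.1)
})

test_that("tethered chains swell less in divalent than monovalent salt", {
  s1 <- sample_tethered_chain(quick_params(Z = 1, E = 0, Nm = 32, seed = 13),
                              n_samples = 400, burn_time = 150,
                              sample_dt = 4, seed = 13)
  s2 <- sample_tethered_chain(quick_params(Z = 2, E = 0, Nm = 32, seed = 13),
                              n_samples = 400, burn_time = 150,
                              sample_dt = 4, seed = 13)
  sel <- 8:32                                   # beyond the tether region
  expect_true(all(s1$R_mean[sel] > s2$R_mean[sel]))
})

test_that("free-chain pair distances behave like blob sizes", {
  p1 <- quick_params(Z = 1, E = 0, Nm = 24, seed = 3)
  p2 <- quick_params(Z = 2, E = 0, Nm = 24, seed = 3)
  f1 <- sample_free_chain(p1, n_samples = 300, burn_time = 150,
                          sample_dt = 3, seed = 3)
  f2 <- sample_free_chain(p2, n_samples = 300, burn_time = 150,
                          sample_dt = 3, seed = 3)
  expect_equal(attr(f1, "mode"), "free")
  # nearest-neighbour distance is the bond length (stiff bonds)
  expect_equal(f1$R_mean[1], p1$b0, tolerance = 0.1)
  # stronger screening with divalent salt: smaller <R_ij> at matched s
  expect_true(all(f2$R_mean[4:23] < f1$R_mean[4:23]))
  # the profile feeds the blob exponent estimator
  prof <- nu_b0_profile(f1)
  expect_true(all(is.finite(prof$value)))
})
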