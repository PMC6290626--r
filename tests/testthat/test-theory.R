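test_that("regime exponents reproduce the four scaling laws", {
  # illustrative set: nu_s = 0.4, z_p(1-gamma_p) = 1.4, p_z(1-q) = 1.67, q = 0.25
  tp <- theory_params(nu_s = 0.4, z_p = 1.4 / 0.5, gamma_p = 0.5, q = 0.25,
                      p_z = 1.67 / 0.75)
  ex <- regime_exponents(tp)
  expect_equal(ex$alpha[ex$regime == "UB"], 2.56)
  expect_equal(ex$delta[ex$regime == "UB"], 0)
  expect_equal(ex$alpha[ex$regime == "WD"], 1.56)
  expect_equal(ex$delta[ex$regime == "WD"], 1)
  expect_equal(ex$delta[ex$regime == "SD(T)"], 1.67)
  expect_equal(ex$alpha[ex$regime == "SD(I)"], 1.4)

  # monovalent-salt observed values: alpha in the trumpet regime
  tp1 <- theory_params(nu_s = 0.35, q = 0.86, p_z = 1.65 / 0.14)
  a_sdt <- regime_exponents(tp1, "SD(T)")$alpha
  expect_equal(a_sdt, 1 + 0.35 * 0.14)
  expect_equal(round(a_sdt, 2), 1.05)
  # divalent isoflux alpha
  expect_equal(regime_exponents(theory_params(nu_s = 0.5), "SD(I)")$alpha, 1.5)

  # a missing member is named in the error
  expect_error(regime_exponents(theory_params(nu_s = 0.4), "UB"), "z_p")
})

test_that("regime boundaries carry the reciprocal exponent structure", {
  tp <- theory_params(nu_s = 0.35, rho = 1.50, eta = 1.32)
  bd <- regime_boundaries(tp)
  expect_equal(bd$f_exponent[bd$boundary == "f1*"], -1)
  expect_equal(bd$f_exponent[bd$boundary == "f2*"], -0.525)
  expect_equal(bd$N_exponent[bd$boundary == "f2*"], -1 / 0.525)
  # reciprocity holds for every boundary
  expect_equal(bd$f_exponent * bd$N_exponent, rep(1, 3))
})

test_that("derived relations close the exponent system", {
  expect_equal(derived_relations(theory_params(nu_b = 0.68))$q, 0.32 / 1.68)
  expect_equal(round(derived_relations(theory_params(nu_b = 0.68))$q, 2), 0.19)
  expect_equal(round(derived_relations(theory_params(nu_b = 0.55))$q, 2), 0.29)

  # gamma_p relation solved for z_p: the printed 4.95 / 4.00 pair
  z1 <- derived_relations(theory_params(nu_s = 0.35, gamma_p = 0.78))$z_p
  z2 <- derived_relations(theory_params(nu_s = 0.50, gamma_p = 0.75))$z_p
  expect_equal(round(z1, 2), 4.95)
  expect_equal(round(z2, 2), 4.00)

  # rod limit
  rod <- derived_relations(theory_params(nu_b = 1))
  expect_equal(rod$q, 0)
  expect_equal(rod$z, 3)
  expect_equal(rod$p_z, 1)

  # contradictory over-determined inputs produce a residual diagnostic
  expect_error(
    derived_relations(theory_params(nu_s = 0.35, gamma_p = 0.78, z_p = 3)),
    "residual")
})

test_that("observed-exponent inversion reproduces the published chain", {
  inv1 <- invert_observed(2.39, 1.05, 1.35, 1.65, 0.78)
  expect_equal(inv1$nu_s_2dp, 0.35)
  expect_equal(inv1$q_2dp, 0.86)
  expect_equal(inv1$z_p_2dp, 5.06)
  expect_equal(inv1$rho_2dp, 1.50)
  expect_equal(inv1$eta_2dp, 1.32)

  inv2 <- invert_observed(2.61, 1.06, 1.50, 1.77, 0.75)
  expect_equal(inv2$nu_s_2dp, 0.50)
  expect_equal(inv2$q_2dp, 0.88)
  expect_equal(inv2$z_p_2dp, 4.88)
  expect_equal(inv2$rho_2dp, 1.43)
  expect_equal(inv2$eta_2dp, 1.14)

  # fully stretched limit
  expect_equal(invert_observed(2.5, 2, 2, 1.5, 0.5)$q, 0)

  # singular inputs are rejected with the offending symbol implied
  expect_error(invert_observed(2.4, 1.05, 1.35, 1, 0.78), "delta_SDT")
  expect_error(invert_observed(2.4, 1.05, 1.35, 1.65, 1), "gamma_p")
})

test_that("inversion followed by the relations is idempotent on consistent inputs", {
  # construct a self-consistent exponent set from nu_s = 0.5, nu_b = 0.6
  nu_s <- 0.5; nu_b <- 0.6
  q <- (1 - nu_b) / (1 + nu_b)          # 0.25
  p_z <- 1 / nu_b                        # Rouse: z - 2
  gamma_p <- 0.75
  z_p <- (1 + nu_s) / (gamma_p * nu_s)   # 4
  a_ub <- 2 + nu_s * z_p * (1 - gamma_p)
  a_sdt <- 1 + nu_s * (1 - q)
  a_sdi <- 1 + nu_s
  d_sdt <- p_z * (1 - q)
  inv <- invert_observed(a_ub, a_sdt, a_sdi, d_sdt, gamma_p,
                         from_reported = FALSE)
  expect_equal(inv$nu_s, nu_s)
  expect_equal(inv$q, q)
  expect_equal(inv$z_p, z_p)
  tp <- derived_relations(theory_params(nu_s = inv$nu_s, q = inv$q,
                                        z_p = inv$z_p, gamma_p = gamma_p))
  tp2 <- derived_relations(tp)
  expect_equal(tidy(tp2), tidy(tp))     # same members (attributes aside)
  expect_equal(tp$rho, inv$rho)
  expect_equal(tp$eta, inv$eta)
})

test_that("consistency inequalities hold for both salt columns", {
  for (Z in 1:2) {
    tp <- observed_theory_params(Z)
    ineq <- check_inequalities(tp)
    expect_true(all(ineq$satisfied))
    expect_true(all(ineq$margin > 0))
  }
  # constructed violation: nu_s*z_p*gamma_p = 3 misses the bound by 1
  bad <- theory_params(nu_s = 1, z_p = 3, gamma_p = 1, q = 0.5, p_z = 4,
                       rho = 2, eta = 1)
  ineq <- check_inequalities(bad)
  row <- ineq[ineq$inequality == "nu_s*z_p*gamma_p < 2", ]
  expect_false(row$satisfied)
  expect_equal(row$margin, -1)
})

test_that("pulled-chain tension propagation gives z_p = 2/nu_s0", {
  expect_equal(round(pulled_chain_zp(0.71), 2), 2.82)
  expect_equal(round(pulled_chain_zp(0.57), 2), 3.51)
  expect_equal(pulled_chain_zp(1), 2)
  expect_error(pulled_chain_zp(0), "positive")
})

test_that("slope ordering X1 < X2 < X3 and Y1 > Y2 > Y3 on the feasible set", {
  set.seed(42)
  n_checked <- 0
  for (i in 1:1500) {
    nu_s <- runif(1, 0.2, 0.9); gamma_p <- runif(1, 0.5, 0.95)
    z_p <- runif(1, 1.5, 8); q <- runif(1, 0.05, 0.95)
    p_z <- runif(1, 1, 15)
    den <- p_z * (1 - q) - 1
    if (abs(den) < 1e-3) next
    rho <- (z_p * (1 - gamma_p) - 1 + q) / den
    eta <- q / den
    if (rho <= 0 || eta <= 0) next
    tp <- theory_params(nu_s = nu_s, gamma_p = gamma_p, z_p = z_p, q = q,
                        p_z = p_z, rho = rho, eta = eta)
    if (!all(check_inequalities(tp)$satisfied)) next
    sl <- boundary_slopes(tp)
    expect_true(sl$X[1] < sl$X[2] && sl$X[2] < sl$X[3])
    expect_true(sl$Y[1] > sl$Y[2] && sl$Y[2] > sl$Y[3])
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 100)
})

test_that("theory curves are continuous piecewise power laws", {
  rho <- (1.4 - 1 + 0.25) / (1.67 - 1)
  eta <- 0.25 / (1.67 - 1)
  tp <- theory_params(nu_s = 0.4, z_p = 2.8, gamma_p = 0.5, q = 0.25,
                      p_z = 1.67 / 0.75, rho = rho, eta = eta)
  grid <- 10^seq(-4, 2, length.out = 400)
  crv <- theory_curve(tp, grid, mode = "tau_vs_f", N = 128)
  expect_setequal(unique(crv$regime), c("UB", "WD", "SD(T)", "SD(I)"))
  # continuity: log tau has no jumps (second differences stay small)
  expect_lt(max(abs(diff(diff(log(crv$tau))))), 0.1)
  # SD(T) section falls with slope -p_z(1-q) = -1.67
  sdt <- crv[crv$regime == "SD(T)", ]
  expect_equal(least_squares_exponent(sdt$x, sdt$tau)$value, -1.67,
               tolerance = 1e-6)
  # doubling N shifts the whole curve upward
  crv2 <- theory_curve(tp, grid, mode = "tau_vs_f", N = 256)
  expect_true(all(crv2$tau >= crv$tau))

  # tau vs N: SD(I) section rises with slope 1 + nu_s
  crvN <- theory_curve(tp, 10^seq(1, 12, length.out = 300),
                       mode = "tau_vs_N", f = 0.05)
  sdi <- crvN[crvN$regime == "SD(I)", ]
  expect_gt(nrow(sdi), 5)
  expect_equal(least_squares_exponent(sdi$x, sdi$tau)$value, 1.4,
               tolerance = 1e-6)
})

test_that("tension-propagation ODE matches its analytic asymptotes", {
  tp <- theory_params(nu_s = 0.4, q = 0.25, p_z = 1.67 / 0.75)
  res <- solve_tension_ode(tp, f = 1e4, N = 2^(10:20))
  slopeN <- least_squares_exponent(res$N, res$tau_p)$value
  expect_equal(slopeN, 1 + 0.4 * 0.75, tolerance = 0.02)

  res_f <- solve_tension_ode(tp, f = 10^seq(4, 8, 0.5), N = 2^16)
  slopeF <- least_squares_exponent(res_f$f, res_f$tau_p)$value
  expect_equal(slopeF, -1.67, tolerance = 0.02)

  # the subleading R_p^2 term is negligible at large f
  full <- solve_tension_ode(tp, f = 1e4, N = 2^16)$tau_p
  lead <- solve_tension_ode(tp, f = 1e4, N = 2^16,
                            drop_subleading = TRUE)$tau_p
  expect_lt(abs(full - lead) / full, 0.01)

  # isoflux variant reproduces tau_p ~ N^(1+nu_s) f^(-1)
  iso_N <- solve_tension_ode(tp, f = 1e4, N = 2^(10:20), variant = "isoflux")
  expect_equal(least_squares_exponent(iso_N$N, iso_N$tau_p)$value, 1.4,
               tolerance = 0.02)
  iso_f <- solve_tension_ode(tp, f = 10^seq(2, 6, 0.5), N = 2^16,
                             variant = "isoflux")
  expect_equal(least_squares_exponent(iso_f$f, iso_f$tau_p)$value, -1,
               tolerance = 0.02)
})

test_that("tidy and glance summarise theory parameter sets", {
  tp <- observed_theory_params(1)
  td <- tidy(tp)
  expect_equal(nrow(td), 9)
  expect_true(all(c("exponent", "value") %in% names(td)))
  gl <- glance(tp)
  expect_true(gl$inequalities_hold)
})
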