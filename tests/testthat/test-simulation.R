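test_that("ODE solution reaches the analytic binding equilibrium", {
  m <- binding_model(kf = 1, kr = 1)
  tr <- simulate_ode(m, t_end = 200)
  ceq <- binding_equilibrium(1, 1)
  expect_equal(unname(tr$conc[nrow(tr$conc), "C"]), ceq, tolerance = 1e-4)
  expect_true(all(diff(tr$times) > 0))
})

test_that("the SM-free subspace is invariant when SM starts at zero", {
  tr <- simulate_ode(yeast_ssnm(sm0 = 0), t_end = 1000)
  sm_cols <- c("ySM", "yPinSM", "yFusedSM")
  expect_true(all(abs(tr$conc[, sm_cols]) < 1e-12))
})

test_that("fusion level is normalized, non-decreasing and complete when all v-SNARE fuses", {
  m <- yeast_ssnm(sm0 = 4.5)
  tr <- simulate_ode(m, t_end = 2000)
  f <- fusion_level(tr)
  expect_equal(f[1], 0)
  expect_true(all(f >= 0 & f <= 1 + 1e-6))
  expect_true(all(diff(f) >= -1e-9))
  # all v-SNARE initialized in a fused complex reads 1 at t = 0
  y0 <- stats::setNames(numeric(length(m$initial)), names(m$initial))
  y0["yFused"] <- 4.5
  tr1 <- simulate_ode(m, t_end = 1, y0 = y0, n_points = 5)
  expect_equal(fusion_level(tr1)[1], 1)
  # no readout moiety at all -> error
  y0["yFused"] <- 0
  tr0 <- simulate_ode(m, t_end = 1, y0 = y0, n_points = 5)
  expect_error(fusion_level(tr0), "readout")
})

test_that("moiety totals are conserved and concentrations stay non-negative", {
  for (cm in catalog_models()) {
    sm <- catalog_sm(cm)
    tr <- simulate_ode(cm, t_end = 1500,
                       y0 = stats::setNames(3, sm), n_points = 200)
    expect_true(all(tr$conc > -1e-9))
    M <- ssnm:::moiety_matrix(cm)
    totals <- tr$conc %*% M
    for (j in seq_len(ncol(totals))) {
      t0 <- totals[1, j]
      if (t0 > 0)
        expect_lt(max(abs(totals[, j] - t0)) / t0, 1e-6)
    }
  }
})

test_that("plateau readout detects immediate plateau, SM stimulation, and self-consistency", {
  m <- yeast_ssnm(sm0 = 4.5)
  r <- rate_set(m)
  # no fusion channels: immediate plateau at zero fusion
  r0 <- r
  r0$R4 <- c(kf = 0, kr = 1e-9)  # keep validity: one rate positive
  r0$R5 <- c(kf = 0, kr = 1e-9)
  p0 <- plateau_readout(m, r0, t_max = 100)
  expect_true(p0$plateau_met)
  expect_equal(p0$fusion, 0, tolerance = 1e-9)

  # SM stimulates: plateau fusion strictly larger with SM than without
  p_sm <- plateau_readout(m, y0 = c(ySM = 4.5))
  p_no <- plateau_readout(m, y0 = c(ySM = 0))
  expect_gt(p_sm$fusion, p_no$fusion)

  # fast-fusing configuration meets the plateau criterion and is stable:
  # value within 1e-3 of the value at twice the plateau time
  rf <- r
  rf$R5 <- c(kf = 0.05, kr = 0)
  p <- plateau_readout(m, rf, t_max = 2000)
  expect_true(p$plateau_met)
  tr2 <- simulate_ode(m, rf, t_end = 2 * p$time)
  expect_lt(abs(tail(fusion_level(tr2), 1) - p$fusion), 1e-3)
})

test_that("plateau fusion is insensitive to halving the integrator tolerances", {
  m <- neuronal_ssnm()
  p1 <- plateau_readout(m, y0 = c(nSM = 3), t_max = 2000)
  p2 <- plateau_readout(m, y0 = c(nSM = 3), t_max = 2000,
                        rtol = 5e-7, atol = 5e-10)
  expect_lt(abs(p1$fusion - p2$fusion), 1e-4)
})

test_that("dose_response is a pure per-dose function with validated input", {
  m <- yeast_ssnm()
  expect_error(dose_response(m, scan_species = "ySM", values = c(0, 1)),
               "at least 3")
  expect_error(dose_response(m, scan_species = "ySM", values = c(0, 1, 1)),
               "strictly increasing")
  expect_error(dose_response(m, scan_species = "nope", values = 0:3),
               "not in the model")
  d1 <- dose_response(m, scan_species = "ySM", values = c(0, 2, 4),
                      t_max = 500)
  d2 <- dose_response(m, scan_species = "ySM", values = c(0, 2, 4),
                      t_max = 500)
  expect_identical(d1$fusion, d2$fusion)
})

test_that("stochastic simulation is seed-reproducible and zero stays zero", {
  m <- yeast_ssnm(sm0 = 3)
  s1 <- simulate_stochastic(m, t_end = 20, omega = 200, seed = 7)
  s2 <- simulate_stochastic(m, t_end = 20, omega = 200, seed = 7)
  expect_identical(s1$conc, s2$conc)
  s3 <- simulate_stochastic(m, t_end = 20, omega = 200, seed = 8)
  expect_false(identical(s1$conc, s3$conc))

  z <- binding_model(a0 = 0, b0 = 0)
  sz <- simulate_stochastic(z, t_end = 10, omega = 100, seed = 1)
  expect_true(all(sz$conc == 0))
})

test_that("Gillespie ensemble mean matches the ODE for the binding system", {
  m <- binding_model(kf = 1, kr = 1)
  nrun <- 60
  omega <- 500
  cs <- numeric(nrun)
  set.seed(123)
  for (i in seq_len(nrun)) {
    s <- simulate_stochastic(m, t_end = 10, omega = omega, n_points = 2)
    cs[i] <- s$conc[2, "C"]
  }
  ode_c <- tail(simulate_ode(m, t_end = 10)$conc[, "C"], 1)
  se <- sd(cs) / sqrt(nrun)
  expect_lt(abs(mean(cs) - ode_c), 3 * se + 1 / omega)
})
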