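test_that("the circadian modulation factor has unit period and mean", {
  expect_equal(modulation_factor(runif(5), 0, 0.3), rep(1, 5))
  expect_equal(modulation_factor(0.4, 0.25, 0.4), 1.25)
  tt <- seq(0, 1, length.out = 2001)[-2001]
  expect_equal(mean(modulation_factor(tt, 0.3, 0.77)), 1, tolerance = 1e-10)
  expect_equal(modulation_factor(2.35, 0.2, 0.1),
               modulation_factor(3.35, 0.2, 0.1))
})

test_that("the compiled RHS matches an independent R transcription", {
  p <- oc_test_params()
  set.seed(11)
  parlist <- list(p = p$baseline, amp = c(0, 0, 0, 0),
                  phase = c(0, 0, 0, 0), r1 = p$rba$r1, r2 = p$rba$r2,
                  inh0 = 0, exo = NULL)
  off <- circadian_switches(FALSE, FALSE, FALSE, FALSE)
  for (i in 1:100) {
    st <- p$init * exp(rnorm(12, 0, 0.5))
    lag <- runif(1, 0.1, 2)
    t <- runif(1, 0, 28)
    got <- cycle_rhs(t, st, lag, p, off)
    parlist$inh0 <- lag
    want <- unlist(oracle_rhs(0.5, unname(st), parlist))  # t enters only
    # via the (disabled) cosine in the oracle when amp = 0, but lagged Inh
    # is read from parlist$inh0 because t - tau < 0 at t = 0.5
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("doubling basal LH synthesis shifts d(RP_LH)/dt by the synthesis term", {
  p <- oc_test_params()
  st <- p$init
  d1 <- cycle_rhs(3.2, st, st[["Inh"]], p)
  p2 <- p
  p2$baseline$V0_LH <- 2 * p$baseline$V0_LH
  d2 <- cycle_rhs(3.2, st, st[["Inh"]], p2)
  ob <- observables(3.2, st, 0, 0, p)
  fac <- modulation_factor(3.2, p$circadian$amplitude[["LH"]],
                           p$circadian$acrophase[["LH"]])
  expected <- p$baseline$V0_LH * fac /
    (1 + ob[["P4"]] / p$baseline$Ki_LH_P)
  expect_equal(d2[["RP_LH"]] - d1[["RP_LH"]], expected, tolerance = 1e-10)
  # only the RP_LH equation is affected instantaneously
  expect_equal(d2[-1], d1[-1], tolerance = 1e-12)
})

test_that("disabling a switch is identical to zeroing its amplitude", {
  p <- oc_test_params()
  off_lh <- circadian_switches(LH = FALSE)
  p0 <- p
  p0$circadian$amplitude[["LH"]] <- 0
  st <- p$init
  expect_identical(cycle_rhs(5.3, st, 0.4, p, off_lh),
                   cycle_rhs(5.3, st, 0.4, p0, circadian_switches()))
  s1 <- simulate_cycle(p, days = 5, switches = off_lh, out_dt = 0.05)
  s2 <- simulate_cycle(p0, days = 5, out_dt = 0.05)
  expect_identical(s1$LH, s2$LH)
  expect_identical(s1$P4, s2$P4)
})

test_that("observables combine stage masses, rhythm and exogenous hormones", {
  p <- oc_test_params()
  st <- rep(0, 12)
  ob <- observables(0.25, st, 0, 0, p,
                    circadian_switches(FALSE, FALSE, FALSE, FALSE))
  expect_equal(ob[["E2"]], p$baseline$e0)
  expect_equal(ob[["P4"]], p$baseline$p0)
  ob2 <- observables(0.25, st, exo_e2 = 100, exo_p4 = 0, p)
  expect_equal(ob2[["E2"]] - observables(0.25, st, 0, 0, p)[["E2"]], 170)
  ob3 <- observables(0.25, st, exo_e2 = 0, exo_p4 = 100, p)
  expect_equal(ob3[["P4"]] - observables(0.25, st, 0, 0, p)[["P4"]], 1)
})

test_that("rhythm-free trajectories match the deSolve oracle over 84 days", {
  p <- oc_test_params()
  off <- circadian_switches(FALSE, FALSE, FALSE, FALSE)
  simC <- simulate_cycle(p, 84, switches = off, out_dt = 0.05,
                         rtol = 1e-9, atol = 1e-9)
  simO <- oracle_simulate(p, 84, dt = 0.05)
  for (v in c("RP_LH", "LH", "FSH", "RcF", "GrF", "DomF", "Lut4", "Inh")) {
    expect_lt(max(abs(simC[[v]] - simO[, v])) / max(abs(simO[, v])), 1e-5)
  }
})

test_that("constant-history bootstrap matches a frozen-lag ODE on [0, tau]", {
  p <- oc_test_params()
  off <- circadian_switches(FALSE, FALSE, FALSE, FALSE)
  tau <- p$baseline$tau
  simC <- simulate_cycle(p, tau * 0.98, switches = off, out_dt = 0.02,
                         rtol = 1e-9, atol = 1e-9)
  # over [0, tau] the delayed inhibin is the constant initial value, so an
  # ODE with the lag frozen at Inh(0) must agree exactly
  lag0 <- unname(p$init[["Inh"]])
  rhs_frozen <- function(t, y, parms) {
    d <- cycle_rhs(t, y, lag0, p, off)
    list(unname(d))
  }
  o <- deSolve::ode(unname(p$init), seq(0, tau * 0.98, 0.02), rhs_frozen,
                    NULL, method = "lsoda", rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(simC$Inh - o[, 13]) / max(o[, 13])), 1e-6)
  expect_lt(max(abs(simC$LH - o[, 3]) / max(o[, 3])), 1e-6)
})

test_that("the drug-free cycle is ovulatory with a 28-day dominant period", {
  p <- oc_test_params()
  sim <- simulate_cycle(p, days = 84, out_dt = 0.02)
  expect_gt(max(sim$P4), 3)          # normal cycle exceeds the threshold
  per <- cycle_period(sim)
  expect_gt(per, 27)
  expect_lt(per, 29)
})

test_that("all state components stay nonnegative over 280 days", {
  p <- oc_test_params()
  sim <- simulate_cycle(p, days = 280, out_dt = 0.05,
                        regimen = constant_regimen(25, 1000, 11, 10))
  states <- as.matrix(sim[, chronOC:::.state_names])
  expect_gt(min(states), -1e-8)
  expect_true(all(sim$E2 > 0) && all(sim$P4 > 0))
})

test_that("halving solver tolerances leaves max P4 unchanged to 0.1%", {
  p <- oc_test_params()
  m1 <- max(simulate_cycle(p, 84, rtol = 1e-8, atol = 1e-8)$P4)
  m2 <- max(simulate_cycle(p, 84, rtol = 5e-9, atol = 5e-9)$P4)
  expect_lt(abs(m1 - m2) / m1, 1e-3)
})

test_that("the synthesis-term modulation has the prescribed daily range", {
  # the daily peak-to-trough range of the modulated synthesis factor is
  # exactly 2*theta1; blood LH inherits a strongly attenuated version of it
  # through the slow reserve-pool turnover, so the propagation check is made
  # on the synthesis factor and the attenuation is verified to be < 1
  p <- oc_test_params()
  th1 <- p$circadian$amplitude[["LH"]]
  tt <- seq(20, 21, by = 1e-3)
  fac <- modulation_factor(tt, th1, p$circadian$acrophase[["LH"]])
  expect_equal(max(fac) - min(fac), 2 * th1, tolerance = 1e-6)
  only_lh <- circadian_switches(TRUE, FALSE, FALSE, FALSE)
  sim <- simulate_cycle(p, 28, switches = only_lh, out_dt = 0.01)
  win <- sim$time >= 20 & sim$time <= 21   # slowly-varying RP_LH window
  lh <- sim$LH[win]
  rel_range <- (max(lh) - min(lh)) / mean(lh)
  expect_gt(rel_range, 0.005)      # the rhythm does propagate
  expect_lt(rel_range, 2 * th1)    # but attenuated below the synthesis range
})

test_that("non-finite states are reported as solver blow-up", {
  p <- oc_test_params()
  st <- p$init
  st[2] <- NaN
  expect_error(cycle_rhs(0, st, 0.3, p), "non-finite")
})
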