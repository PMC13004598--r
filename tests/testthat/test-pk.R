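test_that("closed-form concentration matches the compartment ODE oracle", {
  set.seed(101)
  for (i in 1:20) {
    pk <- random_pk()
    amount <- stats::runif(1, 10, 2000)
    tg <- seq(0, 3, by = 0.02)
    cf <- single_dose_concentration(tg, amount, day_index = 1,
                                    clock_time = 12, pk)
    od <- two_compartment_ode_oracle(tg, amount, t_dose = 12 / 24, pk)
    expect_lt(max(abs(cf - od$conc)), 1e-3 * max(cf))
  }
})

test_that("the tri-exponential coefficients cancel at the dose instant", {
  set.seed(102)
  for (i in 1:100) {
    pk <- random_pk()
    co <- chronOC:::.pk_coefs(pk)
    peak <- max(single_dose_concentration(seq(0.5, 1.5, 0.01), 100, 1, 12, pk))
    expect_lt(abs(sum(co)) * 100, 1e-9 * max(peak, 1e-12) + 1e-9 * abs(co[1]) * 100)
    # concentration exactly at the administration instant is numerically zero
    c0 <- single_dose_concentration(12 / 24, 100, 1, 12, pk)
    expect_lt(abs(c0), 1e-9 * max(peak, abs(co[1]) * 100))
  }
})

test_that("concentration is causal and linear in the dose", {
  set.seed(103)
  pk <- random_pk()
  before <- single_dose_concentration(12 / 24 - 1 / 1440, 500, 1, 12, pk)
  expect_identical(before, 0)
  tg <- seq(0, 5, by = 0.1)
  c1 <- single_dose_concentration(tg, 100, 1, 12, pk)
  c2 <- single_dose_concentration(tg, 200, 1, 12, pk)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  # regimen superposition equals the sum of its single doses
  reg <- oc_regimen(ee = c(rep(10, 5), rep(0, 16)), dng = 0,
                    clock_time = 12, cycles = 1)
  pk_ee <- oc_test_params()$pk$EE
  rc <- regimen_concentration(tg, reg, pk_ee, pk)
  single_sum <- Reduce(`+`, lapply(1:5, function(i)
    single_dose_concentration(tg, 10, i, 12, pk_ee)))
  expect_equal(rc$ee, single_sum, tolerance = 1e-12)
})

test_that("daily dosing approaches a periodic steady state", {
  pk <- oc_test_params()$pk$DNG   # t1/2 well under a day
  reg <- constant_regimen(0, 2000, clock_time = 12, cycles = 1)
  t6 <- seq(5, 6, by = 0.005) + 12 / 24
  t7 <- t6 + 1
  c6 <- regimen_concentration(t6, reg, oc_test_params()$pk$EE, pk)$dng
  c7 <- regimen_concentration(t7, reg, oc_test_params()$pk$EE, pk)$dng
  expect_lt(max(abs(c7 - c6)) / max(c6), 0.01)
  # and matches an independently coded brute-force superposition
  sched <- chronOC:::.dose_schedule(reg, "dng")
  expect_equal(regimen_concentration(t7, reg, oc_test_params()$pk$EE,
                                     pk)$dng,
               brute_conc(t7, sched$times, sched$amounts, pk),
               tolerance = 1e-10)
})

test_that("the oracle conserves drug mass", {
  set.seed(104)
  pk <- random_pk()
  k10 <- pk$alpha1 * pk$beta1 / pk$k21
  od <- two_compartment_ode_oracle(seq(0, 2, by = 0.001), 100, 0, pk)
  total <- od$gut + od$central + od$peripheral
  eliminated <- cumsum(k10 * od$central) * 0.001
  expect_equal(total + eliminated, rep(100 * pk$F, nrow(od)),
               tolerance = 1e-3)
})

test_that("half-life scaling divides the elimination rate", {
  pk <- oc_test_params()$pk$DNG
  hl <- pk_half_life(pk)
  expect_equal(pk_half_life(scale_half_life(pk, 2)), 2 * hl)
  expect_equal(pk_half_life(scale_half_life(pk, 4)), 4 * hl)
  expect_equal(scale_half_life(pk, 1), pk)
  # a factor that pushes beta1 into alpha1 must error (factor < 1 raises it)
  bad_factor <- pk$beta1 / pk$alpha1
  expect_error(scale_half_life(pk, bad_factor), "alpha1|distinct|k21")
})

test_that("degenerate or disordered PK rates are rejected", {
  expect_error(pk_params(Vc = 50, ka = 10, k21 = 2, alpha1 = 10 + 1e-12,
                         beta1 = 1), "distinct")
  expect_error(pk_params(Vc = 50, ka = 10, k21 = 0.5, alpha1 = 4,
                         beta1 = 1), "k21")
  expect_error(pk_params(Vc = 50, ka = 10, k21 = 2, alpha1 = 1,
                         beta1 = 4), "slower|k21")
})

test_that("empty regimens produce zero concentration everywhere", {
  p <- oc_test_params()
  reg <- oc_regimen(0, 0, clock_time = 8, cycles = 2)
  rc <- regimen_concentration(seq(0, 56, 0.5), reg, p$pk$EE, p$pk$DNG)
  expect_true(all(rc$ee == 0) && all(rc$dng == 0))
})
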