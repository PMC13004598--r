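test_that("verdicts are monotone in the threshold and the horizon", {
  p <- oc_test_params()
  reg <- constant_regimen(25, 1000, 11)
  v3 <- evaluate_regimen(reg, p, n_cycles = 3)
  expect_false(evaluate_regimen(reg, p, n_cycles = 3,
                                threshold = Inf)$anovulatory == FALSE)
  # raising the threshold can never flip anovulatory -> ovulatory
  v_hi <- evaluate_regimen(reg, p, n_cycles = 3, threshold = v3$max_p4 + 1)
  expect_true(v_hi$anovulatory)
  expect_identical(v_hi$max_p4, v3$max_p4)
  # max P4 over more cycles dominates max P4 over fewer
  v1 <- evaluate_regimen(reg, p, n_cycles = 1)
  expect_gte(v3$max_p4, v1$max_p4 - 1e-9)
})

test_that("the zero-dose verdict equals the drug-free simulation", {
  p <- oc_test_params()
  v <- evaluate_regimen(constant_regimen(0, 0, 11), p, n_cycles = 3)
  free <- simulate_cycle(p, 84)
  expect_false(v$anovulatory)
  expect_equal(v$max_p4, max(free$P4), tolerance = 1e-9)
})

test_that("dose-grid cells agree with individual verdicts", {
  p <- oc_test_params()
  g <- dose_grid(11, p, n_cycles = 1, ee_axis = c(0, 30),
                 dng_axis = c(0, 2000))
  v00 <- evaluate_regimen(constant_regimen(0, 0, 11), p, n_cycles = 1)
  expect_equal(g$max_p4["0", "0"], v00$max_p4)
  v3 <- evaluate_regimen(constant_regimen(30, 2000, 11), p, n_cycles = 1)
  expect_equal(g$max_p4["30", "2000"], v3$max_p4)
  # checkpointing restores a finished grid without recomputation
  ck <- tempfile(fileext = ".csv")
  g1 <- dose_grid(11, p, n_cycles = 1, ee_axis = c(0, 30),
                  dng_axis = c(0, 2000), checkpoint = ck)
  g2 <- dose_grid(11, p, n_cycles = 1, ee_axis = c(0, 30),
                  dng_axis = c(0, 2000), checkpoint = ck)
  expect_equal(g1$max_p4, g2$max_p4)
})

test_that("minimal-dose search returns an admissible frontier point", {
  p <- oc_test_params()
  r <- minimal_constant_dose(11, p, n_cycles = 1,
                             ee_axis = seq(0, 30, 6),
                             dng_axis = seq(0, 2000, 400))
  expect_true(r$achievable)
  v <- evaluate_regimen(constant_regimen(r$ee_daily, r$dng_daily, 11), p,
                        n_cycles = 1)
  expect_true(v$anovulatory)
  expect_equal(r$total_ee, 21 * r$ee_daily)
  # an infinite threshold makes the origin admissible
  r0 <- minimal_constant_dose(11, p, n_cycles = 1,
                              ee_axis = seq(0, 30, 6),
                              dng_axis = seq(0, 2000, 400),
                              threshold = Inf)
  expect_equal(c(r0$ee_daily, r0$dng_daily), c(0, 0))
})

test_that("half-life sensitivity scales DNG elimination as prescribed", {
  p <- oc_test_params()
  expect_equal(pk_half_life(p$pk$DNG), 9.5, tolerance = 1e-6)
  out <- sensitivity_half_life(p, factors = c(1, 2), times = 11,
                               n_cycles = 1, coarse = TRUE)
  expect_equal(out$half_life_h[out$factor == 2], 19, tolerance = 1e-6)
  base <- minimal_constant_dose(11, p, n_cycles = 1,
                                ee_axis = chronOC:::.coarse_ee_axis(),
                                dng_axis = chronOC:::.coarse_dng_axis())
  expect_equal(out$ee_daily[out$factor == 1], base$ee_daily)
})

test_that("central-volume perturbation rescales concentrations exactly", {
  p <- oc_test_params()
  pp <- p
  vals <- unclass(p$pk$EE)
  vals$Vc <- vals$Vc * 1.3
  pp$pk$EE <- do.call(pk_params, vals[c("Vc", "ka", "k21", "alpha1",
                                        "beta1", "F", "conc_scale",
                                        "drug")])
  tt <- seq(0, 3, 0.05)
  reg <- constant_regimen(30, 0, 11)
  c0 <- regimen_concentration(tt, reg, p$pk$EE, p$pk$DNG)$ee
  c1 <- regimen_concentration(tt, reg, pp$pk$EE, pp$pk$DNG)$ee
  expect_equal(c1, c0 / 1.3, tolerance = 1e-12)
})

test_that("cycle-length scaling rescales the drug-free period", {
  p <- oc_test_params()
  out <- sensitivity_cycle_length(p, scales = c(0.9333, 1, 1.0985),
                                  times = 11, n_cycles = 1, coarse = TRUE)
  len <- out$cycle_length[match(c(0.9333, 1, 1.0985), out$scale)]
  expect_equal(len[2], 28, tolerance = 0.5)
  # larger rate scale -> faster dynamics -> shorter cycle, monotonically
  expect_true(len[1] > len[2] && len[2] > len[3])
  # the scaled parameters act nearly as a pure change of time units
  expect_equal(len[1], 28 / 0.9333, tolerance = 1)
  expect_equal(len[3], 28 / 1.0985, tolerance = 1)
})

test_that("removing the LH rhythm collapses the dosing-time contrast most", {
  p <- oc_test_params()
  ab <- rhythm_ablation(p, ee = 28.2, dng = 320, n_cycles = 3,
                        rtol = 1e-7, atol = 1e-7)
  expect_identical(ab$ranking$ablated[1], "LH")
  none <- ab$table[ab$table$ablated == "none", ]
  expect_equal(none$max_p4_day,
               evaluate_regimen(constant_regimen(28.2, 320, 11), p, 3,
                                rtol = 1e-7, atol = 1e-7)$max_p4,
               tolerance = 1e-9)
  # with all rhythms removed only PK timing remains: contrast nearly gone
  allr <- ab$table[ab$table$ablated == "all", ]
  expect_lt(abs(allr$diff), 0.25 * abs(none$diff))
})
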