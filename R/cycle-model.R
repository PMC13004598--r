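#' Circadian modulation factor
#'
#' The multiplicative factor `1 + amplitude * cos(2*pi*(t - acrophase))`
#' applied to hormone synthesis/output terms. Period is exactly one day;
#' the factor averages to 1 over any whole day.
#'
#' @param t Time in days.
#' @param amplitude Dimensionless amplitude, `>= 0`.
#' @param acrophase Acrophase in days (time of daily maximum).
#' @return Numeric factor(s).
#' @export
modulation_factor <- function(t, amplitude, acrophase) {
  stopifnot(all(amplitude >= 0))
  1 + amplitude * cos(2 * pi * (t - acrophase))
}

#' Right-hand side of the menstrual-cycle DDE
#'
#' Time derivative of the 12-component state (pituitary LH/FSH reserve and
#' blood pools, three follicular and four luteal stage masses, inhibin). The
#' circadian cosine multiplies only the synthesis terms of `RP_LH` and
#' `RP_FSH`; circadian modulation of E2 and P4 enters through the algebraic
#' observables, which feed back into every regulation term together with the
#' RBA-scaled exogenous concentrations.
#'
#' @param t Time (days).
#' @param state Named or positional numeric state vector (length 12, order
#'   `RP_LH, LH, RP_FSH, FSH, RcF, GrF, DomF, Lut1..Lut4, Inh`).
#' @param delayed_inh Value of `Inh` at `t - tau`.
#' @param params An `oc_params` bundle.
#' @param switches An `oc_switches` object.
#' @param exo_e2 Exogenous EE concentration at `t` (pg/mL).
#' @param exo_p4 Exogenous DNG concentration at `t` (ng/mL).
#' @return Named numeric vector of derivatives.
#' @export
cycle_rhs <- function(t, state, delayed_inh, params,
                      switches = circadian_switches(),
                      exo_e2 = 0, exo_p4 = 0) {
  stopifnot(inherits(params, "oc_params"))
  if (any(!is.finite(state)))
    stop("non-finite state: solver blow-up at t = ", t)
  eff <- .eff_circadian(params$circadian, switches)
  dy <- cpp_cycle_rhs(t, as.numeric(state), delayed_inh, .param_vec(params),
                      eff$amp, eff$phase, exo_e2, exo_p4)
  stats::setNames(dy, .state_names)
}

#' Hormone observables E2 and P4
#'
#' Algebraic blood-hormone outputs: the endogenous part (linear in the
#' follicular/luteal stage masses) times its circadian factor, plus the
#' RBA-weighted exogenous concentration (`r1` for EE, `r2` for DNG).
#'
#' @inheritParams cycle_rhs
#' @return Named numeric vector `c(E2, P4)` (pg/mL and ng/mL).
#' @export
observables <- function(t, state, exo_e2 = 0, exo_p4 = 0, params,
                        switches = circadian_switches()) {
  stopifnot(inherits(params, "oc_params"))
  b <- params$baseline
  eff <- .eff_circadian(params$circadian, switches)
  st <- stats::setNames(as.numeric(state), .state_names)
  e2 <- (b$e0 + b$e1 * st[["GrF"]] + b$e2 * st[["DomF"]] +
         b$e3 * st[["Lut4"]]) *
    modulation_factor(t, eff$amp[3], eff$phase[3]) + params$rba$r1 * exo_e2
  p4 <- (b$p0 + b$p1 * st[["Lut3"]] + b$p2 * st[["Lut4"]]) *
    modulation_factor(t, eff$amp[4], eff$phase[4]) + params$rba$r2 * exo_p4
  c(E2 = unname(e2), P4 = unname(p4))
}

#' Simulate the circadian menstrual-cycle model
#'
#' Integrates the DDE system by the method of steps (single constant inhibin
#' delay, constant history equal to the day-0 initial conditions) with an
#' adaptive Dormand-Prince 5(4) scheme, cubic-Hermite interpolation of the
#' stored inhibin history, maximum step 0.05 day, and dense output.
#'
#' @param params An `oc_params` bundle (must carry file provenance; see
#'   [load_oc_params()]).
#' @param days Simulation horizon in days from `t0`.
#' @param regimen Optional `oc_regimen` supplying EE/DNG doses; `NULL` for a
#'   drug-free run.
#' @param switches Circadian switches.
#' @param init Optional initial state (defaults to the packaged day-0
#'   conditions in `params`).
#' @param t0 Start time (days).
#' @param out_dt Dense-output resolution (days).
#' @param rtol,atol Relative/absolute local error tolerances.
#' @param max_step Maximum step size (days); must resolve the daily cosine.
#' @return An object of class `oc_sim`: a data.frame with `time`, the 12
#'   state columns, `E2`, `P4`, `ee_conc`, `dng_conc`, with run metadata in
#'   attributes (`params_checksum`, `switches`, `tolerances`, `regimen`).
#' @export
simulate_cycle <- function(params, days = 84, regimen = NULL,
                           switches = circadian_switches(), init = NULL,
                           t0 = 0, out_dt = 0.01, rtol = 1e-8, atol = 1e-8,
                           max_step = 0.05) {
  stopifnot(inherits(params, "oc_params"))
  if (is.null(params$meta$source_file) || is.null(params$meta$checksum))
    stop("refusing to simulate: parameter bundle lacks file provenance")
  if (days <= 0) stop("days must be positive")
  y0 <- if (is.null(init)) params$init else {
    stopifnot(length(init) == 12L)
    stats::setNames(as.numeric(init), .state_names)
  }
  if (any(y0 < 0)) stop("initial state must be nonnegative")
  eff <- .eff_circadian(params$circadian, switches)
  if (is.null(regimen)) {
    se <- list(times = numeric(0), amounts = numeric(0))
    sdng <- se
  } else {
    stopifnot(inherits(regimen, "oc_regimen"))
    se <- .dose_schedule(regimen, "ee")
    sdng <- .dose_schedule(regimen, "dng")
  }
  ce <- .pk_coefs(params$pk$EE)
  cd <- .pk_coefs(params$pk$DNG)
  pk_ee <- c(params$pk$EE$ka, params$pk$EE$alpha1, params$pk$EE$beta1, ce)
  pk_dng <- c(params$pk$DNG$ka, params$pk$DNG$alpha1, params$pk$DNG$beta1, cd)
  res <- cpp_simulate(unname(y0), t0, t0 + days, .param_vec(params),
                      eff$amp, eff$phase,
                      se$times, se$amounts, pk_ee,
                      sdng$times, sdng$amounts, pk_dng,
                      out_dt, rtol, atol, max_step)
  st <- res$state
  colnames(st) <- .state_names
  tm <- res$time
  ee_conc <- cpp_pk_conc(tm, se$times, se$amounts, params$pk$EE$ka,
                         params$pk$EE$alpha1, params$pk$EE$beta1,
                         ce[["N"]], ce[["L"]], ce[["M"]])
  dng_conc <- cpp_pk_conc(tm, sdng$times, sdng$amounts, params$pk$DNG$ka,
                          params$pk$DNG$alpha1, params$pk$DNG$beta1,
                          cd[["N"]], cd[["L"]], cd[["M"]])
  fE2 <- modulation_factor(tm, eff$amp[3], eff$phase[3])
  fP4 <- modulation_factor(tm, eff$amp[4], eff$phase[4])
  b <- params$baseline
  E2 <- (b$e0 + b$e1 * st[, "GrF"] + b$e2 * st[, "DomF"] +
         b$e3 * st[, "Lut4"]) * fE2 + params$rba$r1 * ee_conc
  P4 <- (b$p0 + b$p1 * st[, "Lut3"] + b$p2 * st[, "Lut4"]) * fP4 +
    params$rba$r2 * dng_conc
  out <- data.frame(time = tm, st, E2 = E2, P4 = P4,
                    ee_conc = ee_conc, dng_conc = dng_conc)
  attr(out, "params_checksum") <- params$meta$checksum
  attr(out, "switches") <- switches
  attr(out, "tolerances") <- c(rtol = rtol, atol = atol,
                               max_step = max_step, out_dt = out_dt)
  attr(out, "regimen") <- regimen
  attr(out, "n_steps") <- res$n_steps
  class(out) <- c("oc_sim", "data.frame")
  out
}

#' Maximum progesterone of a simulated trajectory
#'
#' @param sim An `oc_sim` trajectory.
#' @param from Ignore output before this time (days).
#' @return List with `max_p4` (ng/mL) and `time_of_max` (days).
#' @export
max_p4 <- function(sim, from = 0) {
  stopifnot(inherits(sim, "oc_sim"))
  sel <- sim$time >= from
  i <- which.max(sim$P4[sel])
  list(max_p4 = sim$P4[sel][i], time_of_max = sim$time[sel][i])
}

#' Write a trajectory and its run metadata to disk
#'
#' CSV of the dense trajectory plus a JSON sidecar recording tolerances, the
#' parameter-file checksum and the circadian switches.
#'
#' @param sim An `oc_sim` trajectory.
#' @param prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>_meta.json`.
#' @return `prefix`, invisibly.
#' @export
write_trajectory <- function(sim, prefix) {
  stopifnot(inherits(sim, "oc_sim"))
  utils::write.csv(as.data.frame(sim), paste0(prefix, ".csv"),
                   row.names = FALSE)
  meta <- list(params_checksum = attr(sim, "params_checksum"),
               tolerances = as.list(attr(sim, "tolerances")),
               switches = as.list(attr(sim, "switches")))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
             paste0(prefix, "_meta.json"))
  invisible(prefix)
}

#' Dominant cycle period by autocorrelation
#'
#' Estimates the dominant period of a drug-free trajectory from the first
#' off-zero maximum of the autocorrelation of daily-sampled P4.
#'
#' @param sim An `oc_sim` trajectory spanning at least two cycles.
#' @param var Column to analyse (default `"P4"`).
#' @return Period in days.
#' @export
cycle_period <- function(sim, var = "P4") {
  stopifnot(inherits(sim, "oc_sim"))
  dt <- 0.1
  tt <- seq(min(sim$time), max(sim$time), by = dt)
  x <- stats::approx(sim$time, sim[[var]], tt)$y
  x <- x - mean(x)
  ac <- stats::acf(x, lag.max = round(40 / dt), plot = FALSE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1
  win <- lags * dt >= 15 & lags * dt <= 40
  lags[win][which.max(ac[win])] * dt
}
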