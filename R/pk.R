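#' Two-compartment oral pharmacokinetic parameters
#'
#' Parameters of the closed-form tri-exponential concentration profile after
#' an oral dose: bioavailability `F`, apparent central volume `Vc` (litres),
#' absorption rate `ka`, peripheral-to-central transfer rate `k21`, and the
#' distribution/elimination hybrid rates `alpha1` and `beta1` (all rates per
#' day). Because oral data identify only `F/Vc`, `F` is fixed at 1 by
#' convention and `Vc` is the apparent volume `Vc/F`. The rates must be
#' pairwise distinct (the partial-fraction closed form is undefined at
#' coincident rates) and ordered `beta1 < k21 < alpha1 < ka` — elimination
#' slower than distribution, with `k21` interlaced between the hybrid rates
#' as required for a positive underlying compartment model.
#'
#' @param F Bioavailability (dimensionless, fixed at 1 by convention).
#' @param Vc Apparent central volume (L).
#' @param ka Absorption rate constant (1/day).
#' @param k21 Peripheral-to-central transfer rate (1/day).
#' @param alpha1 Distribution-phase hybrid rate (1/day).
#' @param beta1 Elimination-phase hybrid rate (1/day).
#' @param conc_scale Multiplier from ug/L to the drug's reporting unit
#'   (1000 for EE so concentrations are in pg/mL; 1 for DNG, ng/mL).
#' @param drug Drug label, `"EE"` or `"DNG"`.
#' @return An object of class `oc_pk`.
#' @export
pk_params <- function(Vc, ka, k21, alpha1, beta1, F = 1, conc_scale = 1,
                      drug = c("EE", "DNG")) {
  drug <- match.arg(drug)
  vals <- c(F = as.numeric(F)[1], Vc = as.numeric(Vc)[1],
            ka = as.numeric(ka)[1], k21 = as.numeric(k21)[1],
            alpha1 = as.numeric(alpha1)[1], beta1 = as.numeric(beta1)[1],
            conc_scale = as.numeric(conc_scale)[1])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all PK parameters must be positive and finite")
  rates <- c(ka = ka, alpha1 = alpha1, beta1 = beta1)
  gaps <- abs(c(ka - alpha1, ka - beta1, alpha1 - beta1))
  if (any(gaps < 1e-8 * max(rates)))
    stop("degenerate PK rates: ka, alpha1, beta1 must be pairwise distinct")
  if (!(beta1 < alpha1))
    stop("elimination must be slower than distribution (beta1 < alpha1)")
  if (!(beta1 < k21 && k21 < alpha1))
    stop("k21 must lie strictly between beta1 and alpha1")
  structure(as.list(c(vals, list(drug = drug))), class = "oc_pk")
}

# per-unit-dose partial-fraction coefficients N, L, M (in reporting units)
.pk_coefs <- function(pk) {
  with(pk, {
    N <- ka * F * (k21 - ka) / (Vc * (alpha1 - ka) * (beta1 - ka))
    L <- ka * F * (k21 - alpha1) / (Vc * (ka - alpha1) * (beta1 - alpha1))
    M <- ka * F * (k21 - beta1) / (Vc * (ka - beta1) * (alpha1 - beta1))
    c(N = N, L = L, M = M) * conc_scale
  })
}

#' Elimination half-life of a PK parameter set
#'
#' @param pk An `oc_pk` object.
#' @return Terminal half-life `ln(2)/beta1`, in hours.
#' @export
pk_half_life <- function(pk) {
  stopifnot(inherits(pk, "oc_pk"))
  24 * log(2) / pk$beta1
}

#' Scale the elimination half-life of a drug
#'
#' Returns a copy of `pk` with the elimination rate `beta1` divided by
#' `factor`, i.e. the terminal half-life multiplied by `factor`. Errors if
#' the scaled rate collides with (or crosses) the other rates.
#'
#' @param pk An `oc_pk` object.
#' @param factor Positive multiplier for the half-life.
#' @return A new `oc_pk` object.
#' @export
scale_half_life <- function(pk, factor) {
  stopifnot(inherits(pk, "oc_pk"), is.numeric(factor), factor > 0)
  out <- unclass(pk)
  out$beta1 <- pk$beta1 / factor
  do.call(pk_params, out)
}

#' Single-dose concentration from the closed form
#'
#' Tri-exponential concentration at times `t` (model days) after a dose of
#' `amount` micrograms given at clock time `clock_time` (hours) on day
#' `day_index` (1-based) of cycle `cycle` (0-based), i.e. at model time
#' `28*cycle + (day_index - 1) + clock_time/24`. Zero strictly before the
#' administration instant.
#'
#' @param t Numeric vector of model times (days).
#' @param amount Dose (ug).
#' @param day_index Day of the cycle, integer >= 1.
#' @param clock_time Clock dosing time in hours, in `[1, 24]`.
#' @param pk An `oc_pk` object.
#' @param cycle 0-based cycle index.
#' @return Concentrations in the drug's reporting unit (pg/mL for EE,
#'   ng/mL for DNG).
#' @export
single_dose_concentration <- function(t, amount, day_index, clock_time, pk,
                                      cycle = 0) {
  stopifnot(inherits(pk, "oc_pk"), amount >= 0, day_index >= 1)
  t_dose <- 28 * cycle + (day_index - 1) + clock_time / 24
  co <- .pk_coefs(pk)
  cpp_pk_conc(as.numeric(t), t_dose, amount, pk$ka, pk$alpha1, pk$beta1,
              co[["N"]], co[["L"]], co[["M"]])
}

#' Construct a 28-day-cycle dosing regimen
#'
#' A regimen is 21 daily EE/DNG doses followed by a 7-day drug-free break,
#' all administered at one clock time, repeated for `cycles` cycles.
#'
#' @param ee Daily EE amounts (ug): scalar or length-21 vector, each in
#'   `[0, 30]`.
#' @param dng Daily DNG amounts (ug): scalar or length-21 vector, each in
#'   `[0, 2000]`.
#' @param clock_time Clock dosing time (hours), in `[1, 24]`.
#' @param cycles Number of repeated 28-day cycles.
#' @return An object of class `oc_regimen`.
#' @export
oc_regimen <- function(ee = 0, dng = 0, clock_time = 11, cycles = 1) {
  if (length(ee) == 1L) ee <- rep(ee, 21)
  if (length(dng) == 1L) dng <- rep(dng, 21)
  stopifnot(length(ee) == 21L, length(dng) == 21L,
            clock_time >= 1, clock_time <= 24, cycles >= 1)
  if (any(ee < 0) || any(dng < 0))
    stop("doses must be nonnegative")
  if (any(ee > 30 + 1e-9) || any(dng > 2000 + 1e-9))
    stop("doses exceed the market-dose box (30 ug EE, 2000 ug DNG)")
  structure(list(ee = as.numeric(ee), dng = as.numeric(dng),
                 clock_time = as.numeric(clock_time),
                 cycles = as.integer(cycles)),
            class = "oc_regimen")
}

#' @rdname oc_regimen
#' @export
constant_regimen <- function(ee, dng, clock_time = 11, cycles = 1) {
  oc_regimen(rep(ee, 21), rep(dng, 21), clock_time, cycles)
}

#' @export
print.oc_regimen <- function(x, ...) {
  cat(sprintf("<oc_regimen> %d cycle(s) at %02d:00 | total EE %.2f ug, total DNG %.1f ug/cycle\n",
              x$cycles, round(x$clock_time), sum(x$ee), sum(x$dng)))
  invisible(x)
}

# dose schedule (times in model days, amounts in ug) for one drug
.dose_schedule <- function(regimen, drug = c("ee", "dng")) {
  drug <- match.arg(drug)
  amounts <- regimen[[drug]]
  keep <- which(amounts > 0)
  if (!length(keep))
    return(list(times = numeric(0), amounts = numeric(0)))
  t1 <- outer(keep - 1, 28 * (seq_len(regimen$cycles) - 1), "+") +
    regimen$clock_time / 24
  list(times = as.numeric(t1)[order(as.numeric(t1))],
       amounts = rep(amounts[keep], regimen$cycles)[order(as.numeric(t1))])
}

#' Exogenous-hormone concentrations under a regimen
#'
#' Superposes the closed-form concentration of every administered dose
#' (all elapsed cycles, no wash-out truncation) to give the exogenous EE and
#' DNG concentrations at the requested times.
#'
#' @param t Numeric vector of model times (days).
#' @param regimen An `oc_regimen`.
#' @param pk_ee,pk_dng `oc_pk` parameter sets for EE and DNG.
#' @return A data.frame with columns `time`, `ee` (pg/mL), `dng` (ng/mL).
#' @export
regimen_concentration <- function(t, regimen, pk_ee, pk_dng) {
  stopifnot(inherits(regimen, "oc_regimen"))
  se <- .dose_schedule(regimen, "ee")
  sd_ <- .dose_schedule(regimen, "dng")
  ce <- .pk_coefs(pk_ee); cd <- .pk_coefs(pk_dng)
  data.frame(
    time = t,
    ee = cpp_pk_conc(t, se$times, se$amounts, pk_ee$ka, pk_ee$alpha1,
                     pk_ee$beta1, ce[["N"]], ce[["L"]], ce[["M"]]),
    dng = cpp_pk_conc(t, sd_$times, sd_$amounts, pk_dng$ka, pk_dng$alpha1,
                      pk_dng$beta1, cd[["N"]], cd[["L"]], cd[["M"]])
  )
}

#' Numerical two-compartment oracle for the closed form
#'
#' Integrates the gut/central/peripheral ODE system whose hybrid rates are
#' `alpha1` and `beta1` and returns the central-compartment concentration.
#' This is a validation oracle for [single_dose_concentration()]; it is not
#' used by any simulation path. The micro rate constants are recovered from
#' the hybrid rates as `k10 = alpha1*beta1/k21` and
#' `k12 = alpha1 + beta1 - k21 - k10`.
#'
#' @param t_grid Output times (model days), starting at or after 0.
#' @param amount Dose (ug) given at time `t_dose`.
#' @param t_dose Administration time (model days).
#' @param pk An `oc_pk` object.
#' @return A data.frame with `time`, `conc` (reporting units), and the three
#'   compartment amounts (`gut`, `central`, `peripheral`, ug).
#' @export
two_compartment_ode_oracle <- function(t_grid, amount, t_dose, pk) {
  stopifnot(inherits(pk, "oc_pk"))
  k10 <- pk$alpha1 * pk$beta1 / pk$k21
  k12 <- pk$alpha1 + pk$beta1 - pk$k21 - k10
  if (k12 <= 0) stop("inconsistent hybrid rates: k12 <= 0")
  deriv <- function(t, y, parms) {
    list(c(-pk$ka * y[1],
           pk$ka * y[1] - (k10 + k12) * y[2] + pk$k21 * y[3],
           k12 * y[2] - pk$k21 * y[3]))
  }
  pre <- t_grid[t_grid < t_dose]
  post <- t_grid[t_grid >= t_dose]
  out <- NULL
  if (length(post)) {
    times <- unique(c(t_dose, post))
    sol <- deSolve::ode(c(gut = pk$F * amount, central = 0, peripheral = 0),
                        times, deriv, NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    sol <- sol[sol[, "time"] %in% post, , drop = FALSE]
    out <- data.frame(time = sol[, "time"], gut = sol[, "gut"],
                      central = sol[, "central"],
                      peripheral = sol[, "peripheral"])
  }
  if (length(pre)) {
    out <- rbind(data.frame(time = pre, gut = 0, central = 0, peripheral = 0),
                 out)
  }
  out$conc <- out$central / pk$Vc * pk$conc_scale
  out[order(out$time), c("time", "conc", "gut", "central", "peripheral")]
}
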