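#' Generate a synthetic circadian hormone series
#'
#' Emulates a digitized 24-h hormone rhythm measured during the follicular
#' phase (hourly samples post-wake, wake at 07:00): values are
#' `mean * (1 + a*cos(2*pi*(t - b))) * (1 + eps)` with multiplicative
#' Gaussian noise `eps ~ N(0, sd^2)`, seeded and replayable. The ground
#' truth is returned alongside so recovery tests never regenerate it.
#'
#' @param hormone Label (`"LH"`, `"FSH"`, `"E2"`, `"P4"`).
#' @param mean_level Mean hormone level (assay units).
#' @param amplitude Relative circadian amplitude `a`, in `[0, 0.5]`.
#' @param acrophase Acrophase `b` in days (clock time / 24).
#' @param noise_sd Relative noise standard deviation (default 5%).
#' @param times Sample clock times in hours (default hourly over 24 h
#'   post-wake, wake 07:00).
#' @param seed Integer seed.
#' @return List with `series` (data.frame `time` in clock hours, `value`,
#'   `hormone`, `provenance`) and `truth` (list `a`, `b`, `mean`, `sd`,
#'   `seed`).
#' @export
gen_circadian_series <- function(hormone, mean_level, amplitude, acrophase,
                                 noise_sd = 0.05,
                                 times = 7 + 0:23, seed = 1) {
  stopifnot(amplitude >= 0, amplitude <= 0.5, noise_sd >= 0,
            mean_level > 0)
  td <- times / 24
  eps <- .with_local_seed(seed, stats::rnorm(length(times), 0, noise_sd))
  value <- mean_level * (1 + amplitude * cos(2 * pi * (td - acrophase))) *
    (1 + eps)
  list(series = data.frame(time = times, value = value, hormone = hormone,
                           provenance = "synthetic"),
       truth = list(hormone = hormone, a = amplitude, b = acrophase,
                    mean = mean_level, sd = noise_sd, seed = seed))
}

#' Generate a synthetic post-dose drug concentration series
#'
#' Emulates a digitized 24-h concentration profile after the `n_doses`-th
#' daily dose: superposed closed-form two-compartment concentrations with
#' multiplicative Gaussian noise, seeded. Default sampling follows standard
#' PK blood-draw schedules.
#'
#' @param pk Ground-truth `oc_pk` parameters.
#' @param dose Daily dose (ug); defaults to the market dose for the drug.
#' @param n_doses Number of daily doses received (default 7).
#' @param noise_sd Relative noise sd (default 3%).
#' @param times Sampling times in hours after the last dose.
#' @param seed Integer seed.
#' @return List with `series` (data.frame `time` hours post-dose, `conc`,
#'   `drug`, `provenance`) and `truth`.
#' @export
gen_pk_series <- function(pk, dose = c(EE = 30, DNG = 2000)[[pk$drug]],
                          n_doses = 7, noise_sd = 0.03,
                          times = c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12,
                                    16, 20, 24),
                          seed = 1) {
  stopifnot(inherits(pk, "oc_pk"), noise_sd >= 0, dose > 0)
  clean <- .multi_dose_conc((n_doses - 1) + 1 + times / 24, dose, 24,
                            n_doses, pk)
  conc <- clean * (1 + .with_local_seed(seed,
                                        stats::rnorm(length(times), 0,
                                                     noise_sd)))
  list(series = data.frame(time = times, conc = conc, drug = pk$drug,
                           provenance = "synthetic"),
       truth = list(pk = pk, dose = dose, n_doses = n_doses, sd = noise_sd,
                    seed = seed))
}

#' Find a relapse-prone constant regimen
#'
#' Searches near the anovulation boundary at the given (evening) dosing time
#' for a constant regimen that stays below the P4 threshold in its first
#' cycle but breaks through in a later cycle — the behaviour used to test
#' that long-horizon confirmation rejects short-horizon winners.
#'
#' @param params An `oc_params` bundle.
#' @param clock_time Dosing time (hours), default 22.
#' @param n_cycles Long horizon to test against (default 10).
#' @param ee_grid Candidate daily EE doses (ug), scanned in order.
#' @param dng Daily DNG dose (ug) held fixed.
#' @return List with `regimen` (an `oc_regimen`, `n_cycles` cycles),
#'   `verdict_1cycle`, `verdict_long`, or `NULL` if no candidate qualifies.
#' @export
gen_relapse_regimen <- function(params, clock_time = 22, n_cycles = 10,
                                ee_grid = seq(30, 15, by = -0.6),
                                dng = 1000) {
  stopifnot(inherits(params, "oc_params"))
  for (ee in ee_grid) {
    reg <- constant_regimen(ee, dng, clock_time, cycles = n_cycles)
    one <- evaluate_regimen(reg, params, n_cycles = 1)
    if (!one$anovulatory) next
    long <- evaluate_regimen(reg, params, n_cycles = n_cycles)
    if (!long$anovulatory) {
      return(list(regimen = reg, verdict_1cycle = one,
                  verdict_long = long))
    }
  }
  NULL
}

#' Toy two-objective problem with an analytic Pareto front
#'
#' A box-constrained bi-objective benchmark (Schaffer-type, generalized to
#' `n` variables): `f1 = mean(x^2)`, `f2 = mean((x - 2)^2)` on `[-1, 3]^n`.
#' The Pareto set is `x1 = ... = xn = s`, `s` in `[0, 2]`, giving the
#' closed-form front `f2 = (sqrt(f1) - 2)^2` for `f1` in `[0, 4]`.
#'
#' @param n Number of decision variables.
#' @return List with `fn(x)` returning `c(f1, f2)`, `lower`, `upper`,
#'   `true_front(n_pts)` returning the analytic front, and
#'   `true_hypervolume(ref)` (exact, for reference point `ref`).
#' @export
gen_toy_moo_problem <- function(n = 6) {
  fn <- function(x) c(mean(x^2), mean((x - 2)^2))
  true_front <- function(n_pts = 201) {
    s <- seq(0, 2, length.out = n_pts)
    cbind(f1 = s^2, f2 = (s - 2)^2)
  }
  true_hypervolume <- function(ref = c(4.5, 4.5)) {
    # HV of {(s^2, (2-s)^2): s in [0,2]} w.r.t. ref: the area between the
    # curve and the reference corner, plus the strip beyond f1 = 4 that the
    # front endpoint (4, 0) dominates
    f <- function(u) (ref[2] - (2 - sqrt(u))^2)
    stats::integrate(f, 0, min(4, ref[1]), rel.tol = 1e-10)$value +
      max(0, ref[1] - 4) * ref[2]
  }
  list(fn = fn, lower = rep(-1, n), upper = rep(3, n),
       true_front = true_front, true_hypervolume = true_hypervolume)
}
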