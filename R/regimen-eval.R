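#' Evaluate a regimen's anovulation verdict
#'
#' Simulates `n_cycles` 28-day cycles from the packaged day-0 conditions
#' with the regimen repeated each cycle and extracts the maximum P4 from the
#' dense output. A regimen is anovulatory iff max P4 stays strictly below
#' the threshold (default 3 ng/mL).
#'
#' @param regimen An `oc_regimen` (its `cycles` field is overridden by
#'   `n_cycles`).
#' @param params An `oc_params` bundle.
#' @param n_cycles Simulation horizon in cycles (default 10, i.e. 280 days).
#' @param switches Circadian switches.
#' @param threshold Anovulation threshold (ng/mL); defaults to the bundled
#'   value.
#' @param ... Passed to [simulate_cycle()] (tolerances etc.).
#' @return List of class `oc_verdict`: `max_p4`, `time_of_max`,
#'   `horizon_cycles`, `anovulatory`, `threshold`.
#' @export
evaluate_regimen <- function(regimen, params, n_cycles = 10,
                             switches = circadian_switches(),
                             threshold = params$threshold, ...) {
  stopifnot(inherits(regimen, "oc_regimen"), n_cycles >= 1)
  reg <- regimen
  reg$cycles <- as.integer(n_cycles)
  sim <- simulate_cycle(params, days = 28 * n_cycles, regimen = reg,
                        switches = switches, ...)
  m <- max_p4(sim)
  structure(list(max_p4 = m$max_p4, time_of_max = m$time_of_max,
                 horizon_cycles = n_cycles,
                 anovulatory = m$max_p4 < threshold, threshold = threshold),
            class = "oc_verdict")
}

#' Per-cycle maximum P4 of a regimen
#'
#' @inheritParams evaluate_regimen
#' @return Numeric vector of length `n_cycles`: max P4 within each cycle.
#' @export
per_cycle_max_p4 <- function(regimen, params, n_cycles = 3,
                             switches = circadian_switches(), ...) {
  reg <- regimen
  reg$cycles <- as.integer(n_cycles)
  sim <- simulate_cycle(params, days = 28 * n_cycles, regimen = reg,
                        switches = switches, ...)
  vapply(seq_len(n_cycles), function(cyc) {
    sel <- sim$time >= 28 * (cyc - 1) & sim$time < 28 * cyc
    max(sim$P4[sel])
  }, 0)
}

.default_ee_axis <- function() seq(0, 30, by = 0.6)
.default_dng_axis <- function() seq(0, 2000, by = 40)
.coarse_ee_axis <- function() seq(0, 30, by = 6)
.coarse_dng_axis <- function() seq(0, 2000, by = 400)

#' Max-P4 dose grid at one dosing time
#'
#' Evaluates max P4 over the horizon for every (EE, DNG) daily-dose
#' combination on the grid. Cells are independent; a checkpoint file makes
#' long runs resumable.
#'
#' @param dosing_time Clock dosing time (hours, 1-24).
#' @param params An `oc_params` bundle.
#' @param n_cycles Horizon (default 10).
#' @param ee_axis,dng_axis Dose axes (ug/day); defaults are the 51-point
#'   axes 0-30 by 0.6 and 0-2000 by 40.
#' @param switches Circadian switches.
#' @param checkpoint Optional path to a CSV checkpoint, written after each
#'   EE row and read back on restart.
#' @param ... Passed to [simulate_cycle()].
#' @return An object of class `oc_dose_grid`: list with `max_p4` (matrix,
#'   rows = EE axis, cols = DNG axis), the axes, `dosing_time`, `n_cycles`.
#' @export
dose_grid <- function(dosing_time, params, n_cycles = 10,
                      ee_axis = .default_ee_axis(),
                      dng_axis = .default_dng_axis(),
                      switches = circadian_switches(),
                      checkpoint = NULL, ...) {
  stopifnot(dosing_time >= 1, dosing_time <= 24)
  M <- matrix(NA_real_, length(ee_axis), length(dng_axis),
              dimnames = list(ee = ee_axis, dng = dng_axis))
  done <- rep(FALSE, length(ee_axis))
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    prev <- as.matrix(utils::read.csv(checkpoint, row.names = 1,
                                      check.names = FALSE))
    if (all(dim(prev) == dim(M))) {
      M[] <- prev
      done <- !apply(is.na(M), 1, any)
    }
  }
  for (i in seq_along(ee_axis)) {
    if (done[i]) next
    for (j in seq_along(dng_axis)) {
      v <- evaluate_regimen(constant_regimen(ee_axis[i], dng_axis[j],
                                             dosing_time),
                            params, n_cycles, switches, ...)
      M[i, j] <- v$max_p4
    }
    if (!is.null(checkpoint))
      utils::write.csv(M, checkpoint, row.names = TRUE)
  }
  structure(list(max_p4 = M, ee_axis = ee_axis, dng_axis = dng_axis,
                 dosing_time = dosing_time, n_cycles = n_cycles,
                 threshold = params$threshold),
            class = "oc_dose_grid")
}

#' Minimal anovulatory constant dose at one dosing time
#'
#' Finds the admissible-region minimum on the dose grid using boundary
#' search: for each EE level, the smallest anovulatory DNG dose is located
#' by bisection along the DNG axis (max P4 is treated as non-increasing in
#' each dose coordinate), then the selection rule picks among the frontier
#' pairs. Rules: `"sum"` minimizes daily EE+DNG in ug with a low-DNG
#' tie-break; `"dng_first"`/`"ee_first"` are lexicographic.
#'
#' @inheritParams dose_grid
#' @param rule Selection rule.
#' @param threshold Anovulation threshold (ng/mL).
#' @return List of class `oc_min_dose`: `dosing_time`, `ee_daily`,
#'   `dng_daily`, `total_ee`, `total_dng`, `rule`, `achievable`,
#'   `n_cycles`, `frontier` (data.frame of the admissibility frontier).
#' @export
minimal_constant_dose <- function(dosing_time, params, n_cycles = 10,
                                  rule = c("sum", "dng_first", "ee_first"),
                                  ee_axis = .default_ee_axis(),
                                  dng_axis = .default_dng_axis(),
                                  switches = circadian_switches(),
                                  threshold = params$threshold, ...) {
  rule <- match.arg(rule)
  cache <- new.env(parent = emptyenv())
  eval_cell <- function(ee, dng) {
    key <- paste(ee, dng)
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- evaluate_regimen(constant_regimen(ee, dng, dosing_time), params,
                          n_cycles, switches, threshold = threshold, ...)
    cache[[key]] <- v$max_p4
    v$max_p4
  }
  anov <- function(ee, dng) eval_cell(ee, dng) < threshold

  # frontier: for each EE (descending), the minimal admissible DNG.
  # The low-DNG corner is tested first; if inadmissible, the minimal
  # admissible DNG is located by bisection (valid where additional DNG can
  # only help); rows whose high-DNG corner also fails carry no entry. Two
  # consecutive empty rows below the last admissible EE end the scan.
  frontier <- NULL
  empty_run <- 0L
  for (i in rev(seq_along(ee_axis))) {
    ee <- ee_axis[i]
    if (anov(ee, dng_axis[1])) {
      hit <- dng_axis[1]
    } else if (length(dng_axis) > 1L &&
               anov(ee, dng_axis[length(dng_axis)])) {
      lo <- 1L; hi <- length(dng_axis)
      while (hi - lo > 1L) {
        mid <- (lo + hi) %/% 2L
        if (anov(ee, dng_axis[mid])) hi <- mid else lo <- mid
      }
      hit <- dng_axis[hi]
    } else {
      empty_run <- empty_run + 1L
      if (!is.null(frontier) && empty_run >= 2L) break
      next
    }
    empty_run <- 0L
    frontier <- rbind(frontier,
                      data.frame(ee = ee, dng = hit,
                                 max_p4 = eval_cell(ee, hit)))
  }

  if (is.null(frontier))
    return(structure(list(dosing_time = dosing_time, achievable = FALSE,
                          ee_daily = NA_real_, dng_daily = NA_real_,
                          total_ee = NA_real_, total_dng = NA_real_,
                          rule = rule, n_cycles = n_cycles,
                          frontier = NULL),
                     class = "oc_min_dose"))

  pick <- switch(rule,
    sum = {
      s <- frontier$ee + frontier$dng
      cand <- which(s == min(s))
      cand[which.min(frontier$dng[cand])]
    },
    dng_first = {
      cand <- which(frontier$dng == min(frontier$dng))
      cand[which.min(frontier$ee[cand])]
    },
    ee_first = {
      cand <- which(frontier$ee == min(frontier$ee))
      cand[which.min(frontier$dng[cand])]
    })
  structure(list(dosing_time = dosing_time,
                 ee_daily = frontier$ee[pick], dng_daily = frontier$dng[pick],
                 total_ee = 21 * frontier$ee[pick],
                 total_dng = 21 * frontier$dng[pick],
                 rule = rule, achievable = TRUE, n_cycles = n_cycles,
                 frontier = frontier[order(frontier$ee), ]),
            class = "oc_min_dose")
}

#' Minimal-dose sweep over clock dosing times
#'
#' Runs [minimal_constant_dose()] for each dosing time and summarizes the
#' daytime/evening contrast (reference times 11:00 vs 22:00, and the
#' 07:00-12:00 vs 18:00-24:00 window minima of total EE+DNG).
#'
#' @inheritParams minimal_constant_dose
#' @param times Dosing times to evaluate (hours).
#' @param coarse Use the coarse 6x6 grid axes (default for sensitivity
#'   scenarios).
#' @return List of class `oc_sweep`: `table` (one row per time), `summary`.
#' @export
dosing_time_sweep <- function(params, times = 1:24, n_cycles = 10,
                              rule = "sum", coarse = FALSE,
                              ee_axis = NULL, dng_axis = NULL,
                              switches = circadian_switches(), ...) {
  if (is.null(ee_axis))
    ee_axis <- if (coarse) .coarse_ee_axis() else .default_ee_axis()
  if (is.null(dng_axis))
    dng_axis <- if (coarse) .coarse_dng_axis() else .default_dng_axis()
  rows <- lapply(times, function(tt) {
    r <- try(minimal_constant_dose(tt, params, n_cycles, rule,
                                   ee_axis, dng_axis, switches, ...),
             silent = TRUE)
    if (inherits(r, "try-error"))
      return(data.frame(time = tt, ee_daily = NA, dng_daily = NA,
                        total_ee = NA, total_dng = NA, achievable = NA,
                        error = TRUE))
    data.frame(time = tt, ee_daily = r$ee_daily, dng_daily = r$dng_daily,
               total_ee = r$total_ee, total_dng = r$total_dng,
               achievable = r$achievable, error = FALSE)
  })
  tab <- do.call(rbind, rows)
  summ <- .sweep_summary(tab)
  structure(list(table = tab, summary = summ, rule = rule,
                 n_cycles = n_cycles,
                 grid = list(ee_axis = ee_axis, dng_axis = dng_axis)),
            class = "oc_sweep")
}

.sweep_summary <- function(tab) {
  get <- function(tt, col) {
    v <- tab[[col]][tab$time == tt]
    if (length(v)) v else NA_real_
  }
  day_win <- tab[tab$time >= 7 & tab$time <= 12 & tab$achievable %in% TRUE, ]
  eve_win <- tab[tab$time >= 18 & tab$time <= 24 & tab$achievable %in% TRUE, ]
  tot <- tab$total_ee + tab$total_dng
  list(
    ee_11 = get(11, "total_ee"), dng_11 = get(11, "total_dng"),
    ee_22 = get(22, "total_ee"), dng_22 = get(22, "total_dng"),
    ee_reduction_pct = 100 * (1 - get(11, "total_ee") / get(22, "total_ee")),
    dng_reduction_pct = 100 * (1 - get(11, "total_dng") / get(22, "total_dng")),
    best_time = if (all(is.na(tot))) NA else tab$time[which.min(tot)],
    worst_time = if (all(is.na(tot))) NA else
      tab$time[which.max(ifelse(tab$achievable %in% TRUE, tot, Inf))],
    day_min_total = if (nrow(day_win)) min(day_win$total_ee +
                                           day_win$total_dng) else NA,
    eve_min_total = if (nrow(eve_win)) min(eve_win$total_ee +
                                           eve_win$total_dng) else NA
  )
}

#' PK-parameter perturbation sensitivity
#'
#' Perturbs each of the 10 non-baseline PK parameters (Vc, ka, k21, alpha1,
#' beta1 for both drugs) by the given fraction, one at a time in both
#' directions, reruns the dosing-time sweep (coarse grid by default), and
#' reports whether the daytime optimum (best time in 10:00-12:00) is
#' preserved. Perturbations that violate rate ordering are skipped and
#' logged.
#'
#' @param params An `oc_params` bundle.
#' @param fraction Relative perturbation (default 0.30).
#' @param times Dosing times for the sweep.
#' @param n_cycles Horizon per verdict.
#' @param ... Passed to [dosing_time_sweep()].
#' @return Data.frame: one row per perturbation with the best dosing time,
#'   the 11:00/22:00 totals and a `daytime_optimal` flag; skipped rows carry
#'   `skipped = TRUE`.
#' @export
sensitivity_pk_perturbation <- function(params, fraction = 0.30,
                                        times = c(7:13, 18, 20, 22, 24),
                                        n_cycles = 3, ...) {
  fields <- c("Vc", "ka", "k21", "alpha1", "beta1")
  out <- NULL
  for (drug in c("EE", "DNG")) for (f in fields) for (s in c(1, -1)) {
    pp <- params
    vals <- unclass(pp$pk[[drug]])
    vals[[f]] <- vals[[f]] * (1 + s * fraction)
    pk_new <- try(do.call(pk_params,
                          vals[c("Vc", "ka", "k21", "alpha1", "beta1", "F",
                                 "conc_scale", "drug")]), silent = TRUE)
    row <- data.frame(drug = drug, param = f, direction = s * fraction,
                      skipped = FALSE, best_time = NA_real_,
                      total_11 = NA_real_, total_22 = NA_real_,
                      daytime_optimal = NA)
    if (inherits(pk_new, "try-error")) {
      row$skipped <- TRUE
      out <- rbind(out, row)
      next
    }
    pp$pk[[drug]] <- pk_new
    sw <- dosing_time_sweep(pp, times = times, n_cycles = n_cycles,
                            coarse = TRUE, ...)
    row$best_time <- sw$summary$best_time
    row$total_11 <- sw$summary$ee_11 + sw$summary$dng_11
    row$total_22 <- sw$summary$ee_22 + sw$summary$dng_22
    row$daytime_optimal <- isTRUE(sw$summary$best_time >= 7 &&
                                  sw$summary$best_time <= 13)
    out <- rbind(out, row)
  }
  out
}

#' DNG half-life sensitivity
#'
#' Scales the DNG elimination half-life by each factor and reruns the
#' daytime/evening minimal-dose comparison.
#'
#' @param params An `oc_params` bundle.
#' @param factors Half-life multipliers (default 2 and 4).
#' @param times Dosing times (default 11 and 22).
#' @param n_cycles Horizon.
#' @param coarse Use coarse axes.
#' @param ... Passed to [minimal_constant_dose()].
#' @return Data.frame with one row per (factor, time): minimal daily/total
#'   doses, plus the DNG daytime/evening gap per factor in `attr(,"gaps")`.
#' @export
sensitivity_half_life <- function(params, factors = c(2, 4),
                                  times = c(11, 22), n_cycles = 10,
                                  coarse = FALSE, ...) {
  out <- NULL
  for (f in factors) {
    pp <- params
    pp$pk$DNG <- scale_half_life(params$pk$DNG, f)
    for (tt in times) {
      r <- minimal_constant_dose(
        tt, pp, n_cycles,
        ee_axis = if (coarse) .coarse_ee_axis() else .default_ee_axis(),
        dng_axis = if (coarse) .coarse_dng_axis() else .default_dng_axis(),
        ...)
      out <- rbind(out, data.frame(factor = f, time = tt,
                                   half_life_h = pk_half_life(pp$pk$DNG),
                                   ee_daily = r$ee_daily,
                                   dng_daily = r$dng_daily,
                                   total_ee = r$total_ee,
                                   total_dng = r$total_dng,
                                   achievable = r$achievable))
    }
  }
  gaps <- vapply(factors, function(f) {
    d <- out[out$factor == f, ]
    100 * (1 - d$total_dng[d$time == times[1]] /
             d$total_dng[d$time == times[2]])
  }, 0)
  attr(out, "gaps") <- stats::setNames(gaps, paste0("x", factors))
  out
}

#' Baseline-phase-shift sensitivity
#'
#' Shifts the baseline (rhythm-free) trajectories by the given amount before
#' circadian target construction, re-estimates the circadian parameters and
#' reruns the daytime/evening screening. A `shift` of `+0.5` day means the
#' baseline used for target construction runs half a day late.
#'
#' @param params An `oc_params` bundle.
#' @param fits Per-hormone cosinor fits (as in
#'   [estimate_circadian_params()]).
#' @param shifts Shifts in days (default +/- 12 h).
#' @param times,n_cycles,coarse,... Screening settings.
#' @return List per shift: the re-fitted `oc_circadian` and the screening
#'   rows.
#' @export
sensitivity_baseline_shift <- function(params, fits, shifts = c(-0.5, 0.5),
                                       times = c(9, 11, 22), n_cycles = 3,
                                       coarse = TRUE, ...) {
  lapply(stats::setNames(shifts, paste0("shift_", shifts)), function(sh) {
    est <- estimate_circadian_params(params, fits, baseline_shift = sh,
                                     n_starts = 2, maxit = 250)
    pp <- params
    pp$circadian <- est$circadian
    rows <- lapply(times, function(tt)
      minimal_constant_dose(
        tt, pp, n_cycles,
        ee_axis = if (coarse) .coarse_ee_axis() else .default_ee_axis(),
        dng_axis = if (coarse) .coarse_dng_axis() else .default_dng_axis(),
        ...))
    tab <- data.frame(time = times,
                      total_ee = vapply(rows, `[[`, 0, "total_ee"),
                      total_dng = vapply(rows, `[[`, 0, "total_dng"))
    list(shift = sh, circadian = est$circadian, table = tab)
  })
}

#' Cycle-length scaling sensitivity
#'
#' Multiplies the hormone-regulation and follicle-development rate constants
#' (`V0_LH, V1_LH, V_FSH, k_LH, k_FSH, a_LH, a_FSH, b, c1-c4, d1, d2,
#' k1-k4`) by each scale factor, measures the drug-free cycle length
#' (P4-peak spacing), and reruns daytime/evening screening.
#'
#' @param params An `oc_params` bundle.
#' @param scales Multiplicative factors (0.9333-1.0985 for
#'   30- to 25-day cycles).
#' @param times,n_cycles,coarse,... Screening settings.
#' @return Data.frame per (scale, time) with cycle length and minimal doses.
#' @export
sensitivity_cycle_length <- function(params,
                                     scales = c(0.9333, 1, 1.0985),
                                     times = c(11, 22), n_cycles = 3,
                                     coarse = TRUE, ...) {
  scaled_names <- c("V0_LH", "V1_LH", "V_FSH", "k_LH", "k_FSH", "a_LH",
                    "a_FSH", "b", "c1", "c2", "c3", "c4",
                    "d1", "d2", "k1", "k2", "k3", "k4")
  out <- NULL
  for (s in scales) {
    pp <- params
    for (nm in scaled_names) pp$baseline[[nm]] <- params$baseline[[nm]] * s
    free <- simulate_cycle(pp, days = 28 * 4, out_dt = 0.05)
    clen <- cycle_period(free)
    for (tt in times) {
      r <- minimal_constant_dose(
        tt, pp, n_cycles,
        ee_axis = if (coarse) .coarse_ee_axis() else .default_ee_axis(),
        dng_axis = if (coarse) .coarse_dng_axis() else .default_dng_axis(),
        ...)
      out <- rbind(out, data.frame(scale = s, cycle_length = clen,
                                   time = tt, ee_daily = r$ee_daily,
                                   dng_daily = r$dng_daily,
                                   total = r$total_ee + r$total_dng,
                                   achievable = r$achievable))
    }
  }
  out
}

#' Single-rhythm ablation analysis
#'
#' For a fixed regimen, compares max P4 at a daytime and an evening dosing
#' time with one hormone's circadian rhythm disabled at a time (plus the
#' all-on and all-off references). The summary ranks hormones by how much
#' removing their rhythm shrinks the daytime/evening difference — the
#' hormone whose removal collapses the contrast most is the primary driver
#' of the dosing-time effect.
#'
#' @param params An `oc_params` bundle.
#' @param ee,dng Constant daily doses (ug) of the probe regimen.
#' @param day_time,evening_time Clock hours compared.
#' @param n_cycles Horizon.
#' @param ... Passed to [evaluate_regimen()].
#' @return List with `table` (per ablation: max P4 at both times and their
#'   difference) and `ranking`.
#' @export
rhythm_ablation <- function(params, ee = 25, dng = 1000, day_time = 11,
                            evening_time = 22, n_cycles = 3, ...) {
  configs <- list(
    none = circadian_switches(),
    LH = circadian_switches(LH = FALSE),
    FSH = circadian_switches(FSH = FALSE),
    E2 = circadian_switches(E2 = FALSE),
    P4 = circadian_switches(P4 = FALSE),
    all = circadian_switches(FALSE, FALSE, FALSE, FALSE)
  )
  rows <- lapply(names(configs), function(nm) {
    vd <- evaluate_regimen(constant_regimen(ee, dng, day_time), params,
                           n_cycles, configs[[nm]], ...)
    ve <- evaluate_regimen(constant_regimen(ee, dng, evening_time), params,
                           n_cycles, configs[[nm]], ...)
    data.frame(ablated = nm, max_p4_day = vd$max_p4, max_p4_eve = ve$max_p4,
               diff = ve$max_p4 - vd$max_p4)
  })
  tab <- do.call(rbind, rows)
  full_diff <- tab$diff[tab$ablated == "none"]
  horm <- tab[tab$ablated %in% .hormones, ]
  horm$contrast_reduction <- full_diff - horm$diff
  ranking <- horm[order(-abs(horm$contrast_reduction)),
                  c("ablated", "diff", "contrast_reduction")]
  list(table = tab, ranking = ranking, full_diff = full_diff)
}
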