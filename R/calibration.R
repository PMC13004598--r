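#' Normalize a time series to unit mean
#'
#' Divides the values by their average so the series has mean exactly 1, the
#' form the cosinor fit expects.
#'
#' @param series A data.frame with columns `time` (hours) and `value`.
#' @return The same data.frame with `value` rescaled.
#' @export
normalize_series <- function(series) {
  stopifnot(is.data.frame(series), all(c("time", "value") %in% names(series)))
  m <- mean(series$value)
  if (!is.finite(m) || m <= 0) stop("series mean must be positive")
  series$value <- series$value / m
  series
}

#' Cosinor fit of a mean-normalized daily rhythm
#'
#' Fits `a*cos(2*pi*(t - b)) + 1` by exact linear least squares on the
#' cos/sin basis (no iterative search): writing the curve as
#' `1 + A*cos(2*pi*t) + B*sin(2*pi*t)`, the coefficients `(A, B)` solve an
#' ordinary linear regression, then `a = sqrt(A^2 + B^2)` and
#' `b = atan2(B, A)/(2*pi)` reported in `[0, 1)`.
#'
#' @param series A mean-normalized data.frame with `time` (hours, clock
#'   time) and `value` columns.
#' @return List of class `oc_cosinor` with `a` (amplitude), `b` (acrophase,
#'   days), `sse`, and `n`.
#' @export
fit_cosinor <- function(series) {
  stopifnot(is.data.frame(series), all(c("time", "value") %in% names(series)))
  td <- series$time / 24
  if (length(unique(round(td, 10))) < 3L)
    stop("cosinor fit needs at least 3 distinct time points")
  y <- series$value - 1
  X <- cbind(cos(2 * pi * td), sin(2 * pi * td))
  cf <- stats::lm.fit(X, y)$coefficients
  a <- sqrt(sum(cf^2))
  b <- (atan2(cf[2], cf[1]) / (2 * pi)) %% 1
  resid <- y - X %*% cf
  structure(list(a = unname(a), b = unname(b), sse = sum(resid^2),
                 n = length(y)), class = "oc_cosinor")
}

#' Build a circadian target trajectory from a baseline trajectory
#'
#' Combines a simulated baseline (rhythm-free) hormone trajectory `H(t)`
#' with a fitted daily cosine: `target(t) = H(t) * (1 + a*cos(2*pi*(t-b)))`,
#' so higher hormone levels carry proportionally larger daily oscillations.
#'
#' @param time Model times (days).
#' @param values Baseline hormone values at `time`.
#' @param fit An `oc_cosinor` fit (or a list with `a` and `b`).
#' @return Numeric vector of target values.
#' @export
build_target <- function(time, values, fit) {
  values * (1 + fit$a * cos(2 * pi * (time - fit$b)))
}

# simulate the four hormone observables on a time grid (internal)
.sim_hormones <- function(params, switches, days, out_dt = 1 / 24) {
  sim <- simulate_cycle(params, days = days, switches = switches,
                        out_dt = out_dt, rtol = 1e-7, atol = 1e-7)
  sim[, c("time", "LH", "FSH", "E2", "P4")]
}

#' Estimate circadian amplitudes and acrophases from target rhythms
#'
#' Reproduces the two-stage rhythm calibration: given per-hormone cosinor
#' fits of daily data, targets are built by modulating the baseline
#' (rhythm-free) model trajectory, and the eight circadian parameters
#' (amplitude + acrophase for LH, FSH, E2, P4) are then estimated by
#' Nelder-Mead least squares between the circadian model's simulated
#' hormones and those targets. The objective sums the per-hormone squared
#' errors, each normalized by the hormone's mean squared level, so all four
#' hormones carry comparable weight. Multi-start Nelder-Mead (Latin
#' hypercube starts over the documented bounds) guards against local minima.
#'
#' @param params An `oc_params` bundle; its circadian section is ignored and
#'   re-estimated.
#' @param fits Named list of `oc_cosinor` fits for `LH`, `FSH`, `E2`, `P4`
#'   (daily-rhythm fits of measured data); targets are then built by
#'   modulating the baseline trajectory. Alternatively pass `targets`.
#' @param targets Optional data.frame with columns `time` (days) and `LH`,
#'   `FSH`, `E2`, `P4`: explicit target trajectories (e.g. for recovery
#'   studies). Interpolated onto the comparison grid.
#' @param days Length of the comparison window (days; one 28-day cycle by
#'   default).
#' @param n_starts Number of Nelder-Mead starts.
#' @param maxit Iteration cap per start.
#' @param seed Seed for the Latin-hypercube start points.
#' @param baseline_shift Shift (days) applied to the baseline trajectory
#'   before target construction (used by the phase-shift sensitivity
#'   scenario); 0 for the canonical fit.
#' @param mode `"joint"` fits all eight parameters in one objective;
#'   `"per_hormone"` fits each hormone's (amplitude, acrophase) pair in the
#'   staged order E2, P4, FSH, LH against its own target with the others
#'   held at their current values. The staged mode is better conditioned
#'   when the pituitary reserve pools strongly low-pass-filter the
#'   synthesis-rate modulation.
#' @return List with `circadian` (an `oc_circadian`), `sse`, `starts`
#'   (per-start objective log) and `target` (the target trajectories).
#' @export
estimate_circadian_params <- function(params, fits = NULL, days = 28,
                                      n_starts = 5, maxit = 400, seed = 1,
                                      baseline_shift = 0,
                                      mode = c("joint", "per_hormone"),
                                      targets = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "oc_params"))
  if (is.null(fits) == is.null(targets))
    stop("supply exactly one of `fits` or `targets`")
  off <- circadian_switches(FALSE, FALSE, FALSE, FALSE)
  base <- .sim_hormones(params, off, days)
  if (baseline_shift != 0) {
    for (h in .hormones)
      base[[h]] <- stats::approx(base$time, base[[h]],
                                 base$time - baseline_shift,
                                 rule = 2)$y
  }
  if (is.null(targets)) {
    stopifnot(all(.hormones %in% names(fits)))
    targets <- vapply(.hormones, function(h)
      build_target(base$time, base[[h]], fits[[h]]), numeric(nrow(base)))
  } else {
    stopifnot(all(c("time", .hormones) %in% names(targets)))
    targets <- vapply(.hormones, function(h)
      stats::approx(targets$time, targets[[h]], base$time, rule = 2)$y,
      numeric(nrow(base)))
    # data-informed starts: daily cosinor of the target/baseline ratio
    fits <- lapply(.hormones, function(h) {
      hi <- match(h, .hormones)
      fit_cosinor(data.frame(time = base$time * 24,
                             value = targets[, hi] / pmax(base[[h]], 1e-9)))
    })
    names(fits) <- .hormones
  }
  norms <- colMeans(targets^2)

  objective <- function(theta) {
    amp <- theta[c(1, 3, 5, 7)]
    if (any(amp < 0) || any(amp >= 0.9)) return(1e10)
    pc <- params
    pc$circadian <- oc_circadian(amplitude = amp,
                                 acrophase = theta[c(2, 4, 6, 8)])
    sim <- try(.sim_hormones(pc, circadian_switches(), days), silent = TRUE)
    if (inherits(sim, "try-error")) return(1e10)
    sum(vapply(seq_along(.hormones), function(i)
      mean((sim[[.hormones[i]]] - targets[, i])^2) / norms[i], 0))
  }

  center <- as.numeric(rbind(vapply(fits[.hormones], `[[`, 0, "a"),
                             vapply(fits[.hormones], `[[`, 0, "b")))

  if (mode == "per_hormone") {
    theta <- center
    stage_order <- rep(c("E2", "P4", "FSH", "LH"), 2)
    idx_of <- list(LH = c(1, 2), FSH = c(3, 4), E2 = c(5, 6), P4 = c(7, 8))
    stage_sse <- numeric(0)
    for (h in stage_order) {
      hi <- match(h, .hormones)
      idx <- idx_of[[h]]
      obj_h <- function(pair) {
        th <- theta
        th[idx] <- pair
        amp <- th[c(1, 3, 5, 7)]
        if (any(amp < 0) || any(amp >= 0.9)) return(1e10)
        pc <- params
        pc$circadian <- oc_circadian(amplitude = amp,
                                     acrophase = th[c(2, 4, 6, 8)])
        sim <- try(.sim_hormones(pc, circadian_switches(), days),
                   silent = TRUE)
        if (inherits(sim, "try-error")) return(1e10)
        mean((sim[[h]] - targets[, hi])^2) / norms[hi]
      }
      starts_h <- rbind(theta[idx],
                        c(theta[idx][1], (theta[idx][2] + 0.5) %% 1),
                        c(min(0.6, theta[idx][1] * 3), theta[idx][2] - 0.3))
      runs_h <- lapply(seq_len(nrow(starts_h)), function(i)
        stats::optim(starts_h[i, ], obj_h, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-10)))
      best_h <- runs_h[[which.min(vapply(runs_h, `[[`, 0, "value"))]]
      theta[idx] <- best_h$par
      stage_sse <- c(stage_sse, best_h$value)
    }
    # final joint polish: restarted Nelder-Mead from the staged solution
    # (each restart rebuilds the simplex, which escapes the flat valleys
    # left by the staged fits)
    best_v <- objective(theta)
    for (k in 1:3) {
      pol <- stats::optim(theta, objective, method = "Nelder-Mead",
                          control = list(maxit = 2 * maxit,
                                         reltol = 1e-12))
      if (pol$value < best_v) {
        theta <- pol$par
        best_v <- pol$value
      }
      if (best_v < 1e-14) break
    }
    circ <- oc_circadian(amplitude = pmax(theta[c(1, 3, 5, 7)], 0),
                         acrophase = theta[c(2, 4, 6, 8)])
    return(list(circadian = circ, sse = objective(theta),
                starts = data.frame(stage = stage_order,
                                    final_value = stage_sse),
                target = data.frame(time = base$time, targets)))
  }

  # joint mode: data-informed center plus Latin-hypercube starts
  starts <- matrix(center, n_starts, 8, byrow = TRUE)
  if (n_starts > 1) {
    lh <- .with_local_seed(seed, {
      if (requireNamespace("lhs", quietly = TRUE))
        lhs::randomLHS(n_starts - 1, 8)
      else matrix(stats::runif(8 * (n_starts - 1)), n_starts - 1, 8)
    })
    starts[-1, ] <- t(t(lh) * rep(c(0.4, 1), 4))  # amp in [0,.4], phase [0,1)
  }
  runs <- lapply(seq_len(n_starts), function(i) {
    o <- stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
    list(par = o$par, value = o$value, start = starts[i, ],
         start_value = objective(starts[i, ]), convergence = o$convergence)
  })
  best <- runs[[which.min(vapply(runs, `[[`, 0, "value"))]]
  circ <- oc_circadian(amplitude = pmax(best$par[c(1, 3, 5, 7)], 0),
                       acrophase = best$par[c(2, 4, 6, 8)])
  list(circadian = circ, sse = best$value,
       starts = data.frame(
         start_value = vapply(runs, `[[`, 0, "start_value"),
         final_value = vapply(runs, `[[`, 0, "value"),
         convergence = vapply(runs, `[[`, 0, "convergence")),
       target = data.frame(time = base$time, targets))
}

# superposed closed-form concentration after n daily doses (internal)
.multi_dose_conc <- function(t_after_first, dose, clock_time, n_doses, pk) {
  co <- .pk_coefs(pk)
  times <- (seq_len(n_doses) - 1) + clock_time / 24
  cpp_pk_conc(t_after_first, times, rep(dose, n_doses), pk$ka, pk$alpha1,
              pk$beta1, co[["N"]], co[["L"]], co[["M"]])
}

#' Estimate two-compartment PK parameters from a concentration series
#'
#' Fits the superposed closed-form concentration after `n_prior_doses` daily
#' doses to a 24-h post-dose concentration series by least squares.
#' Parameters are searched in log space with Nelder-Mead (so positivity is
#' automatic) with an ordering penalty keeping `beta1 < k21 < alpha1 < ka`
#' separated; multi-start from perturbed heuristic initials.
#'
#' @param series Data.frame with `time` (hours after the last dose) and
#'   `conc` columns.
#' @param dose Dose amount (ug) given once daily.
#' @param pk_template An `oc_pk` carrying the drug label and `conc_scale`.
#' @param n_prior_doses Number of daily doses administered up to and
#'   including the observed one (default 7).
#' @param n_starts,maxit,seed Optimizer settings.
#' @return List with `pk` (fitted `oc_pk`), `rss`, `aic`, `n`,
#'   `boundary_flag` and the per-start log.
#' @export
estimate_pk_params <- function(series, dose, pk_template, n_prior_doses = 7,
                               n_starts = 5, maxit = 2000, seed = 1) {
  stopifnot(is.data.frame(series), all(c("time", "conc") %in% names(series)),
            nrow(series) >= 10, max(series$time) >= 24 - 1e-9)
  # doses daily at clock_time = 24 so they fall on integer day boundaries;
  # series$time counts hours after the last (n-th) dose
  t_days <- (n_prior_doses - 1) + 1 + series$time / 24
  pred <- function(p) {
    pk <- try(pk_params(Vc = p[1], ka = p[2], k21 = p[3], alpha1 = p[4],
                        beta1 = p[5], conc_scale = pk_template$conc_scale,
                        drug = pk_template$drug), silent = TRUE)
    if (inherits(pk, "try-error")) return(NULL)
    .multi_dose_conc(t_days, dose, 24, n_prior_doses, pk)
  }
  objective <- function(lp) {
    p <- exp(lp)
    # soft ordering barrier: beta1 < k21 < alpha1 < ka with 5% separation
    if (!(p[5] * 1.05 < p[3] && p[3] * 1.05 < p[4] && p[4] * 1.05 < p[2]))
      return(1e10)
    yhat <- pred(p)
    if (is.null(yhat)) return(1e10)
    sum((yhat - series$conc)^2)
  }

  # heuristic initials from curve shape
  tmax <- series$time[which.max(series$conc)]
  beta0 <- log(2) / (max(series$time) / 2) * 24     # 1/day rough terminal
  ka0 <- 24 * 1.4 / max(tmax, 0.5)
  init <- log(c(Vc = dose * pk_template$conc_scale / max(series$conc) / 2,
                ka = ka0, k21 = 3 * beta0, alpha1 = ka0 / 3.5,
                beta1 = beta0))
  # project a start onto the ordered-rate region beta1 < k21 < alpha1 < ka
  order_start <- function(lp) {
    p <- exp(lp)
    p[3] <- max(p[3], 1.2 * p[5])
    p[4] <- max(p[4], 1.3 * p[3])
    p[2] <- max(p[2], 1.3 * p[4])
    log(p)
  }
  runs <- .with_local_seed(seed, lapply(seq_len(n_starts), function(i) {
    st <- order_start(if (i == 1) init else init + stats::rnorm(5, 0, 0.4))
    o <- stats::optim(st, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
    o2 <- stats::optim(o$par, objective, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-10))
    list(par = o2$par, value = o2$value)
  }))
  vals <- vapply(runs, `[[`, 0, "value")
  if (all(vals >= 1e9))
    stop("PK fit failed: no start converged inside the ordered-rate region")
  best <- runs[[which.min(vals)]]
  p <- exp(best$par)
  pk <- pk_params(Vc = p[1], ka = p[2], k21 = p[3], alpha1 = p[4],
                  beta1 = p[5], conc_scale = pk_template$conc_scale,
                  drug = pk_template$drug)
  n <- nrow(series)
  rss <- best$value
  k <- 5
  boundary <- (p[5] * 1.10 > p[3]) || (p[3] * 1.10 > p[4]) ||
    (p[4] * 1.10 > p[2])
  list(pk = pk, rss = rss, aic = 2 * k + n * log(rss / n), n = n,
       boundary_flag = boundary,
       starts = data.frame(final_value = vals))
}

#' One-compartment oral fit (for AIC comparison)
#'
#' Fits `C(t) = (F*u*ka)/(Vc*(ka-ke)) * (exp(-ke*dt) - exp(-ka*dt))`
#' superposed over the prior daily doses.
#'
#' @inheritParams estimate_pk_params
#' @return List with `par` (`Vc`, `ka`, `ke`), `rss`, `aic`, `n`.
#' @export
fit_one_compartment <- function(series, dose, pk_template,
                                n_prior_doses = 7, maxit = 2000) {
  stopifnot(is.data.frame(series), nrow(series) >= 5)
  t_days <- (n_prior_doses - 1) + 1 + series$time / 24
  dose_times <- (seq_len(n_prior_doses) - 1) + 1
  pred <- function(p) {
    # tri-exponential evaluator reused with L-coefficient zeroed:
    # one-compartment curve = A*(e^{-ke dt} - e^{-ka dt})
    A <- pk_template$conc_scale * dose * p[2] / (p[1] * (p[2] - p[3]))
    rowSums(vapply(dose_times, function(td) {
      dt <- pmax(t_days - td, 0)
      ifelse(t_days >= td, A * (exp(-p[3] * dt) - exp(-p[2] * dt)), 0)
    }, numeric(length(t_days))))
  }
  objective <- function(lp) {
    p <- exp(lp)
    if (p[3] * 1.05 > p[2]) return(1e10)
    sum((pred(p) - series$conc)^2)
  }
  tmax <- series$time[which.max(series$conc)]
  init <- log(c(Vc = dose * pk_template$conc_scale / max(series$conc) / 1.5,
                ka = 24 * 1.4 / max(tmax, 0.5),
                ke = log(2) / (max(series$time) / 2) * 24))
  o <- stats::optim(init, objective, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = 1e-10))
  o <- stats::optim(o$par, objective, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = 1e-10))
  n <- nrow(series)
  list(par = stats::setNames(exp(o$par), c("Vc", "ka", "ke")), rss = o$value,
       aic = 2 * 3 + n * log(o$value / n), n = n)
}

#' Compare compartment models by AIC
#'
#' Least-squares AIC, `2k + n*log(RSS/n)`; lower is better.
#'
#' @inheritParams estimate_pk_params
#' @return Data.frame ranked by AIC with a `delta_aic` column.
#' @export
compare_aic <- function(series, dose, pk_template, n_prior_doses = 7,
                        seed = 1) {
  two <- estimate_pk_params(series, dose, pk_template, n_prior_doses,
                            seed = seed)
  one <- fit_one_compartment(series, dose, pk_template, n_prior_doses)
  out <- data.frame(model = c("one-compartment", "two-compartment"),
                    k = c(3, 5), rss = c(one$rss, two$rss),
                    aic = c(one$aic, two$aic))
  out <- out[order(out$aic), ]
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  out
}
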