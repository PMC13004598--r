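#' Objectives of a nonconstant 21-day dose vector
#'
#' `J1` is the maximum P4 (ng/mL) over `n_cycles` cycles with the dose
#' vector repeated each cycle; `J2` is the plain microgram sum of all 42
#' daily doses (EE and DNG mixed, as conventionally printed).
#'
#' @param ee,dng Daily doses (ug), length 21, inside the market-dose box.
#' @param clock_time Dosing time (hours).
#' @param params An `oc_params` bundle.
#' @param n_cycles Evaluation horizon (default 3).
#' @param ... Passed to [simulate_cycle()].
#' @return List `j1`, `j2`, `feasible` (solver success).
#' @export
evaluate_objectives <- function(ee, dng, clock_time, params, n_cycles = 3,
                                ...) {
  j2 <- sum(ee) + sum(dng)
  v <- try(evaluate_regimen(oc_regimen(ee, dng, clock_time), params,
                            n_cycles = n_cycles, ...), silent = TRUE)
  if (inherits(v, "try-error"))
    return(list(j1 = Inf, j2 = j2, feasible = FALSE))
  list(j1 = v$max_p4, j2 = j2, feasible = TRUE)
}

# fast non-dominated sorting (2 objectives, minimization)
.nd_rank <- function(F) {
  n <- nrow(F)
  rank <- integer(n)
  remaining <- seq_len(n)
  r <- 0L
  while (length(remaining)) {
    r <- r + 1L
    Fi <- F[remaining, , drop = FALSE]
    o <- order(Fi[, 1], Fi[, 2])
    nd <- logical(length(remaining))
    best2 <- Inf
    for (idx in o) {
      if (Fi[idx, 2] < best2) { nd[idx] <- TRUE; best2 <- Fi[idx, 2] }
    }
    # handle exact duplicates of front points (keep them in the same front)
    for (idx in seq_along(remaining)) {
      if (!nd[idx] && any(nd & Fi[, 1] == Fi[idx, 1] & Fi[, 2] == Fi[idx, 2]))
        nd[idx] <- TRUE
    }
    rank[remaining[nd]] <- r
    remaining <- remaining[!nd]
  }
  rank
}

.crowding <- function(F) {
  n <- nrow(F)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (m in 1:2) {
    o <- order(F[, m])
    rng <- F[o[n], m] - F[o[1], m]
    d[o[c(1, n)]] <- Inf
    if (rng > 0)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (F[o[3:n], m] - F[o[1:(n - 2)], m]) / rng
  }
  d
}

.sbx <- function(p1, p2, lower, upper, eta = 15, pc = 0.9) {
  n <- length(p1)
  c1 <- p1; c2 <- p2
  if (stats::runif(1) < pc) {
    do <- stats::runif(n) < 0.5 & abs(p1 - p2) > 1e-14
    u <- stats::runif(n)
    bq <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
    x1 <- 0.5 * ((1 + bq) * p1 + (1 - bq) * p2)
    x2 <- 0.5 * ((1 - bq) * p1 + (1 + bq) * p2)
    c1[do] <- x1[do]; c2[do] <- x2[do]
  }
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

.poly_mut <- function(x, lower, upper, eta = 20, pm = NULL) {
  n <- length(x)
  if (is.null(pm)) pm <- 1 / n
  do <- stats::runif(n) < pm
  if (!any(do)) return(x)
  u <- stats::runif(n)
  delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  x[do] <- x[do] + delta[do] * (upper[do] - lower[do])
  pmin(pmax(x, lower), upper)
}

#' Two-dimensional hypervolume (minimization)
#'
#' @param F Matrix of objective pairs.
#' @param ref Reference point (both coordinates must dominate-exceed all
#'   points considered; points beyond it are clipped out).
#' @return The dominated hypervolume.
#' @export
hypervolume_2d <- function(F, ref) {
  F <- F[F[, 1] < ref[1] & F[, 2] < ref[2], , drop = FALSE]
  if (!nrow(F)) return(0)
  F <- F[order(F[, 1], F[, 2]), , drop = FALSE]
  hv <- 0; prev2 <- ref[2]
  for (i in seq_len(nrow(F))) {
    if (F[i, 2] < prev2) {
      hv <- hv + (ref[1] - F[i, 1]) * (prev2 - F[i, 2])
      prev2 <- F[i, 2]
    }
  }
  hv
}

# tournament selection index by (rank, crowding)
.tournament <- function(rank, crowd) {
  n <- length(rank)
  i <- sample.int(n, 1); j <- sample.int(n, 1)
  if (rank[i] < rank[j]) i
  else if (rank[j] < rank[i]) j
  else if (crowd[i] >= crowd[j]) i else j
}

#' Coevolutionary constrained NSGA-II over nonconstant regimens
#'
#' Minimizes `(J1, J2)` over the 42-dimensional dose box (21 daily EE doses
#' in `[0, 30]` ug, 21 daily DNG doses in `[0, 2000]` ug) at a fixed clock
#' dosing time, using NSGA-II inside a two-population coevolutionary
#' constraint-handling scheme: the main population ranks by constrained
#' dominance with constraint `J1 < threshold` (feasibility first), the
#' helper population ignores the constraint and explores the unconstrained
#' front; offspring of both populations enter both selection pools.
#' Simulated binary crossover (eta 15, p 0.9) and polynomial mutation
#' (eta 20, p 1/42). Stops when the relative change of the feasible-front
#' hypervolume over 10 consecutive generations drops below `ftol`, or when
#' the evaluation budget is exhausted.
#'
#' This can also solve a generic test problem: pass `problem` (as from
#' [gen_toy_moo_problem()]) to replace the dose-regimen objective.
#'
#' @param params An `oc_params` bundle (ignored when `problem` is given).
#' @param dosing_time Clock dosing time (hours).
#' @param seed Mandatory integer seed.
#' @param populations Sizes of (main, helper) populations.
#' @param ftol Stopping tolerance on relative hypervolume change.
#' @param budget Maximum number of objective evaluations.
#' @param n_cycles Horizon of the `J1` simulation (default 3).
#' @param threshold Feasibility threshold on `J1` (ng/mL).
#' @param problem Optional generic problem list (`fn`, `lower`, `upper`).
#' @param verbose Print per-generation progress.
#' @param ... Passed to the regimen evaluation.
#' @return An object of class `oc_moo_run`: `archive` (matrix of evaluated
#'   vectors), `archive_obj` (J1, J2, generation), `front` (feasible
#'   non-dominated set), `generations`, `evaluations`, `converged`,
#'   `settings`.
#' @export
run_moo <- function(params = NULL, dosing_time = 11, seed,
                    populations = c(40, 50), ftol = 1e-4, budget = 5000,
                    n_cycles = 3, threshold = 3, problem = NULL,
                    verbose = FALSE, ...) {
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  if (is.null(problem)) {
    stopifnot(inherits(params, "oc_params"))
    lower <- rep(0, 42)
    upper <- c(rep(30, 21), rep(2000, 21))
    fn <- function(x) {
      o <- evaluate_objectives(x[1:21], x[22:42], dosing_time, params,
                               n_cycles, ...)
      c(o$j1, o$j2)
    }
  } else {
    lower <- problem$lower; upper <- problem$upper
    fn <- function(x) problem$fn(x)
  }
  nvar <- length(lower)
  n1 <- populations[1]; n2 <- populations[2]

  arch_x <- matrix(NA_real_, 0, nvar)
  arch_f <- matrix(NA_real_, 0, 2)
  arch_g <- integer(0)
  nev <- 0L
  gen <- 0L
  evaluate <- function(X) {
    Fm <- t(apply(X, 1, fn))
    arch_x <<- rbind(arch_x, X)
    arch_f <<- rbind(arch_f, Fm)
    arch_g <<- c(arch_g, rep(gen, nrow(X)))
    nev <<- nev + nrow(X)
    Fm
  }

  # constrained rank: feasible solutions (J1 < threshold) first by
  # (rank on (J1,J2), crowding); infeasible after, by violation
  c_rank <- function(Fm) {
    cv <- pmax(0, Fm[, 1] - threshold)
    feas <- cv == 0
    rank <- rep(NA_real_, nrow(Fm))
    if (any(feas)) rank[feas] <- .nd_rank(Fm[feas, , drop = FALSE])
    if (any(!feas)) {
      base <- if (any(feas)) max(rank[feas]) else 0
      rank[!feas] <- base + rank(cv[!feas], ties.method = "first")
    }
    rank
  }

  # init: random population, warm-started (dose-regimen mode) with
  # constant-dose heuristics around the market box so the narrow feasible
  # corner is represented from generation 0
  X1 <- t(replicate(n1, lower + stats::runif(nvar) * (upper - lower)))
  X2 <- t(replicate(n2, lower + stats::runif(nvar) * (upper - lower)))
  if (is.null(problem)) {
    seeds <- rbind(
      c(rep(30, 21), rep(0, 21)),
      c(rep(28.2, 21), rep(0, 21)),
      c(rep(30, 14), rep(0, 7), rep(0, 21)),
      c(rep(30, 10), rep(0, 11), rep(0, 21)),
      c(rep(c(30, 0), length.out = 21), rep(0, 21)),
      c(rep(25, 21), rep(1000, 21))
    )
    k <- min(nrow(seeds), n1)
    X1[seq_len(k), ] <- seeds[seq_len(k), ]
    k2 <- min(2L, n2)
    X2[seq_len(k2), ] <- seeds[seq_len(k2), ]
  }
  F1 <- evaluate(X1); F2 <- evaluate(X2)

  hv_hist <- numeric(0)
  ref <- c(max(threshold * 3, 9), sum(upper) * 1.05)
  converged <- FALSE

  while (nev + n1 + n2 <= budget) {
    gen <- gen + 1L
    r1 <- c_rank(F1); cr1 <- .crowding(F1)
    r2 <- .nd_rank(F2); cr2 <- .crowding(F2)

    make_off <- function(X, rank, crowd, n_off) {
      O <- matrix(NA_real_, n_off, nvar)
      i <- 1L
      while (i <= n_off) {
        a <- .tournament(rank, crowd); b <- .tournament(rank, crowd)
        ch <- .sbx(X[a, ], X[b, ], lower, upper)
        O[i, ] <- .poly_mut(ch[[1]], lower, upper)
        if (i + 1L <= n_off) O[i + 1L, ] <- .poly_mut(ch[[2]], lower, upper)
        i <- i + 2L
      }
      O
    }
    O1 <- make_off(X1, r1, cr1, n1)
    O2 <- make_off(X2, r2, cr2, n2)
    FO1 <- evaluate(O1); FO2 <- evaluate(O2)

    # environmental selection from shared pools
    pool_x <- rbind(X1, O1, O2); pool_f <- rbind(F1, FO1, FO2)
    pr <- c_rank(pool_f)
    ord <- order(pr, -.crowding(pool_f))
    keep <- ord[seq_len(n1)]
    X1 <- pool_x[keep, , drop = FALSE]; F1 <- pool_f[keep, , drop = FALSE]

    pool_x <- rbind(X2, O1, O2); pool_f <- rbind(F2, FO1, FO2)
    pr <- .nd_rank(pool_f)
    ord <- order(pr, -.crowding(pool_f))
    keep <- ord[seq_len(n2)]
    X2 <- pool_x[keep, , drop = FALSE]; F2 <- pool_f[keep, , drop = FALSE]

    feas <- F1[, 1] < threshold
    hv <- if (any(feas))
      hypervolume_2d(F1[feas, , drop = FALSE], ref) else 0
    hv_hist <- c(hv_hist, hv)
    if (verbose)
      message(sprintf("gen %d | evals %d | feasible %d | HV %.4g", gen, nev,
                      sum(feas), hv))
    if (length(hv_hist) > 10) {
      w <- utils::tail(hv_hist, 11)
      if (w[1] > 0 && abs(w[11] - w[1]) / w[1] < ftol) {
        converged <- TRUE
        break
      }
    }
  }

  # feasible non-dominated archive front
  feas <- arch_f[, 1] < threshold & is.finite(arch_f[, 1])
  front_idx <- integer(0)
  if (any(feas)) {
    idx <- which(feas)
    rk <- .nd_rank(arch_f[idx, , drop = FALSE])
    front_idx <- idx[rk == 1L]
    # deduplicate identical objective pairs
    front_idx <- front_idx[!duplicated(arch_f[front_idx, , drop = FALSE])]
  }
  structure(list(
    archive = arch_x, archive_obj = data.frame(j1 = arch_f[, 1],
                                               j2 = arch_f[, 2],
                                               generation = arch_g),
    front = list(x = arch_x[front_idx, , drop = FALSE],
                 f = arch_f[front_idx, , drop = FALSE]),
    generations = gen, evaluations = nev, converged = converged,
    hv_history = hv_hist,
    settings = list(seed = seed, populations = populations, ftol = ftol,
                    budget = budget, dosing_time = dosing_time,
                    n_cycles = n_cycles, threshold = threshold)),
    class = "oc_moo_run")
}

#' Select and confirm the cheapest anovulatory front member
#'
#' Orders the feasible Pareto-front members by total dose `J2` and returns
#' the first whose regimen remains anovulatory when re-simulated over the
#' long confirmation horizon (10 cycles).
#'
#' @param run An `oc_moo_run`.
#' @param params An `oc_params` bundle.
#' @param n_cycles_confirm Confirmation horizon (default 10).
#' @param ... Passed to [evaluate_regimen()].
#' @return List: `regimen` (an `oc_regimen`, or `NULL` if none confirmed),
#'   `j2`, `j1_short`, `confirmed`, `n_checked`.
#' @export
select_confirmed_regimen <- function(run, params, n_cycles_confirm = 10,
                                     ...) {
  stopifnot(inherits(run, "oc_moo_run"))
  f <- run$front$f
  if (is.null(f) || !nrow(f))
    return(list(regimen = NULL, confirmed = FALSE, n_checked = 0L))
  o <- order(f[, 2])
  tt <- run$settings$dosing_time
  for (k in seq_along(o)) {
    x <- run$front$x[o[k], ]
    reg <- oc_regimen(x[1:21], x[22:42], tt)
    v <- evaluate_regimen(reg, params, n_cycles = n_cycles_confirm, ...)
    if (v$anovulatory)
      return(list(regimen = reg, j2 = f[o[k], 2], j1_short = f[o[k], 1],
                  max_p4_long = v$max_p4, confirmed = TRUE, n_checked = k))
  }
  list(regimen = NULL, confirmed = FALSE, n_checked = length(o))
}

#' Zero out sub-threshold doses and re-verify
#'
#' Sets daily doses below `threshold` (default 1 ug) to zero and re-verifies
#' anovulation over the long horizon; if verification fails the original
#' regimen is returned with `zeroed = FALSE`.
#'
#' @param regimen An `oc_regimen` confirmed anovulatory.
#' @param params An `oc_params` bundle.
#' @param threshold Dose floor (ug).
#' @param n_cycles Verification horizon.
#' @param ... Passed to [evaluate_regimen()].
#' @return List: `regimen`, `zeroed`, `verdict`.
#' @export
zero_small_doses <- function(regimen, params, threshold = 1, n_cycles = 10,
                             ...) {
  stopifnot(inherits(regimen, "oc_regimen"))
  reg2 <- regimen
  reg2$ee[reg2$ee < threshold] <- 0
  reg2$dng[reg2$dng < threshold] <- 0
  if (identical(reg2$ee, regimen$ee) && identical(reg2$dng, regimen$dng))
    return(list(regimen = regimen, zeroed = FALSE, verdict = NULL))
  v <- evaluate_regimen(reg2, params, n_cycles = n_cycles, ...)
  if (v$anovulatory) list(regimen = reg2, zeroed = TRUE, verdict = v)
  else list(regimen = regimen, zeroed = FALSE, verdict = v)
}

#' Cross-dosing-time validation of candidate regimens
#'
#' Implements the iterative cheapest-first assignment: candidates are
#' sorted by total dose; the cheapest is tested at every dosing time and
#' assigned wherever it keeps anovulation over the long horizon; the next
#' cheapest is tested on the still-unassigned times; and so on. The final
#' per-time total dose is therefore non-increasing relative to any per-time
#' pre-validation assignment.
#'
#' @param candidates List of `oc_regimen` candidates (clock time of each is
#'   overridden during testing).
#' @param params An `oc_params` bundle.
#' @param times Dosing times to cover (hours).
#' @param n_cycles Confirmation horizon.
#' @param ... Passed to [evaluate_regimen()].
#' @return Data.frame, one row per time: assigned candidate index, its
#'   total EE/DNG doses, intake days; unassigned times carry `NA`.
#' @export
cross_time_validation <- function(candidates, params, times = 1:24,
                                  n_cycles = 10, ...) {
  stopifnot(length(candidates) >= 1)
  j2 <- vapply(candidates, function(r) sum(r$ee) + sum(r$dng), 0)
  ord <- order(j2)
  assigned <- rep(NA_integer_, length(times))
  for (k in ord) {
    open <- which(is.na(assigned))
    if (!length(open)) break
    for (i in open) {
      reg <- candidates[[k]]
      reg$clock_time <- times[i]
      v <- evaluate_regimen(reg, params, n_cycles = n_cycles, ...)
      if (v$anovulatory) assigned[i] <- k
    }
  }
  data.frame(
    time = times, candidate = assigned,
    total_ee = vapply(assigned, function(k)
      if (is.na(k)) NA_real_ else sum(candidates[[k]]$ee), 0),
    total_dng = vapply(assigned, function(k)
      if (is.na(k)) NA_real_ else sum(candidates[[k]]$dng), 0),
    intake_days = vapply(assigned, function(k)
      if (is.na(k)) NA_integer_ else intake_day_count(candidates[[k]]),
      0L))
}

#' Number of intake days of a regimen
#'
#' @param regimen An `oc_regimen`.
#' @return Count of days with a nonzero EE or DNG dose.
#' @export
intake_day_count <- function(regimen) {
  stopifnot(inherits(regimen, "oc_regimen"))
  sum(regimen$ee + regimen$dng > 0)
}
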