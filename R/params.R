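#' @useDynLib chronOC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Order of the flattened parameter vector handed to the compiled RHS.
# Must stay in lockstep with the enum in src/cycle_integrate.cpp.
.param_order <- c(
  "V0_LH", "V1_LH", "Km_LH", "Ki_LH_P", "k_LH", "c_LH_P", "c_LH_E", "a_LH",
  "V_FSH", "Ki_FSH_Inh", "w", "k_FSH", "c_FSH_P", "c_FSH_E", "a_FSH", "v",
  "b", "c1", "c2", "c3", "c4", "d1", "d2", "k1", "k2", "k3", "k4",
  "alpha", "beta", "gamma", "nu", "e0", "e1", "e2", "e3", "p0", "p1", "p2",
  "h0", "h1", "h2", "h3", "k_Inh", "tau"
)

.state_names <- c("RP_LH", "LH", "RP_FSH", "FSH", "RcF", "GrF", "DomF",
                  "Lut1", "Lut2", "Lut3", "Lut4", "Inh")

#' Path to the packaged model parameter file
#'
#' Returns the path of the versioned JSON parameter file shipped with the
#' package. The file bundles the baseline menstrual-cycle parameters, the
#' fitted circadian amplitudes/acrophases, the fitted EE and DNG
#' pharmacokinetic parameters, the relative-binding-affinity coefficients,
#' the day-0 initial conditions and the 3 ng/mL anovulation threshold. Every
#' simulation entry point requires an explicit parameter bundle loaded from
#' such a file, so that runs are always traceable to a checksummed source.
#'
#' @return Path to the JSON file.
#' @export
oc_param_file <- function() {
  system.file("extdata", "oc_params_v1.json", package = "chronOC",
              mustWork = TRUE)
}

.params_payload_checksum <- function(payload) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Load a model parameter bundle
#'
#' Reads a versioned parameter file (see [oc_param_file()]), verifies its
#' checksum, validates every invariant (positivity of rate constants and
#' output weights, positive delay, circadian amplitudes in `[0, 1)`,
#' pharmacokinetic rate ordering) and returns an `oc_params` bundle.
#'
#' @param path Path to a parameter JSON file. There is deliberately no
#'   default: simulations must name their parameter source.
#' @return An object of class `oc_params`.
#' @export
load_oc_params <- function(path) {
  if (missing(path) || !is.character(path) || length(path) != 1L)
    stop("an explicit parameter-file path is required")
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("meta", "baseline", "circadian", "rba", "pk",
            "initial_conditions", "threshold")
  if (!all(need %in% names(raw)))
    stop("parameter file is missing sections: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  payload <- raw[setdiff(names(raw), "meta")]
  sum_now <- .params_payload_checksum(payload)
  if (!identical(sum_now, raw$meta$checksum))
    stop("parameter-file checksum mismatch: file may have been edited (",
         sum_now, " != ", raw$meta$checksum, ")")
  baseline <- lapply(raw$baseline, as.numeric)
  if (!all(.param_order %in% names(baseline)))
    stop("baseline section lacks parameters: ",
         paste(setdiff(.param_order, names(baseline)), collapse = ", "))
  bl <- unlist(baseline[.param_order])
  if (any(!is.finite(bl)) || any(bl[setdiff(.param_order,
      c("gamma", "p0", "h0"))] <= 0))
    stop("baseline rate constants and weights must be strictly positive")
  if (bl[["tau"]] <= 0) stop("delay tau must be positive")
  circ <- oc_circadian(amplitude = unlist(raw$circadian$amplitude),
                       acrophase = unlist(raw$circadian$acrophase))
  pk <- list(
    EE = do.call(pk_params, c(raw$pk$EE, list(drug = "EE"))),
    DNG = do.call(pk_params, c(raw$pk$DNG, list(drug = "DNG")))
  )
  init <- unlist(raw$initial_conditions)
  if (!identical(sort(names(init)), sort(.state_names)))
    stop("initial_conditions must name exactly the 12 state components")
  init <- init[.state_names]
  if (any(init < 0)) stop("initial conditions must be nonnegative")
  structure(list(
    baseline = as.list(bl),
    circadian = circ,
    rba = list(r1 = as.numeric(raw$rba$r1), r2 = as.numeric(raw$rba$r2)),
    pk = pk,
    init = init,
    threshold = as.numeric(raw$threshold),
    meta = c(raw$meta, list(source_file = normalizePath(path)))
  ), class = "oc_params")
}

#' Write a model parameter bundle to disk
#'
#' Serializes an `oc_params` bundle to JSON with a fresh payload checksum.
#' Used to derive perturbed parameter files for sensitivity scenarios while
#' keeping the provenance guard intact.
#'
#' @param params An `oc_params` bundle.
#' @param path Output path.
#' @param note Optional provenance note stored in the `meta` section.
#' @return `path`, invisibly.
#' @export
save_oc_params <- function(params, path, note = NULL) {
  stopifnot(inherits(params, "oc_params"))
  payload <- list(
    baseline = params$baseline,
    circadian = list(amplitude = as.list(params$circadian$amplitude),
                     acrophase = as.list(params$circadian$acrophase)),
    rba = params$rba,
    pk = list(EE = unclass(params$pk$EE)[c("F", "Vc", "ka", "k21",
                                           "alpha1", "beta1", "conc_scale")],
              DNG = unclass(params$pk$DNG)[c("F", "Vc", "ka", "k21",
                                             "alpha1", "beta1", "conc_scale")]),
    initial_conditions = as.list(params$init),
    threshold = params$threshold
  )
  meta <- list(
    version = params$meta$version %||% "v1",
    description = params$meta$description %||% "model parameter bundle",
    note = note %||% params$meta$note %||% "",
    checksum = .params_payload_checksum(payload)
  )
  out <- c(list(meta = meta), payload)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run seeded code without disturbing the caller's RNG stream
.with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Circadian modulation parameters
#'
#' Bundles the four circadian amplitudes and acrophases (LH, FSH, E2, P4).
#' Amplitudes are dimensionless fractions of the mean level; acrophases are
#' clock times expressed as fractions of a day (model time is in days with
#' t = 0 at midnight of cycle day 0) and are reported modulo 1.
#'
#' @param amplitude Named or positional numeric vector of length 4
#'   (order LH, FSH, E2, P4), each in `[0, 1)`.
#' @param acrophase Numeric vector of length 4, in days.
#' @return An object of class `oc_circadian`.
#' @export
oc_circadian <- function(amplitude = c(0, 0, 0, 0),
                         acrophase = c(0, 0, 0, 0)) {
  amplitude <- as.numeric(amplitude)
  acrophase <- as.numeric(acrophase) %% 1
  if (length(amplitude) != 4L || length(acrophase) != 4L)
    stop("amplitude and acrophase must each have length 4 (LH, FSH, E2, P4)")
  if (any(amplitude < 0) || any(amplitude >= 1))
    stop("circadian amplitudes must lie in [0, 1)")
  structure(list(amplitude = stats::setNames(amplitude, .hormones),
                 acrophase = stats::setNames(acrophase, .hormones)),
            class = "oc_circadian")
}

.hormones <- c("LH", "FSH", "E2", "P4")

#' Per-hormone circadian rhythm switches
#'
#' Disabling a hormone's switch is exactly equivalent to setting its
#' circadian amplitude to zero.
#'
#' @param LH,FSH,E2,P4 Logical flags.
#' @return Named logical vector of class `oc_switches`.
#' @export
circadian_switches <- function(LH = TRUE, FSH = TRUE, E2 = TRUE, P4 = TRUE) {
  structure(c(LH = isTRUE(LH), FSH = isTRUE(FSH), E2 = isTRUE(E2),
              P4 = isTRUE(P4)), class = "oc_switches")
}

# flattened numeric parameter vector for the compiled code
.param_vec <- function(params) {
  v <- unlist(params$baseline[.param_order])
  c(v, r1 = params$rba$r1, r2 = params$rba$r2)
}

# switch-masked amplitudes
.eff_circadian <- function(circ, switches) {
  amp <- circ$amplitude
  amp[!as.logical(switches)] <- 0
  list(amp = unname(amp), phase = unname(circ$acrophase))
}

#' @export
print.oc_params <- function(x, ...) {
  cat("<oc_params> version", x$meta$version %||% "?",
      "checksum", substr(x$meta$checksum %||% "?", 1, 8), "\n")
  cat("  baseline:", length(x$baseline), "parameters; tau =",
      x$baseline$tau, "days\n")
  cat("  circadian amplitudes:",
      paste(sprintf("%s=%.3f", .hormones, x$circadian$amplitude),
            collapse = ", "), "\n")
  cat("  RBA: r1 =", x$rba$r1, " r2 =", x$rba$r2,
      "; threshold =", x$threshold, "ng/mL\n")
  invisible(x)
}
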