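# Shared fixtures: packaged parameters (loaded once) and random PK draws.

oc_test_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_oc_params(oc_param_file())
    cache
  }
})

# random valid PK parameter set: beta1 < k21 < alpha1 < ka, well separated
random_pk <- function(drug = "DNG") {
  beta1 <- stats::runif(1, 0.5, 3)
  k21 <- beta1 * stats::runif(1, 1.4, 3)
  alpha1 <- k21 * stats::runif(1, 1.4, 3)
  ka <- alpha1 * stats::runif(1, 1.5, 4)
  pk_params(Vc = stats::runif(1, 20, 300), ka = ka, k21 = k21,
            alpha1 = alpha1, beta1 = beta1,
            conc_scale = if (drug == "EE") 1000 else 1, drug = drug)
}

# brute-force tri-exponential sum, written independently of the package path
brute_conc <- function(t, dose_times, amounts, pk) {
  sapply(t, function(tt) {
    tot <- 0
    for (i in seq_along(dose_times)) {
      dt <- tt - dose_times[i]
      if (dt < 0) next
      N <- pk$ka * pk$F * (pk$k21 - pk$ka) /
        (pk$Vc * (pk$alpha1 - pk$ka) * (pk$beta1 - pk$ka))
      L <- pk$ka * pk$F * (pk$k21 - pk$alpha1) /
        (pk$Vc * (pk$ka - pk$alpha1) * (pk$beta1 - pk$alpha1))
      M <- pk$ka * pk$F * (pk$k21 - pk$beta1) /
        (pk$Vc * (pk$ka - pk$beta1) * (pk$alpha1 - pk$beta1))
      tot <- tot + amounts[i] * (N * exp(-pk$ka * dt) + L * exp(-pk$alpha1 * dt) +
                                 M * exp(-pk$beta1 * dt)) * pk$conc_scale
    }
    tot
  })
}
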