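# Independent baseline-model oracle: a fresh R transcription of the cycle
# equations integrated with deSolve::dede. Used only to cross-check the
# compiled integrator; shares no code with it.

oracle_rhs <- function(t, y, parlist) {
  p <- parlist$p
  exo <- parlist$exo  # function(t) -> c(e2, p4), or NULL
  ex <- if (is.null(exo)) c(0, 0) else exo(t)
  amp <- parlist$amp; phase <- parlist$phase
  fac <- function(i) 1 + amp[i] * cos(2 * pi * (t - phase[i]))
  E2 <- (p$e0 + p$e1 * y[6] + p$e2 * y[7] + p$e3 * y[11]) * fac(3) +
    parlist$r1 * ex[1]
  P4 <- (p$p0 + p$p1 * y[10] + p$p2 * y[11]) * fac(4) + parlist$r2 * ex[2]
  inh_lag <- if (t - p$tau <= 0) parlist$inh0 else
    deSolve::lagvalue(t - p$tau, 12)
  LH <- max(y[2], 0)
  synth_lh <- (p$V0_LH + p$V1_LH * E2^8 / (p$Km_LH^8 + E2^8)) /
    (1 + P4 / p$Ki_LH_P) * fac(1)
  rel_lh <- p$k_LH * (1 + p$c_LH_P * P4) * y[1] / (1 + p$c_LH_E * E2)
  synth_fsh <- p$V_FSH / (1 + inh_lag / p$Ki_FSH_Inh + P4 / p$w) * fac(2)
  rel_fsh <- p$k_FSH * (1 + p$c_FSH_P * P4) * y[3] /
    (1 + p$c_FSH_E * E2^2)
  ovul <- p$d2 * LH^p$nu
  list(c(
    synth_lh - rel_lh,
    rel_lh / p$v - p$a_LH * y[2],
    synth_fsh - rel_fsh,
    rel_fsh / p$v - p$a_FSH * y[4],
    p$b * y[4] + (p$c1 * y[4] - p$c2 * LH^p$alpha) * y[5],
    p$c2 * LH^p$alpha * y[5] + (p$c3 * LH^p$beta - p$c4 * LH) * y[6],
    p$c4 * LH * y[6] + (p$d1 * LH^p$gamma - ovul) * y[7],
    ovul * y[7] - p$k1 * y[8],
    p$k1 * y[8] - p$k2 * y[9],
    p$k2 * y[9] - p$k3 * y[10],
    p$k3 * y[10] - p$k4 * y[11],
    p$k_Inh * (p$h0 + p$h1 * y[7] + p$h2 * y[10] + p$h3 * y[11] - y[12])
  ))
}

oracle_simulate <- function(params, days, init = params$init,
                            amp = c(0, 0, 0, 0), phase = c(0, 0, 0, 0),
                            exo = NULL, dt = 0.05) {
  parlist <- list(p = params$baseline, amp = amp, phase = phase,
                  r1 = params$rba$r1, r2 = params$rba$r2,
                  inh0 = unname(init[["Inh"]]), exo = exo)
  out <- deSolve::dede(unname(init), seq(0, days, by = dt), oracle_rhs,
                       parlist, method = "lsoda",
                       rtol = 1e-9, atol = 1e-9)
  colnames(out) <- c("time", names(init))
  out
}

oracle_observables <- function(out, params) {
  b <- params$baseline
  list(E2 = b$e0 + b$e1 * out[, "GrF"] + b$e2 * out[, "DomF"] +
         b$e3 * out[, "Lut4"],
       P4 = b$p0 + b$p1 * out[, "Lut3"] + b$p2 * out[, "Lut4"])
}
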