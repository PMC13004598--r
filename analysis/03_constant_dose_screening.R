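#!/usr/bin/env Rscript
# Step 3: constant-dose anovulation screening — the dosing-time sweep of
# minimal effective doses, the daytime/evening contrast, and the
# threshold-straddling probe regimens.
library(chronOC)

dir.create("results", showWarnings = FALSE)
params <- load_oc_params(oc_param_file())

## minimal-dose sweep over all 24 clock hours (fine EE axis, 3 cycles)
sweep <- dosing_time_sweep(params, times = 1:24, n_cycles = 3,
                           ee_axis = seq(0, 30, by = 0.6), dng_axis = 0,
                           rtol = 1e-6, atol = 1e-6, out_dt = 0.05)
write.csv(sweep$table, "results/03_dosing_time_sweep.csv",
          row.names = FALSE)
print(sweep$table, row.names = FALSE)
cat(sprintf("\nBest dosing time: %02d:00; achievable times: %d of 24\n",
            sweep$summary$best_time, sum(sweep$table$achievable %in% TRUE)))

## fine minimal doses at the reference daytime/evening hours, 10 cycles
for (tt in c(11, 22)) {
  r <- minimal_constant_dose(tt, params, n_cycles = 10,
                             rtol = 1e-6, atol = 1e-6, out_dt = 0.05)
  if (r$achievable) {
    cat(sprintf("%02d:00 -> minimal daily (EE %.1f, DNG %.0f) ug\n",
                tt, r$ee_daily, r$dng_daily))
    write.csv(r$frontier, sprintf("results/03_frontier_%02d.csv", tt),
              row.names = FALSE)
  } else {
    cat(sprintf("%02d:00 -> no anovulatory dose within the market box\n",
                tt))
  }
}

## threshold behaviour of the probe regimens, per cycle
probes <- expand.grid(ee = c(25, 28.2), dng = c(320, 1000),
                      time = c(11, 22))
rows <- lapply(seq_len(nrow(probes)), function(i) {
  pc <- per_cycle_max_p4(constant_regimen(probes$ee[i], probes$dng[i],
                                          probes$time[i]),
                         params, n_cycles = 3)
  data.frame(probes[i, ], cycle1 = pc[1], cycle2 = pc[2], cycle3 = pc[3])
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/03_probe_regimens.csv", row.names = FALSE)
print(tab, row.names = FALSE)
cat("\nThe 28.2/320 regimen stays below 3 ng/mL in all three cycles at\n",
    "11:00 but breaks through from cycle 2 at 22:00; the weaker probes\n",
    "relapse in cycle 2 at either time.\n")
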