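#!/usr/bin/env Rscript
# Calibration of the three model settings the reaction scheme leaves
# open: the membrane boundary concentration, the membrane undocking rate
# (reported both as 0.1 and as 1 s^-1 in different places), and the
# window of the simulated initial-rate estimator.
#
# The anchor is the location of the interior maximum of the non-exchange
# PS transfer rate (3.7 uM^-1 s^-1) together with the PS acceleration
# factor at that maximum (0.13). Finding: the maximum's location barely
# depends on the membrane concentration (docking is fast and saturating
# for M >= 1 uM), moves strongly with the estimator window, and the
# acceleration factor selects the slower undocking rate (0.1 s^-1) —
# with 1 s^-1 the acceleration at the anchored maximum drops to ~0.09.
# A 0.55 s window at M = 100 uM, k_OFF-Mb = 0.1 s^-1 reproduces both
# anchors; these are the package defaults.

suppressPackageStartupMessages(library(ordflux))
dir.create("results", showWarnings = FALSE)

message("grid calibration over membrane concentration, undocking rate, window ...")
cal <- calibrate_sweep_maximum(membrane_grid = c(1, 10, 100, 200),
                               k_off_mb_grid = c(0.1, 1),
                               window_grid = c(0.5, 0.55, 4, 60))
write.csv(cal, "results/calibration.csv", row.names = FALSE)
print(cal, digits = 3)

best <- cal[which.min(abs(cal$argmax_kon_ps - 3.7)), ]
message(sprintf(
  "closest to the 3.7 uM^-1 s^-1 anchor: M = %g uM, k_OFF-Mb = %g s^-1, window = %g s (argmax %.3f, acceleration %.3f)",
  best$m_uM, best$k_off_mb, best$window_s, best$argmax_kon_ps,
  best$accel_ps_at_max))
message("written: results/calibration.csv")
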