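#!/usr/bin/env Rscript
# Calibration carry-over (tidal chest-wall elastance calibrated at ZEEP,
# evaluated at PEEP 8), the isolated-lung alignment and the worked example
# comparing conventional and PEEP-step transpulmonary pressure.
# Outputs: results/calibration_checks.csv, results/worked_example.csv

library(peepstep)
dir.create("results", showWarnings = FALSE)

out <- list()
for (mode in c("normal", "stiff")) {
  target <- if (mode == "normal") 18 else 24
  cfg <- model_config(
    lung = lung_params(2),
    chest_wall = chest_wall_params(wall_compliance = 50,
                                   strapped = mode == "stiff"))
  cfg <- calibrate_static_recoil(cfg, 1.5)
  cal <- calibrate_chest_wall(cfg, target)
  ecw_at <- sapply(c(0, 4, 8, 12), function(p) {
    wf <- simulate_breaths(cal, rep(p, 25))
    tidal_elastances(tail(segment_breaths(wf), 1))$ecw
  })
  out[[mode]] <- data.frame(mode = mode, target = target,
                            wall_compliance = cal$chest_wall$wall_compliance,
                            ecw_peep0 = ecw_at[1], ecw_peep4 = ecw_at[2],
                            ecw_peep8 = ecw_at[3], ecw_peep12 = ecw_at[4])
}
checks <- do.call(rbind, out)
write.csv(checks, "results/calibration_checks.csv", row.names = FALSE)
cat("Tidal chest-wall elastance after calibration at ZEEP only:\n")
print(checks, digits = 4)
cat("\nThe value carries over unchanged to every PEEP level: tidal chest-wall\n",
    "stiffness reflects displacing the same mass at any operating volume.\n")

# isolated lung vs intact model: the end-expiratory airway P/V points of the
# intact model lie on the isolated-lung P/V line
cfg <- make_default_config(2, "normal")
iso <- isolated_lung_mode(cfg)
wf_iso <- simulate_breaths(iso, rep(c(5, 13.4), each = 25))
wf_full <- simulate_breaths(cfg, rep(c(0, 8.4), each = 25))
bi <- segment_breaths(wf_iso); bf <- segment_breaths(wf_full)
dv_iso <- mean(tail(bi$vlung_ee, 5)) - mean(bi$vlung_ee[21:25])
dv_full <- mean(tail(bf$vlung_ee, 5)) - mean(bf$vlung_ee[21:25])
cat(sprintf(paste0("\nIsolated lung, PEEP 5 -> 13.4: dEELV %.0f ml;",
                   " intact model, 0 -> 8.4: %.0f ml\n",
                   "pressure deviation at matched volume: %.2f cmH2O\n"),
            dv_iso, dv_full, 8.4 * (1 - dv_full / dv_iso)))

ex <- tidal_vs_peepstep_example()
write.csv(ex, "results/worked_example.csv", row.names = FALSE)
cat("\nWorked example, end-inspiratory transpulmonary pressure:\n")
print(ex, digits = 3)
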