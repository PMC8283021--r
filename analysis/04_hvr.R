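#!/usr/bin/env Rscript
# Step 4 — hypoxic ventilatory response.
#
# One normoxia->hypoxia challenge per animal (20 min at 21% FiO2, then
# 5 min at 10% FiO2): breath segmentation of the plethysmography airflow,
# body-weight-normalized minute ventilation in the normoxic reference and
# hypoxic (onset+30 s to onset+120 s) windows, and the HVR as the pooled
# least-squares slope of V_E on SpO2. Expected from the presets:
# VE 1.2 -> ~2.9-3.0 mL/min/g, HVR ~0.05 mL/min/g/%.

suppressMessages(library(cardioresp))
dir.create("results", showWarnings = FALSE)

run_animal <- function(preset, id, group, seed) {
  rec <- gen_hvr_session(preset, rate_flow = 200, rate_spo2 = 5, seed = seed,
                         group = group)
  r <- compute_hvr(rec)
  data.frame(animal = id, group = group, ve_normoxia = r$ve_normoxia,
             ve_hypoxia = r$ve_hypoxia, spo2_normoxia = r$spo2_normoxia,
             spo2_hypoxia = r$spo2_hypoxia, hvr = r$hvr,
             hvr_truth = rec$annotations$hvr)
}

rows <- rbind(
  do.call(rbind, lapply(1:8, function(i)
    run_animal(preset_nzo_baseline(), sprintf("c%02d", i), "control",
               4000L + i))),
  do.call(rbind, lapply(1:6, function(i)
    run_animal(preset_alloaca_treated(), sprintf("t%02d", i), "treated",
               4100L + i))))
write.csv(rows, "results/hvr_per_animal.csv", row.names = FALSE)

for (g in unique(rows$group)) {
  r <- rows[rows$group == g, ]
  cat(sprintf("%s: VE %.2f -> %.2f mL/min/g, HVR %.3f +/- %.3f\n", g,
              mean(r$ve_normoxia), mean(r$ve_hypoxia), mean(r$hvr),
              sem(r$hvr)))
}
cat("wrote results/hvr_per_animal.csv\n")
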