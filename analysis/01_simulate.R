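#!/usr/bin/env Rscript
# Step 1 — define the study conditions.
#
# The two presets encode the study arms: an untreated hypertensive-obese
# baseline (light/dark MAP 134.9/137.5 mmHg, NREM breathing 0.3 mL at
# 107.5 breaths/min, apneas at 31.4/h of sleep, normoxic/hypoxic
# ventilation 1.2/2.9 mL/min/g) and a leptin-receptor-blocker-treated arm
# (light/dark MAP 124.9/127.9 mmHg). This script materializes the preset
# library as YAML configs and writes one short demonstration
# polysomnography session to EDF with its JSON ground-truth sidecar.
# The downstream scripts regenerate cohorts deterministically from these
# presets, so no bulk signal files change hands.

suppressMessages(library(cardioresp))

dir.create("results/presets", showWarnings = FALSE, recursive = TRUE)
dir.create("scratch", showWarnings = FALSE)

baseline <- preset_nzo_baseline()
treated <- preset_alloaca_treated()
write_preset(baseline, "results/presets/nzo-baseline.yaml")
write_preset(treated, "results/presets/alloaca-treated.yaml")
print(baseline)
print(treated)

# determinism check: one preset + seed must reproduce bit-identical signals
a <- gen_hr_series(baseline, duration_s = 60, rate = 100)
b <- gen_hr_series(baseline, duration_s = 60, rate = 100)
stopifnot(identical(a$values, b$values))
cat("determinism: identical (preset, seed) -> identical samples\n")

# a 30-min demo sleep session, written to EDF + ground-truth sidecar
demo <- gen_sleep_session(baseline, duration_h = 0.5, rate_flow = 200,
                          rate_eeg = 100, rate_emg = 100, rate_spo2 = 5,
                          seed = 1001L)
write_edf(demo, "scratch/demo_sleep.edf")
write_ground_truth(list(
  hypnogram = as.character(demo$annotations$hypnogram),
  events = demo$annotations$events), "scratch/demo_sleep_truth.json")
cat("wrote scratch/demo_sleep.edf +",
    nrow(demo$annotations$events), "ground-truth events\n")
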