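#!/usr/bin/env Rscript
# Step 5 — polysomnography: staging, architecture, ventilation and SDB.
#
# One 6-h light-phase session per animal (three per arm here; each session
# is ~40 s of compute at the reduced channel rates). Pipeline: EEG/EMG
# staging in 10-s epochs, sleep architecture, REM/NREM analysis windows,
# breath metrics within them, apnea detection (>=90% reduction, >=2 cycles
# or >=0.7 s), apnea index, desaturations (>=5 points) and ODI.

suppressMessages(library(cardioresp))
dir.create("results", showWarnings = FALSE)

run_animal <- function(preset, id, group, seed) {
  rec <- gen_sleep_session(preset, duration_h = 6, rate_flow = 200,
                           rate_eeg = 100, rate_emg = 100, rate_spo2 = 5,
                           seed = seed, group = group)
  hyp <- score_epochs(rec$traces$eeg, rec$traces$emg)
  arch <- architecture(hyp)
  agree <- mean(as.character(hyp) ==
                  as.character(rec$annotations$hypnogram))

  breaths <- segment_breaths(rec$traces$flow)
  breaths <- detect_ifl(breaths, rec$traces$flow, rec$traces$effort)
  wins <- select_analysis_windows(hyp)
  in_windows <- function(type) {
    w <- wins[wins$type == type, ]
    sel <- rep(FALSE, nrow(breaths))
    for (k in seq_len(nrow(w)))
      sel <- sel | (breaths$onset >= w$start_s[k] &
                      breaths$onset < w$start_s[k] + w$duration_s[k])
    breaths[sel, ]
  }
  nrem <- in_windows("NREM"); rem <- in_windows("REM")
  ap <- detect_apneas(rec$traces$flow, hyp, breaths = breaths)
  de <- desaturation_events(rec$traces$spo2, hyp)

  data.frame(
    animal = id, group = group, staging_agreement = agree,
    tst_min = arch$tst_min, pct_nrem = arch$pct_nrem,
    pct_rem = arch$pct_rem, efficiency_pct = arch$efficiency_pct,
    nrem_vt = mean(nrem$V_T), nrem_rr = mean(nrem$RR),
    nrem_mifr = mean(nrem$MIFR), nrem_dc = mean(nrem$DC),
    nrem_ifl_pct = 100 * mean(nrem$ifl),
    rem_vt = mean(rem$V_T), rem_rr = mean(rem$RR),
    rem_ifl_pct = 100 * mean(rem$ifl),
    ve_norm_nrem = minute_ventilation(nrem, rec$body_weight_g)$ve_norm,
    apnea_index = apnea_index(ap, arch), odi = de$odi,
    mean_spo2_nrem = unname(de$mean_spo2["NREM"]),
    mean_spo2_rem = unname(de$mean_spo2["REM"]))
}

rows <- rbind(
  do.call(rbind, lapply(1:3, function(i)
    run_animal(preset_nzo_baseline(), sprintf("c%02d", i), "control",
               5000L + i))),
  do.call(rbind, lapply(1:3, function(i)
    run_animal(preset_alloaca_treated(), sprintf("t%02d", i), "treated",
               5100L + i))))
write.csv(rows, "results/sleep_per_animal.csv", row.names = FALSE)

cat(sprintf("staging agreement vs ground truth: %.1f%% (min %.1f%%)\n",
            100 * mean(rows$staging_agreement),
            100 * min(rows$staging_agreement)))
cat(sprintf("TST %.0f min, NREM %.1f%%, apnea index %.1f/h, ODI %.1f/h\n",
            mean(rows$tst_min), mean(rows$pct_nrem),
            mean(rows$apnea_index), mean(rows$odi)))
cat("wrote results/sleep_per_animal.csv\n")
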