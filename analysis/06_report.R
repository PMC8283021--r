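#!/usr/bin/env Rscript
# Step 6 — study-level report.
#
# Collects the per-animal tables written by steps 2-5 into one tidy report
# (group mean +/- SEM per outcome, two-sided Mann-Whitney p between arms),
# with sections that were not run reported as explicit gaps.

suppressMessages(library(cardioresp))

read_if <- function(path) if (file.exists(path)) read.csv(path) else NULL

sections <- list(
  bp = {
    bp <- read_if("results/bp_per_animal.csv")
    if (!is.null(bp)) bp[bp$phase == "light",
                         c("animal", "group", "map", "sbp", "dbp", "hr")]
  },
  hrv = read_if("results/hrv_per_animal.csv"),
  hvr = read_if("results/hvr_per_animal.csv"),
  sleep = read_if("results/sleep_per_animal.csv"))

rep <- study_report(sections)
write_report(rep, "results/report")
if (length(rep$gaps))
  cat("sections missing (run the earlier steps):",
      paste(rep$gaps, collapse = ", "), "\n")
for (nm in names(rep$tables)) {
  cat("\n==", nm, "==\n")
  print(rep$tables[[nm]]$summary, digits = 3, row.names = FALSE)
}
cat("\nwrote results/report/\n")
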