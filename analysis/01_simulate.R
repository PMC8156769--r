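#!/usr/bin/env Rscript

# Stage 1 — simulate the study cohort.
#
# Generates eight synthetic runners, each performing the track protocol:
# a 10-lap run of 400 m laps at constant speed, a standing gap where the
# variable-length fatiguing run sits (excluded from analysis), and a
# 3-lap post-fatigue run, all at 240 Hz. Writes each session to
# results/sessions/<subject>/ in the package's columnar layout plus the
# per-session ground truth.

suppressPackageStartupMessages(library(runfatigue))

seed <- 1
out_dir <- "results/sessions"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

effects <- fatigue_effect_model()   # literature-inspired default shifts
sims <- generate_cohort(8, effects, seed = seed)

for (sim in sims) {
  rec <- sim$recording
  path <- file.path(out_dir, rec$subject_id)
  write_session(rec, path)
  jsonlite::write_json(
    list(right_ics = sim$truth$right_ics,
         left_ics = sim$truth$left_ics,
         run_bounds = sim$truth$run_bounds,
         lap_conditions = sim$truth$lap_conditions),
    file.path(path, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  message(sprintf("%s: %.0f s at %.1f km/h, %d strides, laps %s",
                  rec$subject_id, session_duration(rec), rec$nominal_speed,
                  nrow(sim$truth$strides),
                  paste(range(rec$laps$lap), collapse = "-")))
}
message("wrote ", length(sims), " sessions under ", out_dir)
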