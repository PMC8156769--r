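#!/usr/bin/env Rscript

# Stage 2 — segment gait and build the modelling table.
#
# For every simulated session under results/sessions/: detect the two runs
# from the pelvis velocity, find stride events and initial contacts, cut
# 150-point gait cycles, and extract the 157-feature vector per stride.
# Then smooth every feature over one lap (400 m, causal window, per run),
# keep the labeled laps, and z-score per subject. Writes the raw
# stride-level table and the prepared modelling table.

suppressPackageStartupMessages(library(runfatigue))

session_dirs <- list.dirs("results/sessions", recursive = FALSE)
if (length(session_dirs) == 0L)
  stop("no sessions found; run analysis/01_simulate.R first")

stride_tbl <- do.call(rbind, lapply(session_dirs, function(p) {
  rec <- read_session(p)
  sf <- session_features(rec)
  message(sprintf("%s: %d strides, labels: %s", rec$subject_id, nrow(sf),
                  paste(sprintf("%s=%d", names(table(sf$label)),
                                table(sf$label)), collapse = " ")))
  sf
}))

write_feature_table(stride_tbl, "results/stride_features.csv")

prepared <- prepare_feature_table(stride_tbl)
write_feature_table(prepared, "results/modelling_table.csv")
message(sprintf(
  "modelling table: %d rows x %d features (run-3 lap 1 dropped by the one-lap smoother)",
  nrow(prepared), length(intersect(feature_names(), names(prepared)))))
print(table(prepared$subject_id, prepared$label))
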