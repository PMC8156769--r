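#!/usr/bin/env Rscript

# Stage 4 — collate the headline outputs.
#
# Reads the evaluation bundles from stage 3 and prints/writes the
# paper-style outputs: the accuracy summary across sensor configurations,
# per-class metrics for the best configuration of each category, the
# aggregate confusion matrices, and the five top-ranked features per
# configuration.

suppressPackageStartupMessages(library(runfatigue))

summary <- data.table::fread("results/evaluation/summary.csv")
message("accuracy by configuration:")
print(summary)

bundles <- list.dirs("results/evaluation", recursive = FALSE)
ranks <- list()
for (b in bundles) {
  rep <- jsonlite::read_json(file.path(b, "report.json"),
                             simplifyVector = TRUE)
  cm <- data.table::fread(file.path(b, "confusion.csv"))
  message("\n== ", rep$configuration, " (", rep$category, ") ==")
  message("aggregate confusion matrix (rows = true):")
  print(cm)
  met <- as.data.frame(rep$metrics)
  print(met[, c("class", "sensitivity_mean", "specificity_mean",
                "precision_mean", "f1_mean")])
  sel <- data.table::fread(file.path(b, "selected_features.csv"))
  top <- sort(table(sel$feature), decreasing = TRUE)
  ranks[[rep$configuration]] <- data.frame(
    configuration = rep$configuration,
    rank = seq_len(min(5, length(top))),
    feature = names(top)[seq_len(min(5, length(top)))],
    folds_selected = as.integer(top)[seq_len(min(5, length(top)))])
}
rank_tbl <- do.call(rbind, ranks)
data.table::fwrite(rank_tbl, "results/top_features.csv")
message("\ntop-5 selected features per configuration written to results/top_features.csv")
print(rank_tbl, row.names = FALSE)
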