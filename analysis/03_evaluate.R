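#!/usr/bin/env Rscript

# Stage 3 — nested leave-one-subject-out evaluation.
#
# Evaluates one representative sensor configuration per comparison
# category (single left tibia; left thigh + tibia; both thighs + tibias;
# whole body) on the modelling table from stage 2. Each outer fold holds
# one subject out; the inner loop selects the 12 best features by OOB
# permutation importance averaged over validation subjects. Writes one
# report bundle per configuration and a cross-configuration summary.
#
# Evaluating all 28 comparison configurations works the same way
# (configurations = unlist(reference_configurations(), recursive = FALSE))
# but takes correspondingly longer.

suppressPackageStartupMessages(library(runfatigue))

tbl <- read_feature_table("results/modelling_table.csv")
tbl$label <- factor(tbl$label, levels = fatigue_levels())

configurations <- list("L6", c("L4", "L6"), c("L3", "L4", "L5", "L6"),
                       names(location_codes()))

res <- run_pipeline(table = tbl, seed = 1, configurations = configurations,
                    out_dir = "results/evaluation")
print(res$summary)
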