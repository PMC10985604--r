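#!/usr/bin/env Rscript
# Step 2: reload the recorded trials and run the kinematic layer.
#
# Reads the TRC study written by step 1 back through the manifest (so the
# whole file-format path is exercised), detects gait events, screens trial
# validity, keeps the first six valid trials per cell, and extracts every
# spatiotemporal task parameter.  Writes the per-trial parameter table,
# validity verdicts, participant summaries, per-participant condition
# differences and failure totals to results/.

library(obstaclegait)

manifest <- "scratch/synthetic_study/manifest.tsv"
if (!file.exists(manifest)) stop("run analysis/01_simulate.R first")

message("loading study from ", manifest, " ...")
ds <- load_study(manifest)
message(length(ds$trials), " trials loaded; running the pipeline ...")

res <- run_pipeline(ds)

write.csv(res$trial_parameters, "results/trial_parameters.csv", row.names = FALSE)
write.csv(res$validity, "results/validity.csv", row.names = FALSE)
write.csv(res$summaries, "results/participant_summaries.csv", row.names = FALSE)
write.csv(res$differences, "results/differences.csv", row.names = FALSE)
write.csv(res$failures, "results/failures.csv", row.names = FALSE)
write.csv(res$condition_stats, "results/condition_stats.csv", row.names = FALSE)
write.csv(res$log, "results/pipeline_log.csv", row.names = FALSE)

message(sprintf("analysed %d trials (%d invalid); %d warnings logged",
                nrow(unique(res$trial_parameters[, c("participant_id", "condition",
                                                     "task", "trial_index")])),
                sum(!res$validity$valid), nrow(res$log)))
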