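#!/usr/bin/env Rscript
# Step 1: simulate the study cohort.
#
# Generates the full two-condition obstacle-course dataset under the study
# protocol: 20 children, both conditions, five tasks, eight recorded trials
# per task and condition, 100 Hz capture with 1 mm marker jitter, VR
# condition effects taken from the published difference column.  Trial
# trajectories (TRC) and the manifest go to scratch/ (large, regenerable);
# small summary tables go to results/.

library(obstaclegait)

SEED <- 20240318
out_scratch <- "scratch/synthetic_study"
dir.create("results", showWarnings = FALSE)
dir.create(out_scratch, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(n_participants = 20, rng_seed = SEED)
message("simulating ", cfg$n_participants, " participants x 2 conditions x ",
        "5 tasks x ", cfg$trials_per_task, " trials ...")
ds <- simulate_study(cfg)

manifest <- write_study(ds, out_scratch)
message("wrote ", length(ds$trials), " TRC trials + manifest: ", manifest)

write.csv(ds$participants, "results/participants.csv", row.names = FALSE)

# the injected participant-level VR shifts (ground truth for step 3)
shift_tb <- do.call(rbind, lapply(names(ds$shifts), function(nm) {
  tp <- strsplit(nm, ".", fixed = TRUE)[[1]]
  data.frame(task = tp[1], parameter = tp[2],
             participant_id = ds$participants$participant_id,
             injected_shift = ds$shifts[[nm]])
}))
write.csv(shift_tb, "results/injected_shifts.csv", row.names = FALSE)

message("condition order balance:")
print(table(ds$participants$condition_order))
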