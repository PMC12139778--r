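#!/usr/bin/env Rscript
## Step 3: rule-based photobleaching step counting on the extracted traces.
##
## Applies the labeling rules — a step is a stepwise, sustained (>25 count)
## decrease; counting stops early at the first upward step — to every
## colocalized trace from 02_detect_colocalize.R, bins the counts into the
## channel-specific classes, and estimates the per-channel bleach
## half-time from first-step survival.

suppressMessages(library(simpullr))

tr_g <- as.matrix(read.csv("results/field01_traces_green.csv", check.names = FALSE))
tr_f <- as.matrix(read.csv("results/field01_traces_farred.csv", check.names = FALSE))
pairs <- read.csv("results/field01_pairs.csv")

lab_g <- classify_traces_oracle(tr_g[, as.character(pairs$green_id), drop = FALSE],
                                "green")
lab_f <- classify_traces_oracle(tr_f[, as.character(pairs$farred_id), drop = FALSE],
                                "farred")

labels <- data.frame(
  pair_id = pairs$pair_id,
  green_id = pairs$green_id, farred_id = pairs$farred_id,
  green_class = as.character(lab_g$labels),
  farred_class = as.character(lab_f$labels),
  farred_steps = vapply(lab_f$annotations, `[[`, 0L, "raw_step_count"),
  farred_early_stop = vapply(lab_f$annotations, `[[`, TRUE, "early_stopped"))
write.csv(labels, "results/field01_oracle_labels.csv", row.names = FALSE)

cat("green classes:\n"); print(table(labels$green_class))
cat("far-red classes:\n"); print(table(labels$farred_class))

ht_f <- try(bleach_half_time(lab_f$annotations, frame_rate = 20), silent = TRUE)
if (!inherits(ht_f, "try-error")) {
  cat(sprintf("far-red bleach half-time: %.0f frames (%.1f s) from %d traces\n",
              ht_f$halftime_frames, ht_f$halftime_seconds, ht_f$n_traces))
}
ht_g <- try(bleach_half_time(lab_g$annotations, frame_rate = 20), silent = TRUE)
if (!inherits(ht_g, "try-error")) {
  cat(sprintf("green bleach half-time:   %.0f frames (%.1f s) from %d traces\n",
              ht_g$halftime_frames, ht_g$halftime_seconds, ht_g$n_traces))
}
cat("wrote results/field01_oracle_labels.csv\n")
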