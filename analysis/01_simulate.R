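#!/usr/bin/env Rscript
# Step 1 — simulate the study's data.
#
# Builds (a) a small EEG cohort whose condition cells follow the hybrid
# latency-ordering scenario at encoding (the simple feature, color, gains a
# 70-ms head start only while attended), written as plain-text epoch-set
# directories, and (b) per-subject behavioral context-memory responses for
# the d-prime analyses. Sizes are kept small so the whole workflow runs in
# minutes; every number downstream is recomputed from these files.

suppressPackageStartupMessages(library(oscmvpa))

out_root <- "results/analysis"
epoch_dir <- file.path(out_root, "epochs")
dir.create(epoch_dir, showWarnings = FALSE, recursive = TRUE)

seed <- 20260921
n_subjects <- 6

base <- simulation_spec(
  n_channels = 8,
  channel_names = c("O1", "O2", "PO3", "PO4", "P3", "P4", "Pz", "Cz"),
  n_trials_per_class = c(correct = 48, incorrect = 32),
  effect_band = "beta", effect_size = 5, effect_window = c(450, 600))

offsets <- scenario_offsets("hybrid", offset = 70, phase = "encoding")
cohort <- generate_cohort(n_subjects, base, offsets, seed = seed)

for (subj in cohort$subjects) {
  for (cell in names(subj$epochs)) {
    tag <- paste(subj$subject_id, gsub("\\.", "_", cell), sep = "_")
    write_epoch_set(subj$epochs[[cell]], file.path(epoch_dir, tag))
  }
}
write.table(cohort$ground_truth, file.path(out_root, "ground_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# Behavioral responses: targets well above chance, distractors near it,
# mirroring the attention manipulation's behavioral signature.
beh <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
  rbind(
    cbind(subject_id = sprintf("s%02d", s),
          generate_behavioral_responses(
            behavioral_sim_spec(36, 36, 0.84, 0.25,
                                seed = derive_seed(seed, s, 1)),
            feature = "color", role = "target")),
    cbind(subject_id = sprintf("s%02d", s),
          generate_behavioral_responses(
            behavioral_sim_spec(36, 36, 0.55, 0.45,
                                seed = derive_seed(seed, s, 2)),
            feature = "color", role = "distractor")))
}))
write.table(beh, file.path(out_root, "behavior.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated %d subjects x %d condition cells -> %s\n",
            n_subjects, nrow(offsets), epoch_dir))
cat(sprintf("Ground-truth effect windows span %d-%d ms; hybrid offsets: %s\n",
            min(cohort$ground_truth$window_start),
            max(cohort$ground_truth$window_end),
            paste(offsets$offset_ms, collapse = "/")))
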