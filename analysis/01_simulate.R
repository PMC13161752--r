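#!/usr/bin/env Rscript

# Step 1 — simulate the study cohort.
#
# Generates the default two-group synthetic frontal-EEG cohort (20 propofol +
# 20 sevoflurane subjects, 30 non-overlapping 30-s epochs each at 250 Hz)
# with between-subject variation drawn from the drug-specific presets and
# artifacts injected at the 3.4% rate. Everything downstream regenerates the
# same cohort from the seed, so only the ground truth is written here.

suppressPackageStartupMessages(library(anesEEG))

SEED <- 42
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(seed = SEED)
print(cohort)

gt <- cohort$ground_truth
truth <- do.call(rbind, lapply(gt$subjects, function(sp) data.frame(
  subject_id = sp$subject_id, group = sp$group,
  offset = sp$aperiodic$offset, exponent = sp$aperiodic$exponent,
  alpha_center_hz = sp$peaks$alpha$center_hz,
  slow_power = sp$peaks$slow$power_uv2,
  theta_power = sp$peaks$theta$power_uv2,
  alpha_power = sp$peaks$alpha$power_uv2,
  beta_power = sp$peaks$beta$power_uv2,
  n_epochs = sp$n_epochs, stringsAsFactors = FALSE)))
write.csv(truth, "results/ground_truth_subjects.csv", row.names = FALSE)
write.csv(gt$artifact_labels, "results/ground_truth_artifacts.csv",
          row.names = FALSE)

rate <- mean(gt$artifact_labels$label != "clean")
cat(sprintf("Injected artifact epochs: %d/%d (%.2f%%; %d dropout, %d cautery)\n",
            sum(gt$artifact_labels$label != "clean"),
            nrow(gt$artifact_labels), 100 * rate,
            sum(gt$artifact_labels$label == "dropout"),
            sum(gt$artifact_labels$label == "cautery")))
cat(sprintf("Group-mean drawn exponents: propofol %.3f, sevoflurane %.3f\n",
            mean(truth$exponent[truth$group == "propofol"]),
            mean(truth$exponent[truth$group == "sevoflurane"])))
cat("Wrote results/ground_truth_subjects.csv and results/ground_truth_artifacts.csv\n")
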