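#!/usr/bin/env Rscript
# Simulate a full synthetic study of the flickering-luminance change-of-mind
# task: 4 participants x 5 sessions x 1000 trials, behaviour generated by the
# stimulus-coupled extended DDM driven by the very luminance residuals that
# are written to disk. Downstream scripts read this dataset.

suppressPackageStartupMessages(library(comddm))

dir.create("results", showWarnings = FALSE)
design <- study_design(seed = 1)
cat("Simulating", design$n_participants, "participants x",
    design$sessions_per_participant, "sessions x",
    design$trials_per_session, "trials ...\n")
ds <- generate_dataset(design)
write_dataset(ds, "results/dataset")

resp <- ds$trials[ds$trials$responded, ]
typed <- classify_response(resp)
summary_tbl <- data.frame(
  quantity = c("trials", "non_response_pct", "initial_accuracy_pct",
               "com_rate_pct", "corrected_error_pct", "spoilt_correct_pct",
               "median_initial_rt_s", "median_com_latency_s"),
  value = round(c(
    nrow(ds$trials),
    mean(!ds$trials$responded) * 100,
    mean(resp$initial_choice == resp$correct_side) * 100,
    mean(resp$n_changes >= 1) * 100,
    mean(typed$response_type == "corrected_error") * 100,
    mean(typed$response_type == "spoilt_correct") * 100,
    median(resp$initial_rt),
    median(resp$com_latency, na.rm = TRUE)), 3))
write.csv(summary_tbl, "results/dataset_summary.csv", row.names = FALSE)
print(summary_tbl, row.names = FALSE)
cat("\nDataset written to results/dataset/; summary to",
    "results/dataset_summary.csv\n")
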