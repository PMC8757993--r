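#!/usr/bin/env Rscript
# Model-predicted psychophysical kernels for the three extended-DDM variants
# (stimulus-coupled drift variability, decoupled variability, no
# variability), and the first-frame contrast that separates them: only the
# coupled variant predicts weaker first-frame support for the initial
# response on change-of-mind trials.

suppressPackageStartupMessages(library(comddm))

dir.create("results", showWarnings = FALSE)
preset <- preset_study_like()
cfg <- task_config()
n <- 100000

rows <- list()
for (v in c("coupled", "decoupled", "novar")) {
  cat("Simulating", n, "trials from the", v, "variant ...\n")
  set.seed(7)
  sim <- simulate_experiment(preset, v, cfg, n_trials = n)
  trials <- classify_response(sim$trials)
  k <- compute_kernels(trials, sim$stim_noise, lock = "stimulus",
                       config = cfg)
  k$variant <- v
  rows[[paste0("k_", v)]] <- k
  fc <- first_frame_contrast(trials, sim$stim_noise, n_boot = 500)
  rows[[paste0("c_", v)]] <- data.frame(
    variant = v, contrast = fc$contrast,
    ci_lo = fc$ci[1], ci_hi = fc$ci[2],
    n_change = fc$n["change"], n_no_change = fc$n["no_change"])
  rm(sim)
}

kernels <- do.call(rbind, rows[grep("^k_", names(rows))])
contrasts <- do.call(rbind, rows[grep("^c_", names(rows))])
write.csv(kernels, "results/variant_kernels.csv", row.names = FALSE)
write.csv(contrasts, "results/variant_contrasts.csv", row.names = FALSE)

cat("\nFirst-frame support-for-initial contrast (change - no change):\n")
print(contrasts, row.names = FALSE, digits = 3)
cat("\nExpected signature: coupled < 0, decoupled > 0, novar ~ 0.\n")
cat("Tables in results/variant_kernels.csv and results/variant_contrasts.csv\n")
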