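#!/usr/bin/env Rscript
# Mixed-effects analyses on the synthetic study: does first-frame (and later
# pre-response) evidence predict whether and how fast decisions are reversed?
# Run analysis/01_simulate_dataset.R first.

suppressPackageStartupMessages(library(comddm))

ds <- read_dataset("results/dataset")
ex <- apply_exclusions(ds$trials)
print(ex$report)
trials <- classify_response(
  attach_evidence_predictors(ex$trials, ds$residuals[ex$retained_idx, ]))

out <- list()
for (ev in c("first_frame", "pre_response_mean")) {
  m_prob <- fit_com_probability_model(trials, ev)
  m_speed <- fit_com_speed_model(trials, ev)
  cat("\n== change-of-mind probability ~ accuracy x", ev, "==\n")
  print(m_prob)
  cat("\n== change-of-mind latency ~ accuracy x", ev, "==\n")
  print(m_speed)
  out[[ev]] <- list(
    probability = m_prob[c("lr_chisq", "df", "p", "interaction", "aic",
                           "r2", "converged", "coding")],
    speed = m_speed[c("lr_chisq", "df", "p", "interaction", "aic",
                      "r2", "converged", "coding")])
}

cat("\n== evidence-window comparison (non-nested, AIC) ==\n")
cmp <- compare_evidence_windows(trials)
print(cmp, row.names = FALSE)
out$window_comparison <- cmp

jsonlite::write_json(out, "results/mixed_models.json",
                     auto_unbox = TRUE, digits = NA, force = TRUE)
cat("\nResults written to results/mixed_models.json\n")
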