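Package: comddm
Title: Change-of-Mind Decisions in an Extended Drift-Diffusion Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for perceptual change-of-mind
    decisions in a flickering two-square luminance discrimination task.
    Implements the task's truncated-Gaussian stimulus generator and
    normalized residual-evidence computation, an extended drift-diffusion
    model with post-decisional accumulation and a change-of-mind threshold
    in which across-trial drift-rate variability can be coupled to the
    first frame of sensory evidence, psychophysical reverse-correlation
    kernel estimation (stimulus-, response-, and change-of-mind-locked,
    with median splits, moving-average smoothing and framewise t-tests),
    mixed-effects analyses of change-of-mind probability and latency,
    RMSE-based model fitting to response proportions and response-time
    quantiles via simplex search, and a synthetic-study generator so the
    full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
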