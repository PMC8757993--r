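---
title: "Modelling change-of-mind decisions with a stimulus-coupled extended DDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling change-of-mind decisions with a stimulus-coupled extended DDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comddm)
```

## The task and the question

In a two-alternative luminance discrimination task, an observer watches two
flickering grey squares and reports which is brighter. Every display frame
(13.33 ms on a 75 Hz monitor) each square's luminance is redrawn from a
Gaussian around its mean (142 for the brighter square, 130 for the darker,
SD 55, truncated at 1 SD by rejection sampling). The observer has 800 ms to
respond; the stimuli then stay on screen for 1.5 s, during which the
response may be reversed — a *change of mind*. Because the frame-wise
luminance fluctuations are random with known statistics, averaging the
*residual evidence* (the mean-corrected, normalized luminance difference)
across trials that share an outcome reveals *when* evidence influenced the
decision: a psychophysical kernel.

The scientific question this package operationalizes: does evidence
presented *before* the initial decision — as early as the very first frame —
influence whether and how fast that decision is later reversed? And which
evidence-accumulation architecture can produce such an effect?

## The model

Evidence accumulates between two bounds (0 and `B`) from a starting point
uniform on `B/2 ± Sz/2`. Per 1-ms Euler step,

```
dDV = (drift + stimulusNoise) * dt + endo * sqrt(dt)
drift = mu + externalVar(t) + internalVar
```

* `mu` is the mean drift toward the correct bound;
* `internalVar ~ N(0, eta)` is drawn once per trial (endogenous
  trial-to-trial drift variability);
* `externalVar(t)` is a decaying "snapshot" of the first frame of stimulus
  evidence: `sign(ff) * max(0, s*|ff| - slope*t)` — it starts at `s *
  firstFrame` and decays linearly to zero at rate `slope`;
* `stimulusNoise` is one draw per display frame from `N(0, theta)` truncated
  at 1 SD, held constant across that frame's steps — the model's analogue of
  the frame-wise luminance residuals;
* `endo ~ N(0, 0.1)` is fresh white noise per step; its SD is fixed at 0.1
  as the model's scaling parameter.

After the first bound crossing, accumulation continues for a fraction
`timeOut` of the 1.5-s post-decision window. If the process re-crosses a
threshold `B_CoM` back from the initial bound, a change of mind is emitted
(one at most; double changes are excluded from all analyses anyway).
A single non-decision time `N(tnd, tndVar)` per trial (negative draws
resampled) is added to both the initial and the reversal response, so the
change-of-mind latency is a pure decision-time difference.

Three variants differ only in the across-trial drift variability:

* **coupled** — `externalVar` is driven by the trial's actual first-frame
  stimulus noise (the full model);
* **decoupled** — a draw with the identical marginal distribution but
  statistically independent of the stimulus;
* **novar** — no across-trial variability at all (`eta = 0`, `s = 0`).

Only the coupled variant predicts *weaker* first-frame support for the
initial response on change-of-mind trials. The decoupled variant predicts
the opposite sign (a pure selection effect: surviving an adverse drift draw
requires strong early stimulus evidence), and the no-variability variant
predicts no first-frame difference, because conditional on the initial
choice the decision state at the bound is always the same and reversal
depends only on post-decisional evidence. These signed signatures — not any
single parameter value — are what identify the architecture, and they are
what the test suite asserts at n = 100,000 simulated trials per variant.

## Numerical scheme

The update above is an Euler–Maruyama scheme with one deliberate choice: the
frame-held stimulus noise is integrated like drift (multiplied by `dt`),
while only the white endogenous noise is scaled by `sqrt(dt)`. Scaling a
*held* noise value by `sqrt(dt)` would make the process depend on the step
size (its variance contribution per frame would grow as `1/dt`), so no
step-size refinement test could ever converge. With the scheme used here,
halving the step size leaves choice probabilities and RT distributions
statistically unchanged, which the test suite verifies against the analytic
two-boundary Wiener first-passage solution (`wiener_choice_prob`,
`wiener_fpt_density`): in the white-noise limit (`theta = 0`) simulated
choice probabilities sit within Monte-Carlo error of the closed form, and
with frame-held noise an effective diffusion coefficient derived from
truncated-normal moments and the steps-per-frame layout does the same job
up to a small, step-size-independent frame-granularity term. A
`noise_scaling = "dt"` mode reproduces the literal
`(stimulusNoise + endo) * stepsize` update for comparison, and
`external_decay = "literal"` reproduces the raw linear form
`-slope*t + s*firstFrame`, which (unlike the default) keeps subtracting
after the snapshot has decayed through zero and is therefore not used by
default.

Other numerical conventions, chosen once and kept fixed:

* a bound reached or passed within a step counts as crossed at that step's
  end; the overshoot is retained when post-decisional accumulation
  continues;
* trials whose initial response would land past the 800-ms deadline are
  non-responses and are excluded downstream (as in the task's "too slow"
  trials);
* response times snap to the display frame containing them (floor), since
  each frame's evidence is on screen for its whole 13.33 ms;
* the frame duration is exactly 1/75 s, so a 0–200 ms window contains
  exactly 15 frame onsets;
* residual evidence is normalized by the largest magnitude achievable under
  the truncation bounds (2 × 1 SD × 55 = 110 luminance units), an affine,
  invertible map into [-1, 1];
* median splits of change-of-mind latencies are computed per participant ×
  session; a latency exactly at the median goes to "slow", and cells where
  all latencies tie are flagged as degenerate;
* in mixed models, accuracy uses treatment coding (1 = initial choice
  correct) and evidence is signed toward the correct side, so "support for
  the initial response" is carried by the accuracy × evidence interaction;
  likelihood-ratio tests compare maximum-likelihood fits with and without
  the interaction.

## The synthetic study generator

`generate_dataset()` emulates the study design end to end: 4 participants ×
5 sessions × 1000 trials by default, with per-participant ground-truth
parameters jittered ±10% (multiplicatively) so participant random
intercepts are non-degenerate. Crucially, behaviour is *driven by the very
stimuli written to disk*: the normalized luminance residuals are scaled to
the SD of the model's internal stimulus-noise draws
(`sqrt(2) * theta` × residual, given the default truncation) and fed to the
simulator as its per-frame stimulus noise. The trial table and residual
matrix therefore have exactly the statistical coupling the
reverse-correlation and mixed-model analyses assume of real data.

The default parameter preset (`preset_study_like()`) was calibrated once by
coarse grid search so the default study lands near the aggregate behaviour
this task produces — roughly two-thirds initial accuracy, a change of mind
on roughly a quarter of responded trials with corrected errors about three
times as common as spoilt corrects, and a low single-digit non-response
rate — and then frozen. It is a fixture for exercising the pipeline, not an
estimate of any observer's parameters.

What the generator deliberately does *not* emulate: luminance quantization
to 8-bit RGB (residuals are kept continuous; quantization would add an
unmodelled discretization), display gamma, perceptual nonlinearities,
sequential effects across trials, lapses, and non-Gaussian non-decision
times. Passing tests on synthetic data therefore show that the pipeline's
logic and directions are right under the model's own assumptions, not that
the model is the true account of any particular dataset.

## Fitting

`summarize_behaviour()` reduces a trial table to the fitting target: the
four response-type proportions (correct, error, corrected error, spoilt
correct) plus RT quantiles (0.1, 0.3, 0.5, 0.7, 0.9) for initially-correct
and initially-wrong responses and change-of-mind latency quantiles for both
reversal types. `com_loss()` simulates the model at candidate parameters
and returns the RMSE over the concatenated vector (proportions
dimensionless, quantiles in seconds, unweighted by default; a weights
option exists). The random seed is reset before every evaluation — common
random numbers — so the simplex search (`fit_ddm()`, Nelder–Mead on
log-/logit-transformed parameters) sees a quasi-deterministic surface;
without this, a simplex on a stochastic loss is ill-posed. Quantile cells
with fewer than 10 trials are dropped from the loss symmetrically.

Problem sizes are configurable; the package's own analyses fit mu and B to
20,000 synthetic trials at 50,000 simulated trials per evaluation, which
recovers both within a few percent (±15% is the acceptance band). The
original protocol's 500,000 trials per iteration is available by setting
`n_sim` accordingly.

## Known limitations

* The reverse-correlation machinery assumes one evidence stream per trial
  (the normalized luminance difference); tasks needing motion-energy
  filtering are out of scope by design.
* Framewise t-tests are illustrative and uncorrected, as in the analysis
  they mirror; no cluster-based correction is provided.
* The change-of-mind threshold is single and symmetric; attractor-network
  and urgency-gating accounts, collapsing bounds, and continuous motor
  read-outs are not modelled.
* With `external_decay = "literal"` the drift keeps drifting away from zero
  after the snapshot has decayed; the mode exists for comparison with the
  printed update rule, not for use.
* Fitted parameters are only as identified as the behavioural summary
  allows: with all eleven parameters free the RMSE surface has broad flats;
  the package exposes the free-parameter set so users choose what the data
  can constrain.
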