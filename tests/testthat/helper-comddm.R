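# Shared helpers for the test suite.

# Effective diffusion SD of the Euler scheme, derived independently of the
# simulator: endogenous white noise contributes endo_sd^2 per second; the
# per-frame held, 1-SD-truncated stimulus noise integrates as a piecewise
# constant drift, contributing Var_trunc(theta) * dt^2 * sum(k_f^2) per
# horizon second, where k_f is the number of 1-ms steps in frame f (13 or 14
# on the 75 Hz frame grid).
sigma_eff_euler <- function(theta, endo_sd = 0.1, dt = 0.001,
                            frame_dur = 1 / 75, horizon = 4) {
  ks <- table(floor((0:(horizon / dt - 1)) * dt / frame_dur))
  vtr <- (1 - 2 * stats::dnorm(1) / (2 * stats::pnorm(1) - 1)) * theta^2
  sqrt(endo_sd^2 + vtr * dt^2 * sum(ks^2) / horizon)
}

# Known boundary displacement of an Euler-discretized first-passage problem
# (Broadie-Glasserman-Kou): each absorbing bound sits effectively
# 0.5826 * sigma * sqrt(dt) beyond its nominal position.
euler_bound_shift <- function(sigma, dt) 0.5826 * sigma * sqrt(dt)

# Fast small-parameter set for unit tests (not the calibrated preset).
test_params <- function(...) {
  p <- model_params(B = 0.12, Sz = 0, B_CoM = 0.12, timeOut = 0.7,
                    mu = 0.12, theta = 1.6, tnd = 0.2, tndVar = 0)
  ch <- list(...)
  for (nm in names(ch)) p[[nm]] <- ch[[nm]]
  validate_params(p)
  p
}

# A minimal well-formed trial row for hand-built tables.
trial_row <- function(initial, final, n_changes, rt, com = NA_real_,
                      correct = "left", participant = 1L, session = 1L) {
  data.frame(participant = participant, session = session,
             correct_side = correct, initial_choice = initial,
             final_choice = final, initial_rt = rt,
             n_changes = n_changes, com_latency = com,
             stringsAsFactors = FALSE)
}
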