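#' Drift rate at a given time point
#'
#' Returns `mu + externalVar(t) + internalVar`. In the default
#' `external_decay = "to_zero"` mode the external component is a
#' sign-symmetric decaying snapshot of the first frame,
#' `sign(firstFrame) * max(0, s*|firstFrame| - slope*t)`; in `"literal"` mode
#' it is the raw linear form `-slope*t + s*firstFrame`.
#'
#' @param params A [model_params()] object.
#' @param t Time within the trial, seconds (vectorized); must be `>= 0`.
#' @param first_frame The first-frame stimulus-noise value driving the
#'   external component.
#' @param internal_var_draw The trial's internal drift-variability draw
#'   (evidence/s). Default 0.
#' @param variant Model variant: `"coupled"`, `"decoupled"` or `"novar"`.
#'   Under `"novar"` both variability components are switched off.
#' @param external_decay `"to_zero"` (default) or `"literal"`, see above.
#' @return Drift rate(s) in evidence units per second.
#' @export
#' @examples
#' p <- model_params(B = 1, mu = 0.1, s = 1, theta = 0.1)
#' drift_at(p, t = 2, first_frame = 0.5, external_decay = "literal")  # 0.6
drift_at <- function(params, t, first_frame, internal_var_draw = 0,
                     variant = c("coupled", "decoupled", "novar"),
                     external_decay = c("to_zero", "literal")) {
  variant <- match.arg(variant)
  external_decay <- match.arg(external_decay)
  if (any(t < 0)) stop("t must be non-negative")
  if (variant == "novar") return(rep(params$mu, length(t)))
  ext <- if (external_decay == "to_zero") {
    sign(first_frame) * pmax(0, params$s * abs(first_frame) - params$slope * t)
  } else {
    -params$slope * t + params$s * first_frame
  }
  params$mu + ext + internal_var_draw
}

#' Simulate a batch of extended-DDM trials
#'
#' Euler simulation of the change-of-mind extended DDM (see
#' [model_params()]). Trials whose initial response would land beyond the
#' deadline are recorded as non-responses. Accumulation stops at the first
#' change of mind, so at most one change per trial is emitted.
#'
#' @param params A [model_params()] object.
#' @param variant `"coupled"`, `"decoupled"` or `"novar"`.
#' @param config A [task_config()] (timing and frame layout).
#' @param n_trials Number of trials (`>= 1`).
#' @param stim_noise Optional `n_trials x n_frames_total` matrix of externally
#'   supplied stimulus-noise values (evidence units, signed toward the correct
#'   bound). When supplied, the model is driven by these values instead of its
#'   internal truncated-normal draws; used to yoke simulated behaviour to
#'   on-file stimulus residuals.
#' @param return_noise Return the per-trial per-frame stimulus-noise matrix
#'   (needed for reverse correlation)? Default `TRUE`.
#' @param noise_scaling `"sqrt_dt"` (default): Euler-Maruyama scheme — the
#'   white endogenous noise is scaled by `sqrt(stepsize)` while the
#'   frame-held stimulus noise, a piecewise-constant signal in drift units,
#'   integrates like drift (`* stepsize`); the only scheme whose behaviour
#'   is independent of `stepsize`. `"dt"`: the literal
#'   `(stimulusNoise + endogenous) * stepsize` update.
#' @param external_decay Passed to the drift computation; see [drift_at()].
#' @param assign_sides Randomize which physical side (left/right) is correct
#'   on each trial and report left/right choices? Default `TRUE`.
#'
#' @return A list with elements
#'   \describe{
#'     \item{trials}{data frame, one row per trial: `trial`, `participant`,
#'       `session`, `correct_side`, `initial_choice`, `final_choice`
#'       (`"left"/"right"/"none"`), `initial_rt`, `decision_time`,
#'       `n_changes`, `com_latency` (s, relative to the initial response;
#'       `NA` if none), `first_frame`, `dv_start`, `responded`.}
#'     \item{stim_noise}{`n_trials x n_frames` matrix of stimulus-noise values
#'       (if `return_noise`), signed toward the correct side.}
#'     \item{params, variant, config}{the inputs, for provenance.}
#'   }
#' @export
simulate_experiment <- function(params, variant = "coupled",
                                config = task_config(), n_trials,
                                stim_noise = NULL, return_noise = TRUE,
                                noise_scaling = c("sqrt_dt", "dt"),
                                external_decay = c("to_zero", "literal"),
                                assign_sides = TRUE) {
  validate_params(params)
  noise_scaling <- match.arg(noise_scaling)
  external_decay <- match.arg(external_decay)
  stopifnot(n_trials >= 1)
  n_frames <- config$n_frames_total
  if (!is.null(stim_noise)) stim_noise <- as.matrix(stim_noise)

  raw <- sim_ddm_cpp(
    params$B, params$Sz, params$B_CoM, params$timeOut, params$mu,
    params$eta, params$slope, params$s, params$theta, params$tnd,
    params$tndVar, params$stepsize, params$endo_noise_sd,
    as.integer(n_trials), config$frame_duration, config$deadline,
    config$post_decision_window, as.integer(n_frames),
    variant_code(variant), noise_scaling == "sqrt_dt",
    external_decay == "to_zero", stim_noise, return_noise)

  responded <- raw$choice != 0L
  init_correct <- ifelse(responded, raw$choice == 1L, NA)
  n_changes <- as.integer(raw$com)
  final_correct <- ifelse(raw$com, !init_correct, init_correct)

  if (assign_sides) {
    correct_side <- ifelse(stats::runif(n_trials) < 0.5, "left", "right")
  } else {
    correct_side <- rep("right", n_trials)
  }
  other <- ifelse(correct_side == "left", "right", "left")
  to_side <- function(is_correct) {
    ifelse(is.na(is_correct), "none",
           ifelse(is_correct, correct_side, other))
  }

  trials <- data.frame(
    trial = seq_len(n_trials),
    participant = 1L, session = 1L,
    correct_side = correct_side,
    initial_choice = to_side(init_correct),
    final_choice = to_side(final_correct),
    initial_rt = raw$initial_rt,
    decision_time = raw$decision_time,
    n_changes = n_changes,
    com_latency = raw$com_latency,
    first_frame = raw$first_frame,
    dv_start = raw$dv_start,
    responded = responded,
    stringsAsFactors = FALSE
  )
  out <- list(trials = trials, params = params, variant = variant,
              config = config)
  if (return_noise) out$stim_noise <- raw$stim_noise
  out
}

#' Simulate a single trial
#'
#' Convenience wrapper around [simulate_experiment()] with `n_trials = 1`;
#' both share the same compiled core, so single-trial and batch simulation
#' agree draw for draw.
#'
#' @inheritParams simulate_experiment
#' @return A one-row version of the [simulate_experiment()] output.
#' @export
simulate_trial <- function(params, variant = "coupled",
                           config = task_config(), ...) {
  simulate_experiment(params, variant, config, n_trials = 1, ...)
}
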