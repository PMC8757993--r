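#' Study-like parameter preset
#'
#' A frozen extended-DDM parameterization calibrated once (coarse grid
#' search) so that a default synthetic study lands near the aggregate rates
#' the task produces in practice: roughly two-thirds initial accuracy, a
#' change of mind on roughly a quarter of trials (corrected errors several
#' times more common than spoilt corrects), and a low non-response rate. It
#' is a fixture for exercising the pipeline, not an estimate of any
#' observer's true parameters.
#'
#' @return A [model_params()] object.
#' @export
preset_study_like <- function() {
  model_params(
    B = 0.12, Sz = 0.04, B_CoM = 0.138, timeOut = 0.7,
    mu = 0.12, eta = 0.06, slope = 0.05, s = 0.08, theta = 1.6,
    tnd = 0.24, tndVar = 0.045,
    stepsize = 0.001, endo_noise_sd = 0.1)
}

# scale mapping data-space residuals (in [-1,1]) to model-space stimulus
# noise: match the SD of the model's internal truncated-normal draws
stim_noise_scale <- function(params, config) {
  sd_model <- sqrt(trunc_norm_var_factor(1)) * params$theta
  sd_model / residual_sd_theory(config)
}

#' Synthetic study design
#'
#' Describes a full synthetic study: participants x sessions x trials, the
#' ground-truth model parameters (jittered per participant so participant
#' random intercepts are non-degenerate), the generating model variant, and
#' the seed.
#'
#' @param n_participants Number of participants. Default 4.
#' @param sessions_per_participant Sessions per participant. Default 5.
#' @param trials_per_session Trials per session. Default 1000.
#' @param params Ground-truth [model_params()] shared across participants
#'   before jittering. Default [preset_study_like()].
#' @param variant Generating variant. Default `"coupled"`.
#' @param jitter Half-width of the uniform multiplicative per-participant
#'   jitter applied to `mu`, `B`, `B_CoM`, `tnd` and `s`. Default 0.1
#'   (+/- 10%); 0 disables jittering.
#' @param seed Integer seed. Default 1.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_participants = 4, sessions_per_participant = 5,
                         trials_per_session = 1000,
                         params = preset_study_like(),
                         variant = "coupled", jitter = 0.1, seed = 1) {
  stopifnot(n_participants >= 1, sessions_per_participant >= 1,
            trials_per_session >= 1, jitter >= 0, jitter < 0.5)
  validate_params(params)
  structure(list(n_participants = n_participants,
                 sessions_per_participant = sessions_per_participant,
                 trials_per_session = trials_per_session,
                 params = params, variant = variant,
                 jitter = jitter, seed = as.integer(seed)),
            class = "study_design")
}

#' Generate a complete synthetic study dataset
#'
#' For each participant and session, draws flickering-luminance stimuli from
#' the task model ([generate_stimuli()]), converts their residual evidence to
#' model-space stimulus noise (scaled to match the SD of the model's internal
#' truncated-normal stimulus-noise draws), and simulates behaviour from the
#' extended DDM driven by those very stimuli, so the on-file residuals and
#' the behaviour are coupled exactly as the analysis assumes. Non-responses
#' past the deadline are included. Per-participant ground-truth parameters
#' are the design's preset jittered multiplicatively.
#'
#' @param design A [study_design()].
#' @param config A [task_config()].
#' @return List with `trials` (trial table across all participants and
#'   sessions), `residuals` (trial x frame matrix of normalized residual
#'   evidence, rows aligned with `trials`), and `manifest` (design, seed,
#'   per-participant ground-truth parameters, stimulus-noise scale).
#' @export
generate_dataset <- function(design = study_design(), config = task_config()) {
  set.seed(design$seed)
  jit <- function(x) x * stats::runif(1, 1 - design$jitter, 1 + design$jitter)
  per_part <- lapply(seq_len(design$n_participants), function(p) {
    pp <- design$params
    if (design$jitter > 0) {
      for (nm in c("mu", "B", "B_CoM", "tnd", "s")) pp[[nm]] <- jit(pp[[nm]])
      pp$Sz <- min(pp$Sz, 0.99 * pp$B)
      validate_params(pp)
    }
    pp
  })

  all_trials <- list()
  all_res <- list()
  for (p in seq_len(design$n_participants)) {
    pars <- per_part[[p]]
    scale <- stim_noise_scale(pars, config)
    for (s in seq_len(design$sessions_per_participant)) {
      stim <- generate_stimuli(design$trials_per_session, config)
      sim <- simulate_experiment(pars, design$variant, config,
                                 n_trials = design$trials_per_session,
                                 stim_noise = stim$residual * scale,
                                 return_noise = FALSE)
      tr <- sim$trials
      tr$participant <- p
      tr$session <- s
      all_trials[[length(all_trials) + 1L]] <- tr
      all_res[[length(all_res) + 1L]] <- stim$residual
    }
  }
  trials <- do.call(rbind, all_trials)
  trials$trial <- seq_len(nrow(trials))
  list(trials = trials,
       residuals = do.call(rbind, all_res),
       manifest = list(design = unclass(design)[c(
                         "n_participants", "sessions_per_participant",
                         "trials_per_session", "variant", "jitter", "seed")],
                       ground_truth = lapply(per_part, unclass),
                       stim_noise_scale = vapply(per_part, stim_noise_scale,
                                                 numeric(1), config = config)))
}

#' Write / read a synthetic dataset
#'
#' Serializes a [generate_dataset()] result: `trials.csv` (the trial table),
#' `residuals.csv` (the residual-evidence matrix, one row per trial), and
#' `manifest.json` (ground truth and seeds).
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` the
#'   dataset list (without the manifest's class attributes).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$residuals),
                   file.path(dir, "residuals.csv"), row.names = FALSE)
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  list(trials = utils::read.csv(file.path(dir, "trials.csv"),
                                stringsAsFactors = FALSE),
       residuals = as.matrix(utils::read.csv(file.path(dir, "residuals.csv"))),
       manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                      simplifyVector = TRUE))
}

#' Hand-sized deterministic fixtures
#'
#' Small trial tables (and, where relevant, residual matrices) with
#' hand-computable expected outputs, used by unit tests across modules.
#'
#' * `"exclusions"`: six trials — one per exclusion rule (no response,
#'   double change, change-of-mind latency under 50 ms, initial RT under
#'   150 ms) plus two clean trials.
#' * `"kernels"`: three trials with a 5-frame residual matrix for exact
#'   kernel averaging.
#' * `"median_split"`: one participant, two sessions with asymmetric
#'   change-of-mind latencies, so per-cell and pooled medians disagree.
#' * `"null"`: twenty trials whose responses are assigned independently of
#'   their residuals.
#'
#' @param name One of `"exclusions"`, `"kernels"`, `"median_split"`,
#'   `"null"`.
#' @return A trial data frame, or a list with `trials` and `residuals` for
#'   fixtures carrying evidence.
#' @export
make_fixture <- function(name = c("exclusions", "kernels", "median_split",
                                  "null")) {
  name <- match.arg(name)
  base_trial <- function(initial, final, n_changes, rt, com = NA_real_,
                         participant = 1L, session = 1L) {
    data.frame(participant = participant, session = session,
               correct_side = "left", initial_choice = initial,
               final_choice = final, initial_rt = rt,
               n_changes = n_changes, com_latency = com,
               stringsAsFactors = FALSE)
  }
  switch(name,
    exclusions = rbind(
      base_trial("none", "none", 0L, NA_real_),        # no response
      base_trial("left", "right", 2L, 0.40, 0.30),     # double change
      base_trial("right", "left", 1L, 0.45, 0.04),     # CoM < 50 ms
      base_trial("left", "left", 0L, 0.10),            # initial RT < 150 ms
      base_trial("left", "left", 0L, 0.50),            # clean correct
      base_trial("right", "left", 1L, 0.55, 0.40)      # clean corrected error
    ),
    kernels = {
      tr <- rbind(
        base_trial("left", "left", 0L, 0.07),          # correct
        base_trial("left", "left", 0L, 0.07),          # correct
        base_trial("right", "right", 0L, 0.07))        # error
      res <- matrix(c(0.2, 0.1, 0.0, -0.1, 0.3,
                      0.4, -0.1, 0.2, 0.1, -0.3,
                      -0.2, -0.4, 0.1, 0.0, 0.2),
                    nrow = 3, byrow = TRUE)
      list(trials = tr, residuals = res)
    },
    median_split = rbind(
      base_trial("right", "left", 1L, 0.4, 0.10, session = 1L),
      base_trial("right", "left", 1L, 0.4, 0.20, session = 1L),
      base_trial("right", "left", 1L, 0.4, 0.30, session = 1L),
      base_trial("right", "left", 1L, 0.4, 0.90, session = 1L),
      base_trial("right", "left", 1L, 0.4, 0.50, session = 2L),
      base_trial("right", "left", 1L, 0.4, 0.70, session = 2L)
    ),
    null = {
      set.seed(20)
      n <- 20
      tr <- do.call(rbind, lapply(seq_len(n), function(i) {
        correct <- i %% 2 == 0
        base_trial(if (correct) "left" else "right",
                   if (correct) "left" else "right", 0L, 0.5)
      }))
      list(trials = tr,
           residuals = matrix(stats::rnorm(n * 10, sd = 0.3), nrow = n))
    })
}
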