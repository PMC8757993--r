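#' Task configuration for the flickering two-square luminance task
#'
#' Describes the stimulus statistics and timing of the luminance
#' discrimination task: two squares refreshed every screen frame, each frame's
#' luminance drawn from a Gaussian around that square's mean and truncated at
#' a fixed number of standard deviations, an initial-response deadline, and a
#' fixed post-decision viewing window during which the observer may change
#' their response.
#'
#' @param frame_duration Duration of one display frame in seconds. Default
#'   `1/75` (a 75 Hz display, i.e. 13.33 ms).
#' @param mean_bright,mean_dark Mean luminance (greyscale units) of the
#'   brighter and darker square. Defaults 142 and 130.
#' @param noise_sd Standard deviation of the per-frame luminance noise
#'   (greyscale units). Default 55.
#' @param truncation_sds Truncation point of the luminance noise, in standard
#'   deviations from the mean. Default 1.
#' @param deadline Initial-response deadline in seconds. Default 0.8.
#' @param post_decision_window Duration of the post-decision viewing window in
#'   seconds. Default 1.5.
#'
#' @return An object of class `task_config`: a list of the above fields plus
#'   `n_frames_total`, the number of frames needed to cover
#'   `deadline + post_decision_window`.
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$n_frames_total
task_config <- function(frame_duration = 1 / 75,
                        mean_bright = 142, mean_dark = 130,
                        noise_sd = 55, truncation_sds = 1,
                        deadline = 0.8, post_decision_window = 1.5) {
  if (frame_duration <= 0) stop("frame_duration must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (truncation_sds <= 0) stop("truncation_sds must be positive")
  if (mean_bright <= mean_dark) stop("mean_bright must exceed mean_dark")
  if (deadline <= 0 || post_decision_window < 0)
    stop("deadline must be positive and post_decision_window non-negative")
  cfg <- list(
    frame_duration = frame_duration,
    mean_bright = mean_bright, mean_dark = mean_dark,
    noise_sd = noise_sd, truncation_sds = truncation_sds,
    deadline = deadline, post_decision_window = post_decision_window,
    n_frames_total = as.integer(ceiling(
      (deadline + post_decision_window) / frame_duration))
  )
  class(cfg) <- "task_config"
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat("Luminance-discrimination task configuration\n")
  cat(sprintf("  frame: %.4f s (%.0f Hz), %d frames total\n",
              x$frame_duration, 1 / x$frame_duration, x$n_frames_total))
  cat(sprintf("  luminance: bright %g, dark %g, SD %g (truncated at %g SD)\n",
              x$mean_bright, x$mean_dark, x$noise_sd, x$truncation_sds))
  cat(sprintf("  deadline %g s, post-decision window %g s\n",
              x$deadline, x$post_decision_window))
  invisible(x)
}

# Normalization constant for residual evidence: the maximum |residual|
# achievable under the truncation bounds. With both squares truncated at
# truncation_sds * noise_sd, the mean-corrected difference spans
# +/- 2 * truncation_sds * noise_sd (= 110 at the defaults).
residual_norm_constant <- function(config) {
  2 * config$truncation_sds * config$noise_sd
}

# Variance of a standard normal truncated at +/- a (rejection-sampled).
trunc_norm_var_factor <- function(a = 1) {
  1 - 2 * a * stats::dnorm(a) / (2 * stats::pnorm(a) - 1)
}

# SD of the normalized residual under the stimulus model: the difference of
# two independent truncated normals, divided by the normalization constant.
residual_sd_theory <- function(config) {
  sd_one <- sqrt(trunc_norm_var_factor(config$truncation_sds)) * config$noise_sd
  sqrt(2) * sd_one / residual_norm_constant(config)
}

#' Generate flickering two-square luminance stimuli
#'
#' Draws, for each trial and display frame, independent luminance values for
#' the brighter and darker square from Gaussians truncated (by rejection
#' sampling, not clipping) at `truncation_sds` standard deviations from their
#' means, and computes the normalized residual-evidence series.
#'
#' @param n_trials Number of trials.
#' @param config A [task_config()].
#' @param n_frames Number of frames per trial; defaults to
#'   `config$n_frames_total`.
#'
#' @return A list with `n_trials` x `n_frames` matrices `bright`, `dark`
#'   (luminance units) and `residual` (normalized evidence in `[-1, 1]`,
#'   positive toward the brighter, i.e. correct, side).
#' @seealso [residual_evidence()]
#' @export
generate_stimuli <- function(n_trials, config = task_config(),
                             n_frames = config$n_frames_total) {
  stopifnot(n_trials >= 1, n_frames >= 1)
  draw_trunc <- function(mean, sd, bound, n) {
    x <- stats::rnorm(n, mean, sd)
    bad <- abs(x - mean) > bound
    while (any(bad)) {
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
      bad <- abs(x - mean) > bound
    }
    x
  }
  n <- n_trials * n_frames
  bound <- config$truncation_sds * config$noise_sd
  bright <- matrix(draw_trunc(config$mean_bright, config$noise_sd, bound, n),
                   n_trials, n_frames)
  dark <- matrix(draw_trunc(config$mean_dark, config$noise_sd, bound, n),
                 n_trials, n_frames)
  list(bright = bright, dark = dark,
       residual = residual_evidence(bright, dark, config))
}

#' Normalized residual evidence from luminance frames
#'
#' Subtracts the darker square's frame-by-frame luminance from the brighter
#' square's, removes the across-trial mean difference, and normalizes by the
#' maximum residual achievable under the truncation bounds, so the result lies
#' in `[-1, 1]` with positive values indicating evidence toward the brighter
#' (correct) side.
#'
#' @param bright,dark Luminance values (vectors or matrices of equal shape).
#' @param config A [task_config()].
#' @return Normalized residual evidence, same shape as the inputs.
#' @export
#' @examples
#' residual_evidence(142, 130, task_config())  # 0
#' residual_evidence(197, 75, task_config())   # +1
residual_evidence <- function(bright, dark, config = task_config()) {
  if (length(bright) != length(dark))
    stop("bright and dark must have the same length")
  ((bright - dark) - (config$mean_bright - config$mean_dark)) /
    residual_norm_constant(config)
}

#' Invert residual evidence back to a luminance difference
#'
#' The normalization is affine and therefore invertible up to the (unobserved)
#' split between the two squares: returns the mean-corrected luminance
#' difference `bright - dark`.
#'
#' @param residual Normalized residual evidence.
#' @param config A [task_config()].
#' @return Luminance difference `bright - dark` in greyscale units.
#' @export
residual_to_difference <- function(residual, config = task_config()) {
  residual * residual_norm_constant(config) +
    (config$mean_bright - config$mean_dark)
}
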