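#' Extended drift-diffusion model parameters
#'
#' Parameter vector for the change-of-mind extended DDM. Evidence accumulates
#' between bounds 0 and `B` from a starting point uniform on
#' `B/2 +/- Sz/2`. The drift rate at time `t` is
#' `mu + externalVar(t) + internalVar`, where `internalVar ~ N(0, eta)` is
#' drawn once per trial and `externalVar` is a decaying "snapshot" of the
#' first frame of stimulus evidence, `s * firstFrame` shrinking toward zero
#' at rate `slope`. Within-trial noise is `stimulusNoise + N(0, endo_noise_sd)`
#' per step, where one `stimulusNoise ~ N(0, theta)` value (truncated at 1 SD)
#' is drawn per display frame and held across that frame's steps. After the
#' initial bound crossing, accumulation continues for `timeOut` of the
#' post-decision window; re-crossing a threshold `B_CoM` back from the initial
#' bound triggers a change of mind.
#'
#' @param B Separation of the two initial decision bounds (evidence units);
#'   lower bound at 0, upper at `B`.
#' @param Sz Range of the uniform starting-point variability around `B/2`.
#' @param B_CoM Distance of the change-of-mind threshold from the initial
#'   bound (evidence units).
#' @param timeOut Proportion of the post-decision window with active
#'   accumulation, in `[0, 1]`.
#' @param mu Mean drift rate (evidence/s), signed toward the correct bound.
#' @param eta SD of the internal across-trial drift variability (evidence/s).
#' @param slope Decay rate of the external drift component (evidence/s^2).
#' @param s Scaling of the first-frame snapshot (evidence/s per unit of
#'   first-frame stimulus noise).
#' @param theta SD of the stimulus-driven within-trial noise (evidence/s; one
#'   draw per display frame, held across that frame's steps, so it acts as a
#'   piecewise-constant drift perturbation).
#' @param tnd Mean non-decision time (s).
#' @param tndVar SD of the non-decision time (s); negative draws resampled.
#' @param stepsize Euler step (s). Fixed at 0.001 in all reported analyses.
#' @param endo_noise_sd SD of the endogenous within-trial noise; fixed at 0.1
#'   as the model's scaling parameter.
#'
#' @return An object of class `ddm_params` (a named list).
#' @export
#' @examples
#' p <- model_params(B = 0.2, mu = 0.15, theta = 0.1, tnd = 0.3)
model_params <- function(B, Sz = 0, B_CoM = B / 2, timeOut = 1,
                         mu = 0, eta = 0, slope = 0, s = 0, theta = 0,
                         tnd = 0.3, tndVar = 0,
                         stepsize = 0.001, endo_noise_sd = 0.1) {
  p <- list(B = B, Sz = Sz, B_CoM = B_CoM, timeOut = timeOut, mu = mu,
            eta = eta, slope = slope, s = s, theta = theta,
            tnd = tnd, tndVar = tndVar,
            stepsize = stepsize, endo_noise_sd = endo_noise_sd)
  class(p) <- "ddm_params"
  validate_params(p)
  p
}

#' Validate a `ddm_params` object
#'
#' @param p A [model_params()] object (or plain named list).
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(p) {
  with(p, {
    if (!(B > 0)) stop("B must be positive")
    if (Sz < 0 || Sz >= B) stop("Sz must satisfy 0 <= Sz < B")
    if (!(B_CoM > 0)) stop("B_CoM must be positive")
    if (timeOut < 0 || timeOut > 1) stop("timeOut must lie in [0, 1]")
    if (eta < 0 || theta < 0 || tndVar < 0 || slope < 0)
      stop("eta, theta, tndVar and slope must be non-negative")
    if (!(tnd > 0)) stop("tnd must be positive")
    if (!(stepsize > 0)) stop("stepsize must be positive")
    if (endo_noise_sd < 0) stop("endo_noise_sd must be non-negative")
  })
  invisible(p)
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Extended-DDM parameters\n")
  flds <- unlist(x[c("B", "Sz", "B_CoM", "timeOut", "mu", "eta", "slope",
                     "s", "theta", "tnd", "tndVar")])
  print(round(flds, 5))
  cat(sprintf("  stepsize = %g s, endogenous noise SD = %g\n",
              x$stepsize, x$endo_noise_sd))
  invisible(x)
}

#' Read / write model parameters as JSON
#'
#' Parameters are keyed by their conventional symbol names (`B`, `Sz`,
#' `B_CoM`, `timeOut`, `mu`, `eta`, `slope`, `s`, `theta`, `tnd`, `tndVar`).
#'
#' @param p A `ddm_params` object.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   `ddm_params` object.
#' @export
write_params <- function(p, path) {
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(model_params, x)
}

# map a variant tag to the integer code used by the C++ core
variant_code <- function(variant) {
  variant <- match.arg(variant, c("coupled", "decoupled", "novar"))
  c(novar = 0L, coupled = 1L, decoupled = 2L)[[variant]]
}
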