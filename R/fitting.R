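#' Summarize behaviour into model-fitting targets
#'
#' Computes, over retained responded trials: the proportions of the four
#' response types (`correct`, `error`, `corrected_error`, `spoilt_correct`);
#' initial-RT quantiles for initially-correct and initially-wrong responses;
#' and change-of-mind latency quantiles for corrected errors and spoilt
#' corrects. Quantiles use linear interpolation (`stats::quantile`, type 7).
#' Cells with fewer than `min_cell` trials are dropped (set to `NA`) with a
#' warning.
#'
#' @param trials Classified trial data frame (see [classify_response()]);
#'   rows with `response_type == "excluded"` or no response are ignored.
#' @param probs Quantile probabilities. Default `c(.1, .3, .5, .7, .9)`.
#' @param min_cell Minimum trials per quantile cell. Default 10.
#' @return An object of class `behaviour_summary`: list with `proportions`
#'   (length 4, sums to 1), `rt_q` (2 x length(probs) matrix, rows
#'   `initial_correct` / `initial_error`), `com_q` (rows `corrected_error` /
#'   `spoilt_correct`), `probs`, and cell counts `n`.
#' @export
summarize_behaviour <- function(trials, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                min_cell = 10) {
  if (!"response_type" %in% names(trials)) trials <- classify_response(trials)
  tr <- trials[trials$response_type != "excluded" &
                 !is.na(trials$initial_rt), , drop = FALSE]
  type <- factor(as.character(tr$response_type),
                 levels = c("correct", "error", "corrected_error",
                            "spoilt_correct"))
  prop <- as.numeric(table(type)) / nrow(tr)
  names(prop) <- levels(type)

  qcell <- function(x, label) {
    if (length(x) < min_cell) {
      warning("cell ", label, " has ", length(x),
              " trials (< ", min_cell, "); dropped from summary")
      return(rep(NA_real_, length(probs)))
    }
    unname(stats::quantile(x, probs, type = 7))
  }
  init_correct <- tr$initial_choice == tr$correct_side
  rt_q <- rbind(
    initial_correct = qcell(tr$initial_rt[init_correct], "initial_correct"),
    initial_error = qcell(tr$initial_rt[!init_correct], "initial_error"))
  com_q <- rbind(
    corrected_error = qcell(tr$com_latency[tr$response_type == "corrected_error"],
                            "corrected_error"),
    spoilt_correct = qcell(tr$com_latency[tr$response_type == "spoilt_correct"],
                           "spoilt_correct"))
  colnames(rt_q) <- colnames(com_q) <- paste0("q", probs * 100)
  structure(list(proportions = prop, rt_q = rt_q, com_q = com_q,
                 probs = probs,
                 n = c(total = nrow(tr),
                       initial_correct = sum(init_correct),
                       initial_error = sum(!init_correct),
                       corrected_error = sum(type == "corrected_error", na.rm = TRUE),
                       spoilt_correct = sum(type == "spoilt_correct", na.rm = TRUE))),
            class = "behaviour_summary")
}

#' @export
print.behaviour_summary <- function(x, ...) {
  cat("Behaviour summary (", x$n["total"], " responded trials)\n", sep = "")
  cat("  proportions:\n")
  print(round(x$proportions, 4))
  cat("  initial RT quantiles (s):\n")
  print(round(x$rt_q, 3))
  cat("  change-of-mind latency quantiles (s):\n")
  print(round(x$com_q, 3))
  invisible(x)
}

# flatten a behaviour_summary into the fitting target vector; cells that are
# NA in `ref` (or in x) are omitted symmetrically
summary_vector <- function(x, ref = x, weights = c(proportions = 1, quantiles = 1)) {
  v <- c(x$proportions * weights["proportions"],
         as.vector(x$rt_q) * weights["quantiles"],
         as.vector(x$com_q) * weights["quantiles"])
  r <- c(ref$proportions, as.vector(ref$rt_q), as.vector(ref$com_q))
  v[!is.na(r)]
}

#' RMSE loss between observed behaviour and a model simulation
#'
#' Simulates `n_sim` trials at `params`, summarizes them, and returns the
#' root mean squared error over the concatenated vector of response-type
#' proportions and RT quantiles, against `observed`. The random seed is set
#' at each call (common random numbers), so the same seed always yields the
#' same loss and simplex search sees a quasi-deterministic surface. Cells
#' missing (`NA`) in either summary are omitted from the loss vector.
#'
#' @param params A [model_params()] object.
#' @param observed A [summarize_behaviour()] result.
#' @param config A [task_config()].
#' @param n_sim Simulated trials per evaluation (>= 1000).
#' @param seed Integer seed for the simulation.
#' @param variant Model variant to simulate. Default `"coupled"`.
#' @param weights Named weights for the `proportions` and `quantiles` blocks
#'   of the loss vector. Default both 1 (proportions dimensionless,
#'   quantiles in seconds).
#' @return The RMSE (non-negative scalar), with attribute `n_cells`.
#' @export
com_loss <- function(params, observed, config = task_config(),
                     n_sim = 50000, seed = 1, variant = "coupled",
                     weights = c(proportions = 1, quantiles = 1)) {
  stopifnot(n_sim >= 1000)
  set.seed(seed)
  sim <- simulate_experiment(params, variant, config, n_trials = n_sim,
                             return_noise = FALSE, assign_sides = FALSE)
  sim_sum <- suppressWarnings(summarize_behaviour(classify_response(sim$trials)))
  # symmetric cell mask: a cell enters only if present in both summaries
  mask_ref <- observed
  mask_ref$proportions[is.na(sim_sum$proportions)] <- NA
  mask_ref$rt_q[is.na(sim_sum$rt_q)] <- NA
  mask_ref$com_q[is.na(sim_sum$com_q)] <- NA
  vo <- summary_vector(observed, mask_ref, weights)
  vs <- summary_vector(sim_sum, mask_ref, weights)
  structure(sqrt(mean((vo - vs)^2)), n_cells = length(vo))
}

# parameter transforms for unconstrained simplex search
encode_params <- function(p, free) {
  vapply(free, function(nm) {
    switch(nm,
      timeOut = stats::qlogis(min(max(p$timeOut, 1e-6), 1 - 1e-6)),
      B_CoM = stats::qlogis(min(max(p$B_CoM / p$B, 1e-6), 1 - 1e-6)),
      Sz = stats::qlogis(min(max(p$Sz / p$B, 1e-6), 1 - 1e-6)),
      log(p[[nm]]))
  }, numeric(1))
}

decode_params <- function(theta, free, template) {
  p <- template
  for (i in seq_along(free)) {
    nm <- free[i]
    p[[nm]] <- unname(switch(nm,
      timeOut = stats::plogis(theta[i]),
      B_CoM = NA_real_,  # resolved after B below
      Sz = NA_real_,
      exp(theta[i])))
  }
  if ("B_CoM" %in% free)
    p$B_CoM <- stats::plogis(theta[match("B_CoM", free)]) * p$B
  if ("Sz" %in% free)
    p$Sz <- stats::plogis(theta[match("Sz", free)]) * p$B * 0.999
  p
}

#' Fit the extended DDM by simulation-based RMSE minimization
#'
#' Nelder-Mead simplex search over a transformed unconstrained space
#' (positive parameters via log; `timeOut` via logit; `B_CoM` and `Sz` via
#' logit of their ratio to `B`), minimizing [com_loss()] with common random
#' numbers across evaluations.
#'
#' @param observed A [summarize_behaviour()] result (the fitting target).
#' @param init A feasible [model_params()] starting point.
#' @param free Character vector of parameter names to fit. Default
#'   `c("mu", "B")`.
#' @param config A [task_config()].
#' @param n_sim Simulated trials per loss evaluation.
#' @param seed Seed used for every loss evaluation (common random numbers).
#' @param variant Variant to simulate. Default `"coupled"`.
#' @param maxit Maximum simplex iterations. Default 200.
#' @param weights Passed to [com_loss()].
#' @return An object of class `ddm_fit`: list with `params` (best-fitting),
#'   `loss`, `initial_loss`, `counts` (loss evaluations), `iterations`,
#'   `converged`, `free`, and `seed_policy`.
#' @export
fit_ddm <- function(observed, init, free = c("mu", "B"),
                    config = task_config(), n_sim = 50000, seed = 1,
                    variant = "coupled", maxit = 200,
                    weights = c(proportions = 1, quantiles = 1)) {
  validate_params(init)
  theta0 <- encode_params(init, free)
  n_eval <- 0L
  obj <- function(theta) {
    n_eval <<- n_eval + 1L
    p <- decode_params(theta, free, init)
    ok <- tryCatch({ validate_params(p); TRUE }, error = function(e) FALSE)
    if (!ok) return(1e6)
    as.numeric(com_loss(p, observed, config, n_sim, seed, variant, weights))
  }
  loss0 <- obj(theta0)
  # simplex search matches the original fitting protocol even in 1-D;
  # silence optim's advisory about that case
  opt <- withCallingHandlers(
    stats::optim(theta0, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit)),
    warning = function(w) {
      if (grepl("one-dimensional optimization", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  best <- decode_params(opt$par, free, init)
  structure(list(
    params = best,
    loss = opt$value, initial_loss = loss0,
    counts = n_eval, iterations = unname(opt$counts["function"]),
    converged = opt$convergence == 0,
    free = free,
    seed_policy = list(seed = seed, n_sim = n_sim,
                       scheme = "seed reset before every loss evaluation")),
    class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("Extended-DDM fit (Nelder-Mead on RMSE)\n")
  cat(sprintf("  free parameters: %s\n", paste(x$free, collapse = ", ")))
  cat(sprintf("  loss %.5f (initial %.5f), %d evaluations, converged: %s\n",
              x$loss, x$initial_loss, x$counts, x$converged))
  for (nm in x$free) cat(sprintf("  %s = %.5f\n", nm, x$params[[nm]]))
  invisible(x)
}

#' Model-predicted psychophysical kernels
#'
#' Simulates an experiment from the model and reverse-correlates its
#' stimulus-noise matrix with the simulated response outcomes, for all three
#' time locks and for both condition sets used in the study: the four
#' response types, and the fast/slow median split of change-of-mind
#' latencies. Conditions with no simulated trials are omitted with a warning.
#'
#' @param params A [model_params()] object.
#' @param variant Model variant. Default `"coupled"`.
#' @param config A [task_config()].
#' @param n Number of simulated trials. Default 100000.
#' @param seed Integer seed.
#' @param locks Which time locks to compute. Default all three.
#' @param min_trials Bin-count threshold for response/com locks. Default 100.
#' @return List with one element per lock, each containing `by_type` and
#'   `by_com_speed` kernel estimates, plus `trials` and the simulation's
#'   `stim_noise` matrix.
#' @export
predicted_kernels <- function(params, variant = "coupled",
                              config = task_config(), n = 100000, seed = 1,
                              locks = c("stimulus", "response", "com"),
                              min_trials = 100) {
  set.seed(seed)
  sim <- simulate_experiment(params, variant, config, n_trials = n,
                             return_noise = TRUE)
  trials <- classify_response(sim$trials)
  trials$com_speed <- median_split_com_rt(trials)
  empty <- setdiff(c("correct", "error", "corrected_error", "spoilt_correct"),
                   as.character(unique(trials$response_type)))
  if (length(empty))
    warning("no simulated trials of type: ", paste(empty, collapse = ", "))
  speed_type <- ifelse(is.na(trials$com_speed), NA_character_,
                       paste(trials$com_speed, trials$response_type, sep = "_"))
  trials$com_speed_type <- speed_type
  out <- list()
  for (lk in locks) {
    out[[lk]] <- list(
      by_type = compute_kernels(trials, sim$stim_noise, lock = lk,
                                group = "response_type", config = config,
                                min_trials = min_trials),
      by_com_speed = compute_kernels(trials, sim$stim_noise, lock = lk,
                                     group = "com_speed_type", config = config,
                                     min_trials = min_trials))
  }
  out$trials <- trials
  out$stim_noise <- sim$stim_noise
  out
}
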