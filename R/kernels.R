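#' Classify trials into response types
#'
#' Maps each trial to one of `correct`, `error`, `corrected_error` (initial
#' wrong choice changed to the correct one), `spoilt_correct` (initial correct
#' choice changed to the wrong one), or `excluded` (no initial response, or
#' more than one change of mind).
#'
#' @param trials A trial data frame with columns `correct_side`,
#'   `initial_choice`, `final_choice` (`"left"/"right"/"none"`), `n_changes`
#'   and `com_latency`.
#' @return `trials` with a `response_type` factor column appended.
#' @export
classify_response <- function(trials) {
  req <- c("correct_side", "initial_choice", "final_choice", "n_changes")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if ("com_latency" %in% names(trials)) {
    bad <- trials$n_changes == 0 & !is.na(trials$com_latency)
    if (any(bad))
      stop("inconsistent records: com_latency present with n_changes = 0")
  }
  bad <- trials$n_changes == 0 &
    trials$initial_choice != "none" &
    trials$final_choice != trials$initial_choice
  if (any(bad))
    stop("inconsistent records: final_choice differs with n_changes = 0")

  init_ok <- trials$initial_choice == trials$correct_side
  final_ok <- trials$final_choice == trials$correct_side
  type <- rep("excluded", nrow(trials))
  usable <- trials$initial_choice != "none" & trials$n_changes <= 1
  type[usable & trials$n_changes == 0 & init_ok] <- "correct"
  type[usable & trials$n_changes == 0 & !init_ok] <- "error"
  type[usable & trials$n_changes == 1 & !init_ok & final_ok] <- "corrected_error"
  type[usable & trials$n_changes == 1 & init_ok & !final_ok] <- "spoilt_correct"
  trials$response_type <- factor(
    type, levels = c("correct", "error", "corrected_error",
                     "spoilt_correct", "excluded"))
  trials
}

# frame index containing a response time (floor: each frame's evidence is on
# screen for its whole duration)
response_frame <- function(rt, config) as.integer(floor(rt / config$frame_duration))

# last displayed frame index for each trial (stimulus stays up for the
# post-decision window after the initial response)
last_shown_frame <- function(trials, config, n_frames) {
  lim <- floor((trials$initial_rt + config$post_decision_window) /
                 config$frame_duration)
  lim[is.na(lim)] <- floor(config$deadline / config$frame_duration) - 1
  pmin(as.integer(lim), n_frames - 1L)
}

#' Psychophysical kernels by reverse correlation
#'
#' Averages normalized residual evidence across trials sharing a condition,
#' per frame-resolution time bin, time-locked to stimulus onset, the initial
#' response, or the change-of-mind response. Trials are pooled (not averaged
#' per participant first) before averaging, matching the main analysis;
#' `per_participant = TRUE` averages within participants first.
#'
#' @param trials Trial data frame including `response_type` (see
#'   [classify_response()]), `initial_rt` and `com_latency`.
#' @param residuals `nrow(trials) x n_frames` matrix of normalized residual
#'   evidence, signed toward the correct side.
#' @param lock `"stimulus"`, `"response"` or `"com"`.
#' @param group Name of the column defining conditions (default
#'   `"response_type"`); its `"excluded"` level and `NA`s are dropped.
#' @param config A [task_config()].
#' @param min_trials Bins backed by fewer trials than this are dropped for
#'   the response- and com-locked kernels (default 100, as in the task's
#'   analysis); stimulus-locked kernels keep all bins.
#' @param per_participant Average within participants before averaging across
#'   them? Default `FALSE` (pooled).
#' @return A data frame of class `kernel_estimate` with columns `lock`,
#'   `condition`, `frame` (signed frame index relative to the lock), `time`
#'   (s), `mean`, `se`, `n`.
#' @export
compute_kernels <- function(trials, residuals, lock = c("stimulus", "response", "com"),
                            group = "response_type", config = task_config(),
                            min_trials = 100, per_participant = FALSE) {
  lock <- match.arg(lock)
  if (!group %in% names(trials)) stop("unknown group column: ", group)
  residuals <- as.matrix(residuals)
  if (nrow(residuals) != nrow(trials))
    stop("residuals must have one row per trial")
  n_frames <- ncol(residuals)

  cond <- trials[[group]]
  keep <- !is.na(cond) & cond != "excluded" & !is.na(trials$initial_rt)
  lock_frame <- switch(lock,
    stimulus = rep(0L, nrow(trials)),
    response = response_frame(trials$initial_rt, config),
    com = response_frame(trials$initial_rt + trials$com_latency, config))
  if (lock == "com") keep <- keep & trials$n_changes >= 1 & !is.na(trials$com_latency)
  keep <- keep & !is.na(lock_frame)

  tr <- trials[keep, , drop = FALSE]
  res <- residuals[keep, , drop = FALSE]
  lf <- lock_frame[keep]
  cond <- droplevels(factor(tr[[group]]))
  if (nrow(tr) == 0) {
    warning("no trials available for this kernel")
    out <- data.frame(lock = character(), condition = character(),
                      frame = integer(), time = numeric(), mean = numeric(),
                      se = numeric(), n = integer())
    class(out) <- c("kernel_estimate", class(out))
    return(out)
  }
  last <- last_shown_frame(tr, config, n_frames)
  min_trials <- if (lock == "stimulus") 0L else as.integer(min_trials)

  rel_range <- range(0L - lf, last - lf)
  rows <- list()
  pid <- if (per_participant) factor(tr$participant) else NULL
  for (r in seq(rel_range[1], rel_range[2])) {
    f <- lf + r
    ok <- f >= 0 & f <= last
    if (!any(ok)) next
    vals <- res[cbind(which(ok), f[ok] + 1L)]
    cc <- cond[ok]
    if (per_participant) {
      # mean per participant within condition, then across participants
      pp <- pid[ok]
      mtab <- tapply(vals, list(cc, pp), mean)
      m <- rowMeans(mtab, na.rm = TRUE)
      sdv <- apply(mtab, 1, stats::sd, na.rm = TRUE)
      np <- rowSums(!is.na(mtab))
      n <- as.integer(table(cc))
      se <- sdv / sqrt(pmax(np, 1))
    } else {
      m <- tapply(vals, cc, mean)
      sdv <- tapply(vals, cc, stats::sd)
      n <- as.integer(table(cc))
      se <- sdv / sqrt(n)
    }
    ok_cond <- n >= min_trials & n > 0
    if (!any(ok_cond)) next
    rows[[length(rows) + 1L]] <- data.frame(
      lock = lock, condition = names(m)[ok_cond], frame = r,
      time = r * config$frame_duration,
      mean = unname(m[ok_cond]), se = unname(se[ok_cond]),
      n = n[ok_cond], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("kernel_estimate", class(out))
  out
}

#' Median split of change-of-mind latencies
#'
#' Labels each single-change trial `"fast"` or `"slow"` by comparing its
#' change-of-mind latency against the median latency of its participant x
#' session cell. Latencies exactly at the median go to `"slow"`; cells with
#' fewer than two change trials are skipped with a warning.
#'
#' @param trials Trial data frame with `participant`, `session`, `n_changes`
#'   and `com_latency`.
#' @return Character vector aligned with `trials` rows: `"fast"`, `"slow"`,
#'   or `NA` for trials without exactly one change (or in skipped cells).
#' @export
median_split_com_rt <- function(trials) {
  lab <- rep(NA_character_, nrow(trials))
  is_com <- trials$n_changes == 1 & !is.na(trials$com_latency)
  cells <- interaction(trials$participant, trials$session, drop = TRUE)
  for (cell in levels(cells)) {
    idx <- which(is_com & cells == cell)
    if (length(idx) == 0) next
    if (length(idx) < 2) {
      warning("cell ", cell, " has fewer than 2 change-of-mind trials; skipped")
      next
    }
    lat <- trials$com_latency[idx]
    if (length(unique(lat)) == 1) {
      warning("cell ", cell, ": all change-of-mind latencies equal; ",
              "degenerate split, all labelled slow")
      lab[idx] <- "slow"
      next
    }
    med <- stats::median(lat)
    lab[idx] <- ifelse(lat < med, "fast", "slow")
  }
  lab
}

#' Moving-average smoothing of a kernel
#'
#' Centered moving average with an odd span, shrinking the window at edges
#' (and at interior gaps left by dropped bins). Display-only: statistics are
#' always run on unsmoothed series.
#'
#' @param kernel A [compute_kernels()] result.
#' @param span Odd window width in frames; default 3.
#' @return The kernel with smoothed `mean` values.
#' @export
smooth_kernel <- function(kernel, span = 3) {
  if (span < 1 || span %% 2 == 0) stop("span must be odd and >= 1")
  if (span == 1) return(kernel)
  h <- (span - 1) / 2
  for (cnd in unique(kernel$condition)) {
    sel <- which(kernel$condition == cnd)
    sel <- sel[order(kernel$frame[sel])]
    fr <- kernel$frame[sel]
    # smooth within runs of consecutive frames only
    run <- cumsum(c(1L, diff(fr) != 1L))
    for (rn in unique(run)) {
      ii <- sel[run == rn]
      x <- kernel$mean[ii]
      n <- length(x)
      sm <- vapply(seq_len(n), function(i)
        mean(x[max(1, i - h):min(n, i + h)]), numeric(1))
      kernel$mean[ii] <- sm
    }
  }
  kernel
}

#' Frame-wise t-tests between two trial conditions
#'
#' Two-sample t-tests on pooled residual-evidence values at each
#' (lock-relative) frame, comparing two conditions. Uncorrected for multiple
#' comparisons; intended as an illustrative overlay, with flags at the .01
#' and .05 alpha levels.
#'
#' @inheritParams compute_kernels
#' @param cond_a,cond_b The two condition labels (values of `group`) to
#'   compare.
#' @param alphas Significance levels to flag. Default `c(0.01, 0.05)`.
#' @param min_per_side Bins with fewer trials than this on either side get no
#'   flag. Default 2.
#' @return Data frame with `frame`, `time`, `n_a`, `n_b`, `statistic`, `p`,
#'   and logical flag columns `sig_01`, `sig_05` (one per alpha).
#' @export
framewise_tests <- function(trials, residuals, cond_a, cond_b,
                            lock = c("stimulus", "response", "com"),
                            group = "response_type", config = task_config(),
                            alphas = c(0.01, 0.05), min_per_side = 2) {
  lock <- match.arg(lock)
  residuals <- as.matrix(residuals)
  cond <- trials[[group]]
  keep <- !is.na(cond) & cond %in% c(cond_a, cond_b) & !is.na(trials$initial_rt)
  lock_frame <- switch(lock,
    stimulus = rep(0L, nrow(trials)),
    response = response_frame(trials$initial_rt, config),
    com = response_frame(trials$initial_rt + trials$com_latency, config))
  if (lock == "com") keep <- keep & trials$n_changes >= 1 & !is.na(trials$com_latency)
  tr <- trials[keep, , drop = FALSE]
  res <- residuals[keep, , drop = FALSE]
  lf <- lock_frame[keep]
  is_a <- tr[[group]] == cond_a
  last <- last_shown_frame(tr, config, ncol(res))

  rows <- list()
  for (r in seq(min(0L - lf), max(last - lf))) {
    f <- lf + r
    ok <- f >= 0 & f <= last
    na <- sum(ok & is_a); nb <- sum(ok & !is_a)
    if (na < min_per_side || nb < min_per_side) next
    va <- res[cbind(which(ok & is_a), f[ok & is_a] + 1L)]
    vb <- res[cbind(which(ok & !is_a), f[ok & !is_a] + 1L)]
    tt <- tryCatch(stats::t.test(va, vb), error = function(e) NULL)
    if (is.null(tt)) next
    row <- data.frame(frame = r, time = r * config$frame_duration,
                      n_a = na, n_b = nb,
                      statistic = unname(tt$statistic), p = tt$p.value)
    for (a in alphas)
      row[[paste0("sig_", sub("^0\\.", "", format(a)))]] <- tt$p.value < a
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' First-frame evidence contrast between change and no-change trials
#'
#' Computes, within each initial-accuracy class, the difference in mean
#' first-frame evidence *supporting the initial response* between trials with
#' and without a change of mind, and combines the two class contrasts
#' weighted by their change-trial counts. Negative values mean weaker
#' first-frame support for the initial response on change-of-mind trials (the
#' signature of stimulus-coupled drift variability); positive values the
#' opposite (the decoupled signature); zero the no-variability signature.
#'
#' @param trials Classified trial data frame (see [classify_response()]).
#' @param residuals Residual-evidence matrix (frame 0 in column 1), signed
#'   toward the correct side. The model-space stimulus-noise matrix can be
#'   passed directly.
#' @param n_boot Bootstrap resamples for the confidence interval (stratified
#'   by accuracy x change cell). Default 1000; 0 skips the CI.
#' @param conf Confidence level. Default 0.95.
#' @return List with `contrast`, `ci` (length 2 or `NULL`), per-class
#'   contrasts `by_accuracy`, and cell counts `n`.
#' @export
first_frame_contrast <- function(trials, residuals, n_boot = 1000,
                                 conf = 0.95) {
  residuals <- as.matrix(residuals)
  ok <- trials$response_type != "excluded" & !is.na(trials$initial_rt)
  tr <- trials[ok, , drop = FALSE]
  ff <- residuals[ok, 1]
  acc <- tr$initial_choice == tr$correct_side
  support <- ifelse(acc, ff, -ff)  # signed toward the initial response
  changed <- tr$n_changes >= 1

  cell_contrast <- function(sup, ch, ac) {
    vapply(c(FALSE, TRUE), function(a) {
      mean(sup[ch & ac == a]) - mean(sup[!ch & ac == a])
    }, numeric(1))
  }
  weights <- vapply(c(FALSE, TRUE), function(a) sum(changed & acc == a),
                    numeric(1))
  combine <- function(by_acc) sum(by_acc * weights) / sum(weights)
  by_acc <- cell_contrast(support, changed, acc)
  names(by_acc) <- c("initial_error", "initial_correct")
  est <- combine(by_acc)

  ci <- NULL
  if (n_boot > 0) {
    cells <- interaction(acc, changed, drop = TRUE)
    idx_by_cell <- split(seq_along(support), cells)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(idx_by_cell, function(ii)
        ii[sample.int(length(ii), replace = TRUE)]), use.names = FALSE)
      combine(cell_contrast(support[idx], changed[idx], acc[idx]))
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  }
  list(contrast = est, ci = ci, by_accuracy = by_acc,
       n = c(change = sum(changed), no_change = sum(!changed)))
}
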