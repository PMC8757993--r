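#' Apply the study's trial exclusions
#'
#' Drops, in order: trials without an initial response; trials with more than
#' one change of mind; trials whose change-of-mind latency is below 50 ms.
#' Trials with an initial response faster than 150 ms are screened and
#' counted but kept by default (in the study this screen rejected nothing);
#' set `exclude_fast_initial = TRUE` to drop them as well. A trial hitting
#' several rules is attributed to the first rule in that order.
#'
#' @param trials Raw trial data frame with columns `initial_choice`,
#'   `n_changes`, `com_latency`, `initial_rt`.
#' @param com_min_latency Minimum change-of-mind latency (s). Default 0.05.
#' @param fast_initial_rt Screening threshold for initial RT (s).
#'   Default 0.15.
#' @param exclude_fast_initial Drop (rather than just count) fast-initial
#'   trials? Default `FALSE`.
#' @return List with `trials` (retained rows), `retained_idx` (row indices
#'   into the input, for subsetting a parallel residual matrix) and `report`,
#'   an `exclusion_report` with per-rule counts (`n_input`, `n_no_response`,
#'   `n_multi_change`, `n_fast_com`, `n_fast_initial`, `n_retained`).
#' @export
apply_exclusions <- function(trials, com_min_latency = 0.05,
                             fast_initial_rt = 0.15,
                             exclude_fast_initial = FALSE) {
  req <- c("initial_choice", "n_changes", "com_latency", "initial_rt")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  no_resp <- trials$initial_choice == "none" | is.na(trials$initial_rt)
  multi <- !no_resp & trials$n_changes > 1
  fast_com <- !no_resp & !multi & !is.na(trials$com_latency) &
    trials$com_latency < com_min_latency
  fast_init <- !no_resp & !multi & !fast_com &
    trials$initial_rt < fast_initial_rt

  drop <- no_resp | multi | fast_com
  if (exclude_fast_initial) drop <- drop | fast_init

  report <- list(
    n_input = nrow(trials),
    n_no_response = sum(no_resp),
    n_multi_change = sum(multi),
    n_fast_com = sum(fast_com),
    n_fast_initial = sum(fast_init),
    fast_initial_excluded = exclude_fast_initial,
    n_retained = sum(!drop))
  class(report) <- "exclusion_report"
  list(trials = trials[!drop, , drop = FALSE],
       retained_idx = which(!drop), report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Trial exclusions\n")
  cat(sprintf("  input:            %d\n", x$n_input))
  cat(sprintf("  no response:      %d\n", x$n_no_response))
  cat(sprintf("  >1 change:        %d\n", x$n_multi_change))
  cat(sprintf("  CoM < 50 ms:      %d\n", x$n_fast_com))
  cat(sprintf("  initial < 150 ms: %d (%s)\n", x$n_fast_initial,
              if (x$fast_initial_excluded) "excluded" else "screened only"))
  cat(sprintf("  retained:         %d\n", x$n_retained))
  invisible(x)
}

#' Attach evidence predictors to trials
#'
#' Computes, per trial: `first_frame` (frame-0 residual evidence),
#' `pre_response_mean` (mean residual over frames 1 to the frame before the
#' initial response, excluding the first frame), and one mean per requested
#' stimulus-onset window, over the frames whose onsets fall in `[a, b)`.
#' Window frames beyond the initial response are not available to the
#' observer pre-decision, so window means are computed over the pre-response
#' portion only; trials where this truncates the window are flagged in
#' `<name>_partial`.
#'
#' @param trials Trial data frame (responded trials; rows align with
#'   `residuals`).
#' @param residuals Residual-evidence matrix, frame 0 in column 1.
#' @param config A [task_config()].
#' @param windows Named list of `c(start, end)` windows in seconds. Default
#'   `list(win_0_200 = c(0, 0.2), win_200_400 = c(0.2, 0.4))`.
#' @return `trials` with predictor columns appended; all predictors lie in
#'   `[-1, 1]`.
#' @export
attach_evidence_predictors <- function(trials, residuals,
                                       config = task_config(),
                                       windows = list(win_0_200 = c(0, 0.2),
                                                      win_200_400 = c(0.2, 0.4))) {
  residuals <- as.matrix(residuals)
  if (nrow(residuals) != nrow(trials))
    stop("residuals must have one row per trial")
  n_frames <- ncol(residuals)
  rf <- response_frame(trials$initial_rt, config)

  trials$first_frame <- residuals[, 1]
  pre_mean <- rep(NA_real_, nrow(trials))
  for (i in seq_len(nrow(trials))) {
    if (is.na(rf[i]) || rf[i] < 2) next  # needs at least frame 1 pre-response
    pre_mean[i] <- mean(residuals[i, 2:min(rf[i], n_frames)])
  }
  trials$pre_response_mean <- pre_mean

  onsets <- (seq_len(n_frames) - 1) * config$frame_duration
  for (nm in names(windows)) {
    w <- windows[[nm]]
    in_win <- which(onsets >= w[1] & onsets < w[2])
    if (!length(in_win)) stop("window ", nm, " covers no frame onsets")
    mean_w <- rep(NA_real_, nrow(trials))
    partial <- rep(FALSE, nrow(trials))
    for (i in seq_len(nrow(trials))) {
      if (is.na(rf[i])) next
      avail <- in_win[in_win <= rf[i]]  # pre-response frames only
      if (length(avail) < length(in_win)) partial[i] <- TRUE
      if (length(avail)) mean_w[i] <- mean(residuals[i, avail])
    }
    trials[[nm]] <- mean_w
    trials[[paste0(nm, "_partial")]] <- partial
  }
  trials
}

# Nakagawa marginal/conditional pseudo-R2 for an lme4 fit (logit link uses
# pi^2/3 as the residual variance; gaussian uses the estimated sigma^2)
r2_nakagawa <- function(fit) {
  vf <- stats::var(as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vr <- sum(vc$vcov[is.na(vc$var2) & vc$grp != "Residual"])
  ve <- if (inherits(fit, "glmerMod")) pi^2 / 3 else stats::sigma(fit)^2
  c(marginal = vf / (vf + vr + ve),
    conditional = (vf + vr) / (vf + vr + ve))
}

# shared mixed-model LR machinery for the probability / speed models
com_interaction_test <- function(data, response, evidence, family) {
  f_full <- stats::as.formula(paste(
    response, "~ accuracy *", evidence, "+ (1 | participant)"))
  f_red <- stats::as.formula(paste(
    response, "~ accuracy +", evidence, "+ (1 | participant)"))
  fit1 <- fit0 <- NULL
  msgs <- character()
  wh <- withCallingHandlers({
    if (family == "binomial") {
      fit1 <- lme4::glmer(f_full, data = data, family = stats::binomial())
      fit0 <- lme4::glmer(f_red, data = data, family = stats::binomial())
    } else {
      fit1 <- lme4::lmer(f_full, data = data, REML = FALSE)
      fit0 <- lme4::lmer(f_red, data = data, REML = FALSE)
    }
  }, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  an <- stats::anova(fit0, fit1)
  conv_ok <- !any(grepl("failed to converge", msgs))
  cf <- lme4::fixef(fit1)
  int_name <- grep(":", names(cf), value = TRUE)
  structure(list(
    model_full = fit1, model_reduced = fit0,
    lr_chisq = an$Chisq[2], df = an$Df[2], p = an$`Pr(>Chisq)`[2],
    coef = cf, interaction = unname(cf[int_name]),
    aic = stats::AIC(fit1), r2 = r2_nakagawa(fit1),
    converged = conv_ok, messages = msgs,
    coding = paste("treatment coding; accuracy 1 = initial choice correct;",
                   "evidence signed toward the correct side"),
    evidence = evidence),
    class = "com_model_test")
}

#' @export
print.com_model_test <- function(x, ...) {
  cat("Accuracy x evidence interaction (likelihood-ratio test)\n")
  cat(sprintf("  evidence: %s\n", x$evidence))
  cat(sprintf("  chisq(%d) = %.3f, p = %.3g\n", x$df, x$lr_chisq, x$p))
  cat(sprintf("  interaction coefficient = %.4f\n", x$interaction))
  cat(sprintf("  AIC (full) = %.1f; R2 marginal/conditional = %.3f/%.3f\n",
              x$aic, x$r2["marginal"], x$r2["conditional"]))
  if (!x$converged) cat("  NOTE: convergence warnings; treat with caution\n")
  invisible(x)
}

#' Mixed-effects model of change-of-mind probability
#'
#' Logistic mixed-effects regression of change-of-mind occurrence on initial
#' accuracy, an evidence predictor, and their interaction, with a random
#' intercept per participant; the interaction is tested by a likelihood-ratio
#' test against the same model without it. Because evidence is signed toward
#' the correct side, "support for the initial decision" is carried by the
#' interaction: a negative interaction coefficient (with accuracy coded
#' 1 = initial correct) means changes of mind are less likely when the
#' evidence supported the initial choice.
#'
#' @param trials Retained trials (after [apply_exclusions()]) with predictor
#'   columns from [attach_evidence_predictors()] and columns `correct_side`,
#'   `initial_choice`, `n_changes`, `participant`.
#' @param evidence Name of the predictor column: `"first_frame"` (default),
#'   `"pre_response_mean"`, or a window-mean column.
#' @return A `com_model_test` list: fitted models, LR `chisq`/`df`/`p`,
#'   coefficients, interaction estimate, AIC, Nakagawa pseudo-R2, and a
#'   convergence flag (non-convergence is flagged, never silently replaced).
#' @export
fit_com_probability_model <- function(trials, evidence = "first_frame") {
  if (!evidence %in% names(trials)) stop("no such predictor: ", evidence)
  if (length(unique(trials$participant)) < 2)
    stop("need at least 2 participants for a random intercept")
  d <- data.frame(
    com = as.integer(trials$n_changes >= 1),
    accuracy = as.integer(trials$initial_choice == trials$correct_side),
    participant = factor(trials$participant))
  d[[evidence]] <- trials[[evidence]]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  com_interaction_test(d, "com", evidence, "binomial")
}

#' Mixed-effects model of change-of-mind speed
#'
#' Linear mixed model of change-of-mind latency (untransformed, s) on initial
#' accuracy x evidence with a participant random intercept, fit by maximum
#' likelihood; LR test of the interaction. Only single-change trials enter.
#' A positive interaction coefficient (accuracy coded 1 = initial correct)
#' means slower changes of mind when the evidence supported the initial
#' choice.
#'
#' @inheritParams fit_com_probability_model
#' @return A `com_model_test` list (see [fit_com_probability_model()]).
#' @export
fit_com_speed_model <- function(trials, evidence = "first_frame") {
  if (!evidence %in% names(trials)) stop("no such predictor: ", evidence)
  tr <- trials[trials$n_changes == 1 & !is.na(trials$com_latency), ,
               drop = FALSE]
  if (length(unique(tr$participant)) < 2)
    stop("need at least 2 participants for a random intercept")
  d <- data.frame(
    com_latency = tr$com_latency,
    accuracy = as.integer(tr$initial_choice == tr$correct_side),
    participant = factor(tr$participant))
  d[[evidence]] <- tr[[evidence]]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  com_interaction_test(d, "com_latency", evidence, "gaussian")
}

#' Compare evidence-window predictors of change-of-mind probability
#'
#' Fits the change-probability model once per window predictor and reports
#' AIC and marginal/conditional pseudo-R2 for each. The models are not
#' nested, so no p-value is attached.
#'
#' @param trials As in [fit_com_probability_model()].
#' @param predictors Character vector of predictor column names to compare.
#' @return Data frame with one row per predictor: `predictor`, `aic`,
#'   `r2_marginal`, `r2_conditional`, `converged`.
#' @export
compare_evidence_windows <- function(trials,
                                     predictors = c("win_0_200", "win_200_400")) {
  rows <- lapply(predictors, function(pr) {
    fit <- fit_com_probability_model(trials, evidence = pr)
    data.frame(predictor = pr, aic = fit$aic,
               r2_marginal = unname(fit$r2["marginal"]),
               r2_conditional = unname(fit$r2["conditional"]),
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
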