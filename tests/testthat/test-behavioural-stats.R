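test_that("exclusion rules count one trial each on the rule-per-trial fixture", {
  fx <- make_fixture("exclusions")
  # default: the 150 ms rule screens but does not exclude
  out <- apply_exclusions(fx)
  expect_equal(out$report$n_no_response, 1)
  expect_equal(out$report$n_multi_change, 1)
  expect_equal(out$report$n_fast_com, 1)
  expect_equal(out$report$n_fast_initial, 1)
  expect_equal(out$report$n_retained, 3)
  # with the screen turned into an exclusion, two clean trials remain
  strict <- apply_exclusions(fx, exclude_fast_initial = TRUE)
  expect_equal(strict$report$n_retained, 2)
  expect_equal(nrow(strict$trials), 2)
})

test_that("clean tables pass through exclusions untouched", {
  tr <- rbind(trial_row("left", "left", 0L, 0.5),
              trial_row("right", "left", 1L, 0.5, 0.4))
  out <- apply_exclusions(tr)
  expect_equal(out$trials, tr)
  expect_equal(out$report$n_no_response + out$report$n_multi_change +
                 out$report$n_fast_com + out$report$n_fast_initial, 0)
})

test_that("a trial hitting several rules is attributed to the first rule", {
  tr <- trial_row("none", "none", 2L, NA_real_)  # no response AND multi-change
  out <- apply_exclusions(tr)
  expect_equal(out$report$n_no_response, 1)
  expect_equal(out$report$n_multi_change, 0)
})

test_that("exclusion reports are stable under row permutation", {
  fx <- make_fixture("exclusions")
  set.seed(30)
  perm <- sample(nrow(fx))
  a <- apply_exclusions(fx)$report
  b <- apply_exclusions(fx[perm, ])$report
  expect_equal(unclass(a), unclass(b))
})

test_that("evidence predictors reduce to the constant on constant residuals", {
  tr <- trial_row("left", "left", 0L, 0.41)
  res <- matrix(0.25, 1, 40)
  out <- attach_evidence_predictors(tr, res)
  expect_equal(out$first_frame, 0.25)
  expect_equal(out$pre_response_mean, 0.25)
  expect_equal(out$win_0_200, 0.25)
  expect_equal(out$win_200_400, 0.25)
})

test_that("a 0-200 ms window covers exactly 15 frame onsets", {
  cfg <- task_config()
  onsets <- (0:(cfg$n_frames_total - 1)) * cfg$frame_duration
  expect_equal(sum(onsets >= 0 & onsets < 0.2), 15)
  # long-RT trial: full window available, equals the plain 15-frame mean
  tr <- trial_row("left", "left", 0L, 0.79)
  set.seed(31)
  res <- matrix(rnorm(60, sd = 0.3), 1, 60)
  out <- attach_evidence_predictors(tr, res, cfg)
  expect_equal(out$win_0_200, mean(res[1, 1:15]))
  expect_false(out$win_0_200_partial)
})

test_that("pre-response mean excludes the first frame", {
  # response in frame 3; residuals {1, 0, 0} over frames 0..2
  tr <- trial_row("left", "left", 0L, 0.045)
  res <- matrix(c(1, 0, 0), 1, 3)
  out <- attach_evidence_predictors(tr, res, windows = list(w = c(0, 0.04)))
  expect_equal(out$pre_response_mean, 0)
  expect_equal(out$first_frame, 1)
})

test_that("windows truncated by an early response are flagged as partial", {
  tr <- trial_row("left", "left", 0L, 0.1)  # response in frame 7
  res <- matrix(0.2, 1, 30)
  out <- attach_evidence_predictors(tr, res,
                                    windows = list(w = c(0, 0.2)))
  expect_true(out$w_partial)
  expect_equal(out$w, 0.2)  # mean over the available pre-response frames
})

# shared small coupled dataset for the model-fitting checks below
local({
  ds <- generate_dataset(study_design(n_participants = 3,
                                      sessions_per_participant = 1,
                                      trials_per_session = 1200, seed = 8))
  ex <- apply_exclusions(ds$trials)
  tr <- classify_response(
    attach_evidence_predictors(ex$trials, ds$residuals[ex$retained_idx, ]))

  test_that("change-probability model recovers the interaction direction", {
    m <- fit_com_probability_model(tr, "first_frame")
    expect_s3_class(m, "com_model_test")
    expect_lt(m$p, 0.05)
    expect_lt(m$interaction, 0)
    # slopes: evidence toward the correct side raises changes after errors
    # and lowers them after correct initials
    slope_err <- unname(m$coef["first_frame"])
    slope_corr <- slope_err + m$interaction
    expect_gt(slope_err, 0)
    expect_lt(slope_corr, 0)
  })

  test_that("likelihood-ratio statistic is invariant to predictor scaling", {
    m1 <- fit_com_probability_model(tr, "first_frame")
    tr2 <- tr
    tr2$first_frame <- tr2$first_frame * 3
    m2 <- fit_com_probability_model(tr2, "first_frame")
    expect_equal(m1$lr_chisq, m2$lr_chisq, tolerance = 1e-3)
  })

  test_that("a constant evidence predictor yields a null interaction test", {
    tr0 <- tr
    tr0$first_frame <- 0
    m <- suppressMessages(fit_com_probability_model(tr0, "first_frame"))
    expect_lt(m$lr_chisq, 1e-6)
  })

  test_that("change-speed model runs on change trials and reports the LR test", {
    m <- fit_com_speed_model(tr, "first_frame")
    expect_s3_class(m, "com_model_test")
    expect_true(is.finite(m$lr_chisq))
    expect_equal(m$df, 1)
    expect_equal(nrow(m$model_full@frame), sum(tr$n_changes == 1))
  })

  test_that("window comparison reports AIC and pseudo-R2 per predictor", {
    cmp <- compare_evidence_windows(tr)
    expect_equal(nrow(cmp), 2)
    expect_true(all(is.finite(cmp$aic)))
    expect_true(all(cmp$r2_conditional >= cmp$r2_marginal - 1e-12))
    expect_true(all(cmp$r2_marginal > 0 & cmp$r2_conditional < 1))
  })
})
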