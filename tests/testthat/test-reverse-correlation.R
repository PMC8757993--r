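test_that("response classification follows the four-type taxonomy", {
  tr <- rbind(
    trial_row("left", "left", 0L, 0.4),                 # correct
    trial_row("right", "right", 0L, 0.4),               # error
    trial_row("right", "left", 1L, 0.4, 0.3),           # corrected error
    trial_row("left", "right", 1L, 0.4, 0.3),           # spoilt correct
    trial_row("left", "right", 2L, 0.4, 0.3),           # double change
    trial_row("none", "none", 0L, NA_real_))            # no response
  out <- classify_response(tr)
  expect_equal(as.character(out$response_type),
               c("correct", "error", "corrected_error", "spoilt_correct",
                 "excluded", "excluded"))
  # group sizes are conserved
  expect_equal(sum(table(out$response_type)), nrow(tr))
})

test_that("inconsistent trial records are rejected", {
  expect_error(classify_response(trial_row("left", "left", 0L, 0.4, com = 0.3)),
               "com_latency")
  expect_error(classify_response(trial_row("left", "right", 0L, 0.4)),
               "final_choice")
  expect_error(classify_response(data.frame(a = 1)), "missing columns")
})

test_that("kernel bin means equal brute-force averages on a hand-built fixture", {
  fx <- make_fixture("kernels")
  tr <- classify_response(fx$trials)
  cfg <- task_config()

  k_stim <- compute_kernels(tr, fx$residuals, lock = "stimulus", config = cfg)
  # brute force: average each frame within each response type
  for (f in 0:4) {
    expect_equal(k_stim$mean[k_stim$condition == "correct" & k_stim$frame == f],
                 mean(fx$residuals[1:2, f + 1]))
    expect_equal(k_stim$mean[k_stim$condition == "error" & k_stim$frame == f],
                 fx$residuals[3, f + 1])
  }
  expect_equal(unique(k_stim$n[k_stim$condition == "correct"]), 2L)

  # response lock: all three trials responded in frame 5, so displayed
  # frames 0..4 sit at relative positions -5..-1
  k_resp <- compute_kernels(tr, fx$residuals, lock = "response", config = cfg,
                            min_trials = 1)
  expect_equal(sort(unique(k_resp$frame)), -5:-1)
  for (r in -5:-1) {
    expect_equal(k_resp$mean[k_resp$condition == "correct" & k_resp$frame == r],
                 mean(fx$residuals[1:2, r + 5 + 1]))
  }
})

test_that("under-populated bins are dropped for response-locked kernels only", {
  # 99 corrected errors vs 120 spoilt corrects, identical timing
  mk <- function(n, initial, final) {
    do.call(rbind, replicate(n, trial_row(initial, final, 1L, 0.4, 0.3),
                             simplify = FALSE))
  }
  tr <- classify_response(rbind(mk(99, "right", "left"), mk(120, "left", "right")))
  res <- matrix(0.1, nrow(tr), 60)
  k_com <- compute_kernels(tr, res, lock = "com", min_trials = 100)
  expect_false("corrected_error" %in% k_com$condition)
  expect_true("spoilt_correct" %in% k_com$condition)
  # stimulus-locked kernels keep all conditions regardless
  k_stim <- compute_kernels(tr, res, lock = "stimulus", min_trials = 100)
  expect_true(all(c("corrected_error", "spoilt_correct") %in% k_stim$condition))
})

test_that("median split labels fast and slow within participant-session cells", {
  tr <- do.call(rbind, lapply(c(0.2, 0.4, 0.6, 0.8), function(lat)
    trial_row("right", "left", 1L, 0.4, lat)))
  expect_equal(median_split_com_rt(tr), c("fast", "fast", "slow", "slow"))
})

test_that("per-cell and pooled median splits disagree on an asymmetric fixture", {
  fx <- make_fixture("median_split")
  per_cell <- median_split_com_rt(fx)
  # direct computation: cell medians are 0.55 (session 1) and 0.35 (session 2)
  expect_equal(per_cell, c("fast", "fast", "slow", "slow", "fast", "slow"))
  # pooled split across sessions, computed directly
  pooled_med <- median(fx$com_latency)
  pooled <- ifelse(fx$com_latency < pooled_med, "fast", "slow")
  expect_false(all(per_cell == pooled))
})

test_that("degenerate equal latencies all go to slow with a warning", {
  tr <- do.call(rbind, lapply(rep(0.3, 4), function(lat)
    trial_row("right", "left", 1L, 0.4, lat)))
  expect_warning(lab <- median_split_com_rt(tr), "degenerate")
  expect_equal(lab, rep("slow", 4))
})

test_that("cells with fewer than two change trials are skipped with a warning", {
  tr <- rbind(trial_row("right", "left", 1L, 0.4, 0.3),
              trial_row("left", "left", 0L, 0.4))
  expect_warning(lab <- median_split_com_rt(tr), "fewer than 2")
  expect_true(all(is.na(lab)))
})

test_that("moving-average smoothing shrinks at edges and keeps statistics pristine", {
  k <- data.frame(lock = "stimulus", condition = "all", frame = 0:2,
                  time = (0:2) / 75, mean = c(0, 3, 0), se = 1, n = 10L)
  sm <- smooth_kernel(k, span = 3)
  expect_equal(sm$mean, c(1.5, 1, 1.5))
  expect_equal(smooth_kernel(k, span = 1)$mean, k$mean)  # identity
  kc <- k; kc$mean <- rep(2, 3)
  expect_equal(smooth_kernel(kc, span = 3)$mean, rep(2, 3))  # constant
  expect_error(smooth_kernel(k, span = 2), "odd")
})

test_that("framewise test flags nest across alpha levels and catch a planted shift", {
  set.seed(21)
  n <- 200
  tr <- classify_response(rbind(
    do.call(rbind, replicate(n, trial_row("left", "left", 0L, 0.4),
                             simplify = FALSE)),
    do.call(rbind, replicate(n, trial_row("right", "right", 0L, 0.4),
                             simplify = FALSE))))
  res <- matrix(rnorm(2 * n * 10, sd = 0.3), 2 * n, 10)
  res[1:n, 4] <- res[1:n, 4] + 0.3  # 1-SD shift at frame 3, group A only
  ft <- framewise_tests(tr, res, "correct", "error", lock = "stimulus")
  expect_true(ft$sig_01[ft$frame == 3])
  # nesting: everything significant at .01 is significant at .05
  expect_true(all(ft$sig_05[ft$sig_01]))
})

test_that("null data produce flags at no more than the nominal rate", {
  set.seed(22)
  n <- 150
  tr <- classify_response(rbind(
    do.call(rbind, replicate(n, trial_row("left", "left", 0L, 0.4),
                             simplify = FALSE)),
    do.call(rbind, replicate(n, trial_row("right", "right", 0L, 0.4),
                             simplify = FALSE))))
  res <- matrix(rnorm(2 * n * 100, sd = 0.3), 2 * n, 100)
  ft <- framewise_tests(tr, res, "correct", "error", lock = "stimulus")
  # 100 independent null bins at alpha .01: P(more than 5 hits) < 1e-5
  expect_lte(sum(ft$sig_01), 5)
})

test_that("kernels from decision-independent residuals are flat at zero", {
  set.seed(23)
  n <- 4000
  correct <- rep(c(TRUE, FALSE), length.out = n)
  tr <- classify_response(data.frame(
    participant = 1L, session = 1L, correct_side = "left",
    initial_choice = ifelse(correct, "left", "right"),
    final_choice = ifelse(correct, "left", "right"),
    initial_rt = 0.5, n_changes = 0L, com_latency = NA_real_,
    stringsAsFactors = FALSE))
  res <- matrix(rnorm(n * 30, sd = 0.38), n, 30)
  tr$all <- "all"
  k <- compute_kernels(tr, res, lock = "stimulus", group = "all")
  expect_true(all(abs(k$mean) < 4 * k$se))
})

test_that("coupled-model kernels show the change-of-mind topology", {
  p <- preset_study_like()
  cfg <- task_config()
  set.seed(24)
  sim <- simulate_experiment(p, "coupled", cfg, n_trials = 30000)
  tr <- classify_response(sim$trials)
  k <- compute_kernels(tr, sim$stim_noise, lock = "stimulus", config = cfg)
  ce <- k[k$condition == "corrected_error", ]
  # early evidence favours the (wrong) initial response, late evidence the
  # correct final response: the kernel crosses zero
  expect_lt(mean(ce$mean[ce$frame <= 5]), 0)
  expect_gt(mean(ce$mean[ce$frame >= 30 & ce$frame <= 60]), 0)
  # frame 0: corrected errors carry weaker evidence for the initial (error)
  # response than uncorrected errors
  err <- k[k$condition == "error", ]
  expect_gt(ce$mean[ce$frame == 0], err$mean[err$frame == 0])
})
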