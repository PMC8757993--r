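test_that("drift rate composes mean drift, snapshot and internal variability", {
  p <- test_params(mu = 0.1, s = 1, slope = 0)
  # all variability off -> constant mu
  p0 <- test_params(mu = 0.1, s = 0, slope = 0)
  expect_equal(drift_at(p0, c(0, 0.5, 2), first_frame = 0.7),
               rep(0.1, 3))
  # literal substitution into the linear form
  expect_equal(drift_at(p, t = 2, first_frame = 0.5,
                        external_decay = "literal"), 0.6)
  expect_error(drift_at(p, t = -1, first_frame = 0), "non-negative")
})

test_that("snapshot decay reaches exactly zero at the independently derived time", {
  p <- test_params(mu = 0.07, s = 1, slope = 0.5)
  ff <- 0.5
  t_star <- p$s * abs(ff) / p$slope  # zero-crossing, derived by hand
  expect_equal(t_star, 1)
  tt <- seq(0, 3, by = 0.01)
  d <- drift_at(p, tt, first_frame = ff)
  expect_true(all(d[tt >= t_star] == p$mu))
  expect_true(all(d[tt < t_star] > p$mu))
  # sign-symmetric: negative first frame decays up toward mu
  d_neg <- drift_at(p, tt, first_frame = -ff)
  expect_true(all(d_neg[tt >= t_star] == p$mu))
  expect_true(all(d_neg[tt < t_star] < p$mu))
})

test_that("noiseless accumulation is ballistic with the exact crossing time", {
  p <- test_params(theta = 0, endo_noise_sd = 0, Sz = 0, eta = 0, s = 0,
                   mu = 0.2, B = 0.12, tnd = 0.2, tndVar = 0)
  cfg <- task_config()
  set.seed(10)
  sim <- simulate_experiment(p, "novar", cfg, n_trials = 3)
  tr <- sim$trials
  expect_true(all(tr$initial_choice == tr$correct_side))
  # crossing of B from B/2 at rate mu: (B/2)/mu = 0.3 s, within one step
  expect_true(all(abs(tr$decision_time - 0.3) <= p$stepsize + 1e-12))
  expect_equal(tr$initial_rt, tr$decision_time + 0.2)
  expect_true(all(tr$n_changes == 0))
})

test_that("zero drift yields symmetric choices", {
  p <- test_params(mu = 0, Sz = 0)
  cfg <- task_config(deadline = 3)  # long deadline so nearly all respond
  set.seed(11)
  sim <- simulate_experiment(p, "novar", cfg, n_trials = 20000,
                             return_noise = FALSE)
  tr <- sim$trials[sim$trials$responded, ]
  phat <- mean(tr$initial_choice == tr$correct_side)
  expect_lt(abs(phat - 0.5), 4 * sqrt(0.25 / nrow(tr)))
})

test_that("simulation is deterministic under a fixed seed", {
  p <- test_params(eta = 0.05, s = 0.08, slope = 0.05)
  cfg <- task_config()
  set.seed(42)
  a <- simulate_experiment(p, "coupled", cfg, n_trials = 500)
  set.seed(42)
  b <- simulate_experiment(p, "coupled", cfg, n_trials = 500)
  expect_identical(a$trials, b$trials)
  expect_identical(a$stim_noise, b$stim_noise)
})

test_that("single-trial and batch simulation share the same draws", {
  p <- test_params()
  cfg <- task_config()
  set.seed(7)
  one <- simulate_trial(p, "novar", cfg)
  set.seed(7)
  batch <- simulate_experiment(p, "novar", cfg, n_trials = 1)
  expect_identical(one$trials, batch$trials)
  expect_equal(nrow(one$trials), 1L)
})

test_that("non-responses respect the deadline and are flagged", {
  p <- test_params(mu = 0.02, B = 0.3, tnd = 0.3)  # slow: many misses
  cfg <- task_config()
  set.seed(12)
  sim <- simulate_experiment(p, "novar", cfg, n_trials = 2000,
                             return_noise = FALSE)
  tr <- sim$trials
  expect_gt(sum(!tr$responded), 0)
  expect_true(all(is.na(tr$initial_rt[!tr$responded])))
  expect_true(all(tr$initial_choice[!tr$responded] == "none"))
  expect_true(all(tr$initial_rt[tr$responded] <= cfg$deadline + 1e-12))
})

test_that("change-of-mind rate is monotone in the change threshold", {
  cfg <- task_config()
  grid <- c(0.5, 0.8, 1, 1.3)  # B_CoM as multiples of B, spanning past B
  rates <- vapply(grid, function(g) {
    p <- test_params(B_CoM = g * 0.12)
    set.seed(99)  # common random numbers across the grid
    sim <- simulate_experiment(p, "novar", cfg, n_trials = 4000,
                               return_noise = FALSE)
    mean(sim$trials$n_changes[sim$trials$responded] >= 1)
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_lt(rates[length(rates)], rates[1])
})

test_that("raising the bound raises accuracy and slows decisions", {
  cfg <- task_config(deadline = 3)
  out <- lapply(c(0.08, 0.16), function(B) {
    p <- test_params(B = B, B_CoM = B)
    set.seed(123)
    sim <- simulate_experiment(p, "novar", cfg, n_trials = 5000,
                               return_noise = FALSE)
    tr <- sim$trials[sim$trials$responded, ]
    c(acc = mean(tr$initial_choice == tr$correct_side),
      dt = mean(tr$decision_time))
  })
  expect_gt(out[[2]]["acc"], out[[1]]["acc"])
  expect_gt(out[[2]]["dt"], out[[1]]["dt"])
})

test_that("changes of mind are more frequent after errors than after correct responses", {
  cfg <- task_config()
  for (mu in c(0.08, 0.14)) {
    p <- test_params(mu = mu, eta = 0.05, s = 0.08, slope = 0.05)
    set.seed(31)
    sim <- simulate_experiment(p, "coupled", cfg, n_trials = 10000,
                               return_noise = FALSE)
    tr <- sim$trials[sim$trials$responded, ]
    err <- tr$initial_choice != tr$correct_side
    expect_gt(mean(tr$n_changes[err] >= 1), mean(tr$n_changes[!err] >= 1))
  }
})

test_that("simulated stimulus noise has zero mean per frame", {
  p <- test_params()
  cfg <- task_config()
  set.seed(13)
  sim <- simulate_experiment(p, "novar", cfg, n_trials = 20000)
  m <- colMeans(sim$stim_noise)
  se <- apply(sim$stim_noise, 2, sd) / sqrt(nrow(sim$stim_noise))
  expect_true(all(abs(m) < 4 * se))
  # truncation at 1 SD holds for internal draws
  expect_true(all(abs(sim$stim_noise) <= p$theta))
})

test_that("invalid parameterizations are rejected", {
  expect_error(model_params(B = 0), "B must be positive")
  expect_error(model_params(B = 0.1, Sz = 0.1), "Sz")
  expect_error(model_params(B = 0.1, timeOut = 1.2), "timeOut")
  expect_error(model_params(B = 0.1, tnd = 0), "tnd")
  expect_error(test_params(eta = -1), "non-negative")
})

test_that("parameters round-trip through JSON by symbol name", {
  p <- test_params(eta = 0.05, s = 0.08)
  f <- tempfile(fileext = ".json")
  write_params(p, f)
  keys <- names(jsonlite::read_json(f))
  expect_true(all(c("B", "Sz", "B_CoM", "timeOut", "mu", "eta", "slope",
                    "s", "theta", "tnd", "tndVar") %in% keys))
  q <- read_params(f)
  expect_equal(unclass(q), unclass(p))
  unlink(f)
})
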