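trial_label <- function(ds, k) {
  rows <- ds$trial_id == k & ds$decision_mask
  unique(ds$targets[rows, 1])
}

test_that("noiseless perceptual trials are separable by a mean threshold", {
  ds <- make_perceptual_dm(10, coherences = c(-0.5, 0.5), noise_sd = 0,
                           seed = 1)
  for (k in 1:10) {
    # during the stimulus epoch x2 + x3 = 2 * baseline = 1, elsewhere 0
    stim <- ds$trial_id == k & (ds$inputs[, "x2"] + ds$inputs[, "x3"]) != 0
    decided <- if (mean(ds$inputs[stim, "x2"] - ds$inputs[stim, "x3"]) > 0)
      1L else 2L
    expect_identical(decided, trial_label(ds, k))
  }
})

test_that("perceptual labels are balanced and bookkeeping holds", {
  ds <- make_perceptual_dm(10000, seed = 7)
  labs <- vapply(1:10000, function(k) trial_label(ds, k), integer(1))
  expect_gte(mean(labs == 1), 0.49)
  expect_lte(mean(labs == 1), 0.51)
  expect_equal(nrow(ds$inputs), 10000 * (3 + 10 + 3))
  # trials tile time without overlap; mask only inside trials
  expect_equal(unname(ds$trial_bounds[1, 1]), 1)
  expect_equal(unname(ds$trial_bounds[10000, 2]), nrow(ds$inputs) + 1)
  expect_true(all(ds$targets[!ds$decision_mask, 1] == 0))
  expect_true(all(ds$targets[ds$decision_mask, 1] %in% c(1, 2)))
  expect_error(make_perceptual_dm(5, coherences = numeric(0)),
               class = "connrc_parameter_error")
})

test_that("context task has 7 channels, a one-hot cue, and follows the cued modality", {
  ds <- make_context_dm(200, noise_sd = 0, seed = 3)
  expect_equal(ncol(ds$inputs), 7)
  in_trial <- ds$inputs[, "x1"] == 1
  expect_true(all(ds$inputs[in_trial, "x2"] + ds$inputs[in_trial, "x3"] == 1))
  n_disagree <- 0
  for (k in 1:200) {
    stim <- ds$trial_id == k & ds$inputs[, "x4"] != 0
    cue <- if (ds$inputs[which(ds$trial_id == k)[1], "x2"] == 1) 1L else 2L
    d1 <- mean(ds$inputs[stim, "x4"] - ds$inputs[stim, "x5"])
    d2 <- mean(ds$inputs[stim, "x6"] - ds$inputs[stim, "x7"])
    if (sign(d1) != sign(d2)) n_disagree <- n_disagree + 1
    cued <- if (cue == 1L) d1 else d2
    expect_identical(if (cued > 0) 1L else 2L, trial_label(ds, k))
  }
  expect_gt(n_disagree, 0)  # the check above exercised disagreeing trials
})

test_that("a linear rule on the cued decision variable solves both tasks", {
  # task solvability ceiling, independent of any reservoir
  dsp <- make_perceptual_dm(300, noise_sd = 0, seed = 5)
  okp <- vapply(1:300, function(k) {
    stim <- dsp$trial_id == k & dsp$inputs[, "x2"] != 0
    d <- mean(dsp$inputs[stim, "x2"] - dsp$inputs[stim, "x3"])
    (if (d > 0) 1L else 2L) == trial_label(dsp, k)
  }, logical(1))
  expect_true(all(okp))
  dsc <- make_context_dm(300, noise_sd = 0, seed = 6)
  okc <- vapply(1:300, function(k) {
    stim <- dsc$trial_id == k & dsc$inputs[, "x4"] != 0
    cue1 <- dsc$inputs[which(dsc$trial_id == k)[1], "x2"] == 1
    d <- if (cue1) mean(dsc$inputs[stim, "x4"] - dsc$inputs[stim, "x5"])
         else mean(dsc$inputs[stim, "x6"] - dsc$inputs[stim, "x7"])
    (if (d > 0) 1L else 2L) == trial_label(dsc, k)
  }, logical(1))
  expect_true(all(okc))
})

test_that("memory-capacity targets are exact lagged copies of the input", {
  ds <- make_memory_capacity(500, max_lag = 5, washout = 50, seed = 2)
  u <- ds$inputs[, 1]
  for (k in 1:5) {
    scored <- which(ds$decision_mask)
    expect_identical(ds$targets[scored, k], u[scored - k])
  }
  expect_true(all(abs(u) <= 1))
  expect_false(any(ds$decision_mask[1:55]))
  u_long <- make_memory_capacity(10000, seed = 9)$inputs[, 1]
  expect_lt(abs(mean(u_long)), 0.02)
  expect_error(make_memory_capacity(100, max_lag = 50, washout = 60),
               class = "connrc_parameter_error")
})

test_that("generators are pure functions of parameters and seed", {
  expect_identical(make_perceptual_dm(50, seed = 11),
                   make_perceptual_dm(50, seed = 11))
  expect_identical(make_context_dm(50, seed = 11),
                   make_context_dm(50, seed = 11))
  expect_identical(make_memory_capacity(300, seed = 11),
                   make_memory_capacity(300, seed = 11))
  expect_false(identical(make_perceptual_dm(50, seed = 11)$inputs,
                         make_perceptual_dm(50, seed = 12)$inputs))
})

test_that("trial splits partition trials and time correctly", {
  ds <- make_perceptual_dm(1000, seed = 1)
  sp <- split_trials(ds, 0.7, seed = 2)
  expect_length(sp$train_trials, 700)
  expect_length(sp$test_trials, 300)
  expect_setequal(c(sp$train_trials, sp$test_trials), 1:1000)
  expect_length(intersect(sp$train_trials, sp$test_trials), 0)
  expect_length(intersect(sp$train_rows, sp$test_rows), 0)
  # no trial straddles the split
  expect_true(all(tapply(ds$trial_id[sp$train_rows] %in% sp$train_trials,
                         ds$trial_id[sp$train_rows], all)))

  mc <- make_memory_capacity(1000, seed = 1)
  spt <- split_trials(mc, 0.7)
  expect_identical(spt$train_rows, 1:700)
  expect_identical(spt$test_rows, 701:1000)
  expect_identical(spt$by, "time")

  expect_identical(split_trials(ds, 0.7, seed = 5),
                   split_trials(ds, 0.7, seed = 5))
  expect_error(split_trials(ds, 0.0001), class = "connrc_parameter_error")
})

test_that("task datasets roundtrip through the plain-text export", {
  ds <- make_context_dm(20, seed = 4)
  dir <- tempfile()
  write_task_dataset(ds, dir)
  back <- read_task_dataset(dir)
  expect_equal(unname(back$inputs), unname(ds$inputs), tolerance = 1e-12)
  expect_equal(unname(back$targets), unname(ds$targets), tolerance = 1e-12)
  expect_identical(back$decision_mask, ds$decision_mask)
  expect_equal(unname(back$trial_bounds), unname(ds$trial_bounds))
  expect_equal(back$meta$task, "context_dm")
})
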