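small_mc_config <- function(cn, alphas = 0.9, n_realizations = 2, seed = 5,
                            ...) {
  experiment_config("memory_capacity", cn, input_nodes = 1:3,
                    readout_nodes = 4:nrow(cn$weights), alphas = alphas,
                    n_realizations = n_realizations,
                    task_params = list(T_total = 250, max_lag = 5,
                                       washout = 30),
                    seed = seed, ...)
}

test_that("a single-cell grid yields one row per metric and reruns identically", {
  cn <- fixture_random_conn(25, seed = 1)
  cfg <- small_mc_config(cn, n_realizations = 1)
  curve <- run_experiment(cfg)
  expect_identical(nrow(as.data.frame(curve)), 2L)  # MC + mean per-lag r2
  expect_setequal(curve$metric, c("memory_capacity", "mean_per_lag_r2"))
  expect_identical(as.data.frame(run_experiment(cfg)), as.data.frame(curve))
})

test_that("every (alpha, realization) pair appears exactly once per metric", {
  cn <- fixture_random_conn(25, seed = 1)
  curve <- run_experiment(small_mc_config(cn, alphas = c(0.5, 1.0),
                                          n_realizations = 3))
  df <- as.data.frame(curve)
  counts <- table(df$alpha, df$realization, df$metric)
  expect_true(all(counts == 1))
})

test_that("growing n_realizations leaves earlier realizations unchanged", {
  cn <- fixture_random_conn(25, seed = 1)
  c10 <- as.data.frame(run_experiment(small_mc_config(cn, n_realizations = 2)))
  c20 <- as.data.frame(run_experiment(small_mc_config(cn, n_realizations = 4)))
  expect_identical(c20[c20$realization <= 2, ], c10)
})

test_that("the noiseless perceptual task is solved near criticality", {
  cn <- fixture_random_conn(40, seed = 3)
  cfg <- experiment_config("perceptual_dm", cn, input_nodes = 1:4,
                           readout_nodes = 5:40, alphas = 0.9,
                           n_realizations = 2,
                           task_params = list(n_trials = 100, noise_sd = 0),
                           seed = 7)
  sm <- summary(run_experiment(cfg))
  expect_gte(sm$mean[sm$metric == "balanced_accuracy"], 0.95)
})

test_that("summary reports a per-alpha mean with a 95% CI from realizations", {
  cn <- fixture_random_conn(25, seed = 1)
  sm <- summary(run_experiment(small_mc_config(cn, alphas = c(0.5, 1.0),
                                               n_realizations = 3)))
  expect_identical(nrow(sm), 4L)
  expect_true(all(sm$n == 3))
  expect_true(all(sm$ci_lo <= sm$mean & sm$mean <= sm$ci_hi))
})

test_that("stage failures propagate with cell coordinates", {
  cn <- make_synthetic("delay_line", 6)  # nilpotent: cannot be alpha-scaled
  cfg <- small_mc_config(cn)
  err <- tryCatch(run_experiment(cfg), error = identity)
  expect_s3_class(err, "connrc_pipeline_error")
  expect_match(conditionMessage(err), "set_connectivity")
})

test_that("null comparison p-values honour the +1 correction and bounds", {
  cn <- fixture_random_conn(25, seed = 2)
  cfg <- small_mc_config(cn, n_realizations = 1, seed = 11)
  cmp <- null_comparison(cfg, n_nulls = 3, statistic = "value_at_alpha",
                         alpha_at = 0.9)
  expect_equal(cmp$metric, "memory_capacity")
  expect_length(cmp$null_values, 3)
  n_ge <- sum(cmp$null_values >= cmp$empirical_value)
  expect_equal(cmp$p_value, (1 + n_ge) / 4)
  expect_gte(cmp$p_value, 1 / 4)
  expect_lte(cmp$p_value, 1)
  # mirrored alternative
  cmp_less <- null_comparison(cfg, n_nulls = 3, statistic = "value_at_alpha",
                              alpha_at = 0.9, alternative = "less")
  n_le <- sum(cmp_less$null_values <= cmp_less$empirical_value)
  expect_equal(cmp_less$p_value, (1 + n_le) / 4)
})

test_that("peak-over-grid statistics use the per-alpha mean curve", {
  cn <- fixture_random_conn(25, seed = 2)
  curve <- run_experiment(small_mc_config(cn, alphas = c(0.6, 1.0),
                                          n_realizations = 2))
  sm <- summary(curve)
  mc <- sm[sm$metric == "memory_capacity", ]
  expect_equal(connrc:::curve_statistic(curve, "memory_capacity",
                                        "peak_over_grid"),
               max(mc$mean))
  expect_equal(connrc:::curve_statistic(curve, "memory_capacity",
                                        "value_at_alpha", alpha_at = 0.6),
               mc$mean[mc$alpha == 0.6])
  expect_error(connrc:::curve_statistic(curve, "memory_capacity",
                                        "value_at_alpha", alpha_at = 0.77),
               class = "connrc_configuration_error")
})

test_that("one-way ANOVA matches hand computations and degenerate cases", {
  # two groups {1,1,1} vs {2,2,2}: MS_within = 0 -> F = +Inf with note
  a <- connrc:::one_way_anova(c(1, 1, 1, 2, 2, 2), rep(c("a", "b"), each = 3))
  expect_identical(a$F, Inf)
  expect_identical(a$p, 0)
  expect_match(a$note, "MS_within")
  # hand ANOVA: groups {1,2,3} and {2,3,4}: ssb = 1.5, ssw = 4, F = 1.5
  b <- connrc:::one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  expect_equal(b$F, 1.5)
  expect_equal(b$p, stats::pf(1.5, 1, 4, lower.tail = FALSE))
  # agreement with stats::anova on a random problem
  set.seed(9)
  v <- stats::rnorm(30)
  g <- rep(letters[1:3], 10)
  ref <- stats::anova(stats::lm(v ~ g))
  d <- connrc:::one_way_anova(v, g)
  expect_equal(d$F, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(d$p, ref$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("ANOVA false-positive rate is calibrated under the null", {
  set.seed(123)
  rejections <- vapply(1:200, function(i) {
    v <- stats::rnorm(24)
    g <- rep(1:3, 8)
    connrc:::one_way_anova(v, g)$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.09)
})

test_that("stratified readouts score modules on shared dynamics", {
  cn <- make_synthetic("modular", 36, within = 0.5, between = 0.1,
                       n_blocks = 3, seed = 4)
  cfg <- experiment_config("memory_capacity", cn,
                           input_nodes = which(cn$partition == "block1")[1:3],
                           readout_nodes = 1,  # ignored when stratifying
                           alphas = 0.9, n_realizations = 3,
                           task_params = list(T_total = 250, max_lag = 5,
                                              washout = 30),
                           seed = 6)
  st <- stratified_readout(cfg, modules = c("block2", "block3"),
                           alpha_at = 0.9)
  expect_setequal(unique(st$table$module), c("block2", "block3"))
  expect_true(is.finite(st$anova$F) || !is.null(st$anova$note))
  expect_identical(st$anova$df_between, 1L)
  expect_identical(st$anova$df_within, 4L)
  # identical scores across modules (as identical node sets would produce)
  # give zero between-module variance
  v <- rep(c(0.5, 0.6, 0.7), 2)
  expect_lt(connrc:::one_way_anova(v, rep(c("m1", "m2"), each = 3))$F, 1e-12)
})

test_that("reports write deterministic CSVs and faithful JSON", {
  cn <- fixture_random_conn(25, seed = 2)
  curve <- run_experiment(small_mc_config(cn, alphas = c(0.6, 1.0)))
  d1 <- tempfile()
  d2 <- tempfile()
  report(curve, d1)
  report(curve, d2)
  expect_identical(readBin(file.path(d1, "cells.csv"), "raw", 1e6),
                   readBin(file.path(d2, "cells.csv"), "raw", 1e6))
  sm <- utils::read.csv(file.path(d1, "summary.csv"))
  expect_identical(nrow(sm), 4L)  # 2 alphas x 2 metrics
  cfg <- small_mc_config(cn, n_realizations = 1, seed = 11)
  cmp <- null_comparison(cfg, 2, "value_at_alpha", alpha_at = 0.9)
  d3 <- tempfile()
  report(cmp, d3)
  j <- jsonlite::read_json(file.path(d3, "comparison.json"),
                           simplifyVector = TRUE)
  expect_equal(j$p_value, cmp$p_value)
  expect_equal(j$n_nulls, 2)
})
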