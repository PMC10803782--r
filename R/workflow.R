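#' Configure a reservoir experiment
#'
#' Bundles everything one pipeline run needs: the task, the connectome, the
#' input/readout node sets, the spectral-radius grid, the activation
#' function(s) and the realization count. All randomness in
#' [run_experiment()] derives from \code{seed} through deterministic child
#' seeds, one stream per realization, so results are reproducible and the
#' first k realizations are unchanged when \code{n_realizations} grows.
#'
#' @param task \code{"perceptual_dm"}, \code{"context_dm"} or
#'   \code{"memory_capacity"}; ignored when \code{dataset} is supplied.
#' @param connectome a [connectome()].
#' @param input_nodes integer indices or partition labels of input nodes.
#' @param readout_nodes integer indices or partition labels of readout nodes.
#' @param alphas spectral-radius grid (default 0.05 to 2 in steps of 0.05,
#'   spanning stable through chaotic regimes).
#' @param activations one or more activation names.
#' @param n_realizations independent realizations of the task dataset.
#' @param frac_train training fraction of trials (default 0.7).
#' @param lambda ridge penalty for the readout.
#' @param task_params list of overrides passed to the task generator
#'   (e.g. \code{n_trials}, \code{noise_sd}, \code{T_total}, \code{max_lag}).
#' @param input_gain,leak_rate forwarded to [echo_state_reservoir()].
#' @param input_weights input-map option: \code{"uniform"} (default here)
#'   draws a seeded uniform-random weight per channel-node pair, so distinct
#'   channels reach the reservoir with distinct projections; \code{"ones"}
#'   broadcasts every channel with weight 1 onto every input node, which
#'   superimposes channels (with multichannel tasks whose channels sum to a
#'   constant, that cancels the discriminative signal — hence not the
#'   workflow default). The map is drawn once per experiment and shared by
#'   all cells.
#' @param dataset optional externally supplied \code{task_dataset}; each
#'   realization then re-splits it instead of regenerating.
#' @param seed master seed.
#' @return object of class \code{experiment_config}.
#' @export
experiment_config <- function(task = c("memory_capacity", "perceptual_dm",
                                       "context_dm"),
                              connectome, input_nodes, readout_nodes,
                              alphas = seq(0.05, 2, by = 0.05),
                              activations = "tanh", n_realizations = 50,
                              frac_train = 0.7, lambda = 1,
                              task_params = list(), input_gain = 1,
                              leak_rate = 1, input_weights = "uniform",
                              dataset = NULL, seed = 1) {
  task <- match.arg(task)
  stopifnot(inherits(connectome, "connectome"), n_realizations >= 1,
            length(alphas) >= 1, all(alphas > 0))
  resolve <- function(nodes) {
    if (is.character(nodes)) select_nodes(connectome, nodes) else as.integer(nodes)
  }
  cfg <- structure(list(task = task, connectome = connectome,
                        input_nodes = resolve(input_nodes),
                        readout_nodes = resolve(readout_nodes),
                        alphas = alphas, activations = activations,
                        n_realizations = n_realizations,
                        frac_train = frac_train, lambda = lambda,
                        task_params = task_params, input_gain = input_gain,
                        leak_rate = leak_rate, input_weights = input_weights,
                        dataset = dataset, seed = seed),
                   class = "experiment_config")
  cfg
}

generate_task <- function(cfg, seed) {
  if (!is.null(cfg$dataset)) return(cfg$dataset)
  p <- cfg$task_params
  switch(cfg$task,
         perceptual_dm = do.call(make_perceptual_dm, utils::modifyList(
           list(n_trials = 1000, seed = seed), p)),
         context_dm = do.call(make_context_dm, utils::modifyList(
           list(n_trials = 1000, seed = seed), p)),
         memory_capacity = do.call(make_memory_capacity, utils::modifyList(
           list(T_total = 1000, seed = seed), p)))
}

with_cell_context <- function(stage, alpha, realization, expr) {
  tryCatch(expr, error = function(e) {
    stop_connrc("stage '%s' failed at alpha = %g, realization %d: %s",
                stage, alpha, realization, conditionMessage(e),
                class = "connrc_pipeline_error")
  })
}

score_cell <- function(ds, trace, split, cfg) {
  mask <- ds$decision_mask
  tr_rows <- intersect(split$train_rows, which(mask))
  te_rows <- intersect(split$test_rows, which(mask))
  X_tr <- retrieve_states(trace$states, cfg$readout_nodes)[tr_rows, , drop = FALSE]
  X_te <- retrieve_states(trace$states, cfg$readout_nodes)[te_rows, , drop = FALSE]
  is_class <- if (is.null(cfg$dataset)) {
    cfg$task %in% c("perceptual_dm", "context_dm")
  } else {
    ncol(ds$targets) == 1 && all(ds$targets == round(ds$targets))
  }
  if (is_class) {
    y_tr <- ds$targets[tr_rows, 1]
    y_te <- ds$targets[te_rows, 1]
    m <- fit_readout(X_tr, y_tr, "classification", cfg$lambda)
    pred <- predict(m, X_te)
    trial_true <- tapply(y_te, ds$trial_id[te_rows], function(v) v[1])
    trial_pred <- suppressMessages(
      majority_vote(pred$predictions, ds$trial_id[te_rows]))
    list(balanced_accuracy = balanced_accuracy(trial_true, trial_pred)$value,
         f1 = f1_score(trial_true, trial_pred, "binary")$value,
         balanced_accuracy_timestep =
           balanced_accuracy(y_te, pred$predictions)$value,
         f1_timestep = f1_score(y_te, pred$predictions, "binary")$value)
  } else {
    Y_tr <- ds$targets[tr_rows, , drop = FALSE]
    Y_te <- ds$targets[te_rows, , drop = FALSE]
    m <- fit_readout(X_tr, Y_tr, "regression", cfg$lambda)
    pred <- predict(m, X_te)
    mc <- suppressWarnings(memory_capacity(Y_te, pred$predictions))
    list(memory_capacity = mc$value,
         mean_per_lag_r2 = mc$extras$mean_per_lag)
  }
}

#' Run the five-stage reservoir pipeline over an alpha grid
#'
#' For every realization: fetch (generate) the task dataset and the
#' train/test split; then for every activation and every alpha: rescale the
#' connectome to spectral radius alpha, simulate the echo-state dynamics on
#' the full input series, retrieve decision-masked readout-node states, fit
#' the ridge readout on training rows and score it on held-out rows.
#' Classification tasks report trial-level (majority-vote) and per-timestep
#' balanced accuracy and F1; the memory-capacity task reports MC and the
#' mean per-lag squared correlation.
#'
#' @param cfg an [experiment_config()].
#' @param verbose log one line per pipeline cell.
#' @return object of class \code{performance_curve}: a data.frame with
#'   columns \code{task}, \code{alpha}, \code{activation},
#'   \code{realization}, \code{metric}, \code{value}.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  scaled <- lapply(cfg$alphas, function(a)
    with_cell_context("set_connectivity", a, 0,
                      scale_to_alpha(cfg$connectome, a)$weights))
  rows <- list()
  for (r in seq_len(cfg$n_realizations)) {
    ds <- with_cell_context("fetch_task", NA_real_, r,
                            generate_task(cfg, child_seed(cfg$seed, 1, r)))
    split <- split_trials(ds, cfg$frac_train, seed = child_seed(cfg$seed, 2, r))
    for (act in cfg$activations) {
      for (ai in seq_along(cfg$alphas)) {
        a <- cfg$alphas[ai]
        t0 <- proc.time()[["elapsed"]]
        res <- echo_state_reservoir(scaled[[ai]], cfg$input_nodes,
                                    ncol(ds$inputs), activation = act,
                                    input_gain = cfg$input_gain,
                                    leak_rate = cfg$leak_rate,
                                    input_weights = cfg$input_weights,
                                    seed = child_seed(cfg$seed, 3))
        trace <- with_cell_context("simulate", a, r, simulate_esn(res, ds$inputs))
        scores <- with_cell_context("learning", a, r,
                                    score_cell(ds, trace, split, cfg))
        rows[[length(rows) + 1L]] <-
          data.frame(task = cfg$task, alpha = a, activation = act,
                     realization = r, metric = names(scores),
                     value = unlist(scores, use.names = FALSE))
        if (verbose)
          message(sprintf("cell task=%s act=%s alpha=%.2f realization=%d elapsed=%.2fs",
                          cfg$task, act, a, r,
                          proc.time()[["elapsed"]] - t0))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("performance_curve", "data.frame"),
            config_seed = cfg$seed)
}

#' @export
summary.performance_curve <- function(object, level = 0.95, ...) {
  df <- as.data.frame(object)
  key <- interaction(df$alpha, df$activation, df$metric, drop = TRUE)
  agg <- do.call(rbind, lapply(split(df, key), function(g) {
    n <- nrow(g)
    m <- mean(g$value)
    half <- if (n >= 2) stats::qt(1 - (1 - level) / 2, n - 1) *
      stats::sd(g$value) / sqrt(n) else NA_real_
    data.frame(task = g$task[1], alpha = g$alpha[1],
               activation = g$activation[1], metric = g$metric[1],
               n = n, mean = m, ci_lo = m - half, ci_hi = m + half)
  }))
  agg <- agg[order(agg$metric, agg$activation, agg$alpha), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' @export
print.performance_curve <- function(x, ...) {
  cat(sprintf("<performance_curve> %s: %d cell rows (%d alpha(s) x %s x %d realization(s))\n",
              x$task[1], nrow(x), length(unique(x$alpha)),
              paste(unique(x$activation), collapse = "/"),
              max(x$realization)))
  print(utils::head(summary(x), 10))
  invisible(x)
}

#' Plot mean performance against spectral radius
#'
#' One panel per metric; one mean line per activation with a 95 percent
#' confidence band when at least two realizations are present.
#'
#' @param x a \code{performance_curve}.
#' @param metrics subset of metrics to draw (default: the primary ones).
#' @param ... forwarded to \code{matplot}.
#' @export
plot.performance_curve <- function(x, metrics = NULL, ...) {
  sm <- summary(x)
  if (is.null(metrics))
    metrics <- intersect(c("balanced_accuracy", "f1", "memory_capacity"),
                         unique(sm$metric))
  old <- graphics::par(mfrow = c(length(metrics), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (met in metrics) {
    d <- sm[sm$metric == met, ]
    acts <- unique(d$activation)
    cols <- grDevices::hcl.colors(max(2, length(acts)), "Dark 2")
    graphics::plot(NULL, xlim = range(d$alpha),
                   ylim = range(c(d$ci_lo, d$ci_hi, d$mean), na.rm = TRUE),
                   xlab = expression(alpha), ylab = met, main = met, ...)
    for (i in seq_along(acts)) {
      g <- d[d$activation == acts[i], ]
      if (all(is.finite(g$ci_lo)))
        graphics::polygon(c(g$alpha, rev(g$alpha)), c(g$ci_lo, rev(g$ci_hi)),
                          col = grDevices::adjustcolor(cols[i], 0.25),
                          border = NA)
      graphics::lines(g$alpha, g$mean, col = cols[i], lwd = 2)
    }
    graphics::abline(v = 1, lty = 3)
    graphics::legend("topright", legend = acts, col = cols[seq_along(acts)],
                     lwd = 2, bty = "n")
  }
  invisible(x)
}

curve_statistic <- function(curve, metric,
                            statistic = c("value_at_alpha", "peak_over_grid"),
                            alpha_at = NULL) {
  statistic <- match.arg(statistic)
  sm <- summary(curve)
  sm <- sm[sm$metric == metric, ]
  if (nrow(sm) == 0)
    stop_connrc("metric '%s' not present in curve", metric,
                class = "connrc_configuration_error")
  if (statistic == "value_at_alpha") {
    if (is.null(alpha_at))
      stop_connrc("value_at_alpha needs alpha_at",
                  class = "connrc_configuration_error")
    i <- which(abs(sm$alpha - alpha_at) < 1e-9)
    if (length(i) != 1)
      stop_connrc("alpha_at = %g is not on the grid", alpha_at,
                  class = "connrc_configuration_error")
    sm$mean[i]
  } else {
    max(sm$mean)
  }
}

#' Compare an empirical connectome against rewired nulls
#'
#' Runs the full pipeline on the empirical network and on each of
#' \code{n_nulls} degree-preserving rewired surrogates, using matched
#' datasets (the same master seed drives every network, a paired design).
#' The test statistic is the realization-mean performance either at a fixed
#' alpha or at its peak over the grid. The nonparametric p-value uses the
#' +1 correction
#' \deqn{p = (1 + \#\{null \ge empirical\}) / (1 + n_{nulls})}
#' for \code{alternative = "greater"} (mirrored for \code{"less"}), so the
#' minimum attainable p is \code{1/(n_nulls + 1)} — with 500 nulls, 0.002.
#'
#' @param cfg an [experiment_config()].
#' @param n_nulls number of rewired surrogates (>= 1).
#' @param statistic \code{"value_at_alpha"} or \code{"peak_over_grid"}.
#' @param alpha_at grid alpha at which to take the statistic (required for
#'   \code{value_at_alpha}).
#' @param metric metric name; defaults to \code{memory_capacity} for the
#'   memory task, trial-level \code{balanced_accuracy} otherwise.
#' @param alternative \code{"greater"} (empirical better than nulls) or
#'   \code{"less"}.
#' @param n_swaps_per_edge forwarded to [rewire_null()].
#' @param null_source optional connectome to rewire instead of
#'   \code{cfg$connectome} (used e.g. for calibration studies where the
#'   "empirical" network is itself a draw from the null generator).
#' @param verbose log progress.
#' @return object of class \code{null_comparison}.
#' @export
null_comparison <- function(cfg, n_nulls,
                            statistic = c("value_at_alpha", "peak_over_grid"),
                            alpha_at = NULL, metric = NULL,
                            alternative = c("greater", "less"),
                            n_swaps_per_edge = 10, null_source = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"), n_nulls >= 1)
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  if (is.null(metric))
    metric <- if (cfg$task == "memory_capacity") "memory_capacity"
              else "balanced_accuracy"
  emp_curve <- run_experiment(cfg, verbose = verbose)
  emp <- curve_statistic(emp_curve, metric, statistic, alpha_at)
  src <- null_source %||% cfg$connectome
  ens <- rewire_null(src, n_nulls, n_swaps_per_edge,
                     seed = child_seed(cfg$seed, 99))
  null_values <- vapply(seq_len(n_nulls), function(k) {
    ck <- cfg
    ck$connectome$weights <- ens$replicates[[k]]
    if (verbose) message(sprintf("null replicate %d/%d", k, n_nulls))
    curve_statistic(run_experiment(ck), metric, statistic, alpha_at)
  }, numeric(1))
  p <- if (alternative == "greater") {
    (1 + sum(null_values >= emp)) / (1 + n_nulls)
  } else {
    (1 + sum(null_values <= emp)) / (1 + n_nulls)
  }
  structure(list(empirical_value = emp, null_values = null_values,
                 p_value = p, alpha_at = alpha_at, statistic = statistic,
                 metric = metric, alternative = alternative,
                 empirical_curve = emp_curve),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf("<null_comparison> %s (%s%s): empirical = %.4f, null mean = %.4f, p = %.4g (%s, %d nulls)\n",
              x$metric, x$statistic,
              if (!is.null(x$alpha_at)) sprintf(" at alpha = %g", x$alpha_at) else "",
              x$empirical_value, mean(x$null_values), x$p_value,
              x$alternative, length(x$null_values)))
  invisible(x)
}

#' @export
plot.null_comparison <- function(x, ...) {
  graphics::hist(x$null_values, breaks = "FD", col = "grey80",
                 main = sprintf("%s vs %d rewired nulls (p = %.4g)",
                                x$metric, length(x$null_values), x$p_value),
                 xlab = x$metric,
                 xlim = range(c(x$null_values, x$empirical_value)), ...)
  graphics::abline(v = x$empirical_value, col = "red3", lwd = 2)
  invisible(x)
}

# One-way ANOVA from the standard sums of squares, F = MS_between/MS_within.
# MS_within exactly zero is reported as F = +Inf with a note rather than NaN.
one_way_anova <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  n <- length(values)
  values <- as.numeric(values)
  grand <- mean(values)
  ssb <- sum(tapply(values, g, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(values, g, function(x) sum((x - mean(x))^2)))
  df_b <- as.integer(k - 1)
  df_w <- as.integer(n - k)
  if (ssw == 0 || df_w == 0) {
    list(F = Inf, p = 0, df_between = df_b, df_within = df_w,
         note = "MS_within is zero; F reported as +Inf")
  } else {
    F_ <- (ssb / df_b) / (ssw / df_w)
    list(F = F_, p = stats::pf(F_, df_b, df_w, lower.tail = FALSE),
         df_between = df_b, df_within = df_w, note = NULL)
  }
}

#' Stratify readout performance by functional system
#'
#' Simulates the reservoir once per realization and fits an independent
#' readout for every module (partition label), so modules are compared on
#' identical dynamics. Returns the per-module performance table and a
#' one-way ANOVA across modules of the realization-level scores at
#' \code{alpha_at} (F = MS_between / MS_within). When MS_within is exactly
#' zero the F statistic is reported as +Inf with a note.
#'
#' @param cfg an [experiment_config()]; its \code{readout_nodes} are ignored
#'   in favour of the module node sets.
#' @param modules character vector of partition labels to use as readout
#'   modules (default: all labels not containing input nodes). Modules with
#'   zero nodes are excluded with a warning.
#' @param alpha_at alpha at which the ANOVA is computed (default: the grid
#'   value closest to 1, criticality).
#' @param metric metric for the ANOVA (defaults as in [null_comparison()]).
#' @return object of class \code{stratified_readout}: \code{table}
#'   (module-level curve rows) and \code{anova} (F, p, dfs, note).
#' @export
stratified_readout <- function(cfg, modules = NULL, alpha_at = NULL,
                               metric = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  part <- cfg$connectome$partition
  if (is.null(part))
    stop_connrc("connectome has no partition to stratify by",
                class = "connrc_configuration_error")
  if (is.null(modules)) {
    input_labels <- unique(part[cfg$input_nodes])
    modules <- setdiff(unique(part), input_labels)
  }
  sizes <- vapply(modules, function(m) sum(part == m), integer(1))
  if (any(sizes == 0)) {
    warning(sprintf("excluding empty module(s): %s",
                    paste(modules[sizes == 0], collapse = ", ")))
    modules <- modules[sizes > 0]
  }
  if (length(modules) < 2)
    stop_connrc("need >= 2 non-empty readout modules",
                class = "connrc_configuration_error")
  if (is.null(metric))
    metric <- if (cfg$task == "memory_capacity") "memory_capacity"
              else "balanced_accuracy"
  if (is.null(alpha_at)) alpha_at <- cfg$alphas[which.min(abs(cfg$alphas - 1))]

  tabs <- lapply(modules, function(m) {
    ck <- cfg
    ck$readout_nodes <- which(part == m)
    tab <- as.data.frame(run_experiment(ck))
    tab$module <- m
    tab
  })
  table_ <- do.call(rbind, tabs)
  rownames(table_) <- NULL

  d <- table_[table_$metric == metric &
                abs(table_$alpha - alpha_at) < 1e-9, , drop = FALSE]
  aov_ <- one_way_anova(d$value, d$module)
  aov_$alpha_at <- alpha_at
  aov_$metric <- metric
  structure(list(table = table_, anova = aov_),
            class = "stratified_readout")
}

#' @export
print.stratified_readout <- function(x, ...) {
  a <- x$anova
  cat(sprintf("<stratified_readout> %d modules; one-way ANOVA on %s at alpha = %g: F(%d, %d) = %.2f, p = %.3g\n",
              length(unique(x$table$module)), a$metric, a$alpha_at,
              a$df_between, a$df_within, a$F, a$p))
  if (!is.null(a$note)) cat("note:", a$note, "\n")
  invisible(x)
}
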