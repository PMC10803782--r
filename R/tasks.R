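new_task_dataset <- function(inputs, targets, trial_bounds, decision_mask,
                             meta) {
  T_ <- nrow(inputs)
  stopifnot(nrow(targets) == T_, length(decision_mask) == T_)
  # trials must tile [1, T] without overlap (half-open [start, end) rows)
  stopifnot(trial_bounds[1, 1] == 1,
            trial_bounds[nrow(trial_bounds), 2] == T_ + 1,
            all(trial_bounds[-1, 1] == trial_bounds[-nrow(trial_bounds), 2]))
  trial_id <- rep(seq_len(nrow(trial_bounds)),
                  times = trial_bounds[, 2] - trial_bounds[, 1])
  structure(list(inputs = inputs, targets = targets,
                 trial_bounds = trial_bounds, trial_id = trial_id,
                 decision_mask = as.logical(decision_mask), meta = meta),
            class = "task_dataset")
}

#' @export
print.task_dataset <- function(x, ...) {
  cat(sprintf("<task_dataset> %s: T=%d, %d input channel(s), %d target(s), %d trial(s)\n",
              x$meta$task, nrow(x$inputs), ncol(x$inputs), ncol(x$targets),
              nrow(x$trial_bounds)))
  invisible(x)
}

#' @export
plot.task_dataset <- function(x, max_time = 200, ...) {
  Tn <- min(nrow(x$inputs), max_time)
  old <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::matplot(x$inputs[seq_len(Tn), , drop = FALSE], type = "l",
                    lty = 1, ylab = "inputs", xlab = "", ...)
  graphics::matplot(x$targets[seq_len(Tn), , drop = FALSE], type = "l",
                    lty = 1, ylab = "targets", xlab = "time step")
  invisible(x)
}

epoch_lengths_ok <- function(epoch_lengths) {
  length(epoch_lengths) == 3 && all(epoch_lengths >= 1)
}

# Lay out per-trial epochs; returns row indices for each epoch of each trial.
trial_layout <- function(n_trials, epoch_lengths) {
  len <- sum(epoch_lengths)
  starts <- (seq_len(n_trials) - 1) * len + 1
  list(len = len,
       bounds = cbind(start = starts, end = starts + len),
       fix = lapply(starts, function(s) s + seq_len(epoch_lengths[1]) - 1),
       stim = lapply(starts, function(s)
         s + epoch_lengths[1] + seq_len(epoch_lengths[2]) - 1),
       dec = lapply(starts, function(s)
         s + epoch_lengths[1] + epoch_lengths[2] + seq_len(epoch_lengths[3]) - 1))
}

#' Perceptual decision-making task dataset
#'
#' Two-alternative forced choice: on every trial two noisy stimulus streams
#' (channels x2, x3) are presented during the stimulus epoch with generating
#' means \code{baseline + delta} and \code{baseline - delta} (or swapped), and
#' the network must report which stream is higher on average. Channel x1 is a
#' constant bias (1 during the trial). The target label (1 if x2's generating
#' mean is higher, else 2) is emitted during the decision epoch and 0
#' (fixation, no decision required) elsewhere; performance is scored only on
#' decision-epoch timesteps (the \code{decision_mask}).
#'
#' @param n_trials number of trials (>= 1).
#' @param coherences signed mean offsets delta; one is drawn per trial. The
#'   sign decides which stream is higher, the magnitude how discriminable.
#' @param epoch_lengths timesteps for (fixation, stimulus, decision).
#' @param noise_sd additive Gaussian noise sd on the stimulus streams.
#' @param baseline generating baseline mean of the stimulus streams.
#' @param seed integer seed; generation is a pure function of parameters+seed.
#' @return a \code{task_dataset}.
#' @export
make_perceptual_dm <- function(n_trials,
                               coherences = c(-0.4, -0.2, -0.1, 0.1, 0.2, 0.4),
                               epoch_lengths = c(3, 10, 3),
                               noise_sd = 0.25, baseline = 0.5, seed = 1) {
  stopifnot(n_trials >= 1, epoch_lengths_ok(epoch_lengths))
  if (length(coherences) == 0)
    stop_connrc("coherence set must be non-empty", class = "connrc_parameter_error")
  lay <- trial_layout(n_trials, epoch_lengths)
  T_ <- n_trials * lay$len
  inputs <- matrix(0, T_, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  targets <- matrix(0L, T_, 1)
  mask <- logical(T_)
  with_seed(seed, {
    coh <- sample(rep(coherences, length.out = max(n_trials, length(coherences))),
                  n_trials)
    for (k in seq_len(n_trials)) {
      rows <- lay$bounds[k, 1]:(lay$bounds[k, 2] - 1)
      inputs[rows, 1] <- 1
      st <- lay$stim[[k]]
      m2 <- baseline + coh[k]
      m3 <- baseline - coh[k]
      inputs[st, 2] <- m2 + stats::rnorm(length(st), sd = noise_sd)
      inputs[st, 3] <- m3 + stats::rnorm(length(st), sd = noise_sd)
      y <- if (coh[k] > 0) 1L else 2L
      targets[lay$dec[[k]], 1] <- y
      mask[lay$dec[[k]]] <- TRUE
    }
  })
  new_task_dataset(inputs, targets, lay$bounds, mask,
                   meta = list(task = "perceptual_dm", n_trials = n_trials,
                               coherences = coherences,
                               epoch_lengths = epoch_lengths,
                               noise_sd = noise_sd, baseline = baseline,
                               labels = c(1L, 2L), seed = seed))
}

#' Context-dependent decision-making task dataset
#'
#' On every trial both stimulus modalities are presented, but a one-hot
#' contextual cue indicates which modality is relevant; the target follows the
#' cued modality's higher-mean stream only. Seven input channels: x1 constant
#' bias; x2, x3 one-hot context cue (active throughout the trial); x4, x5
#' noisy stimulus pair of modality 1; x6, x7 of modality 2.
#'
#' @inheritParams make_perceptual_dm
#' @return a \code{task_dataset}.
#' @export
make_context_dm <- function(n_trials,
                            coherences = c(-0.4, -0.2, -0.1, 0.1, 0.2, 0.4),
                            epoch_lengths = c(3, 10, 3),
                            noise_sd = 0.25, baseline = 0.5, seed = 1) {
  stopifnot(n_trials >= 1, epoch_lengths_ok(epoch_lengths))
  if (length(coherences) == 0)
    stop_connrc("coherence set must be non-empty", class = "connrc_parameter_error")
  lay <- trial_layout(n_trials, epoch_lengths)
  T_ <- n_trials * lay$len
  inputs <- matrix(0, T_, 7,
                   dimnames = list(NULL, paste0("x", 1:7)))
  targets <- matrix(0L, T_, 1)
  mask <- logical(T_)
  with_seed(seed, {
    context <- sample(c(1L, 2L), n_trials, replace = TRUE)
    coh1 <- sample(coherences, n_trials, replace = TRUE)
    coh2 <- sample(coherences, n_trials, replace = TRUE)
    for (k in seq_len(n_trials)) {
      rows <- lay$bounds[k, 1]:(lay$bounds[k, 2] - 1)
      inputs[rows, 1] <- 1
      inputs[rows, 1 + context[k]] <- 1       # one-hot cue on x2/x3
      st <- lay$stim[[k]]
      ns <- length(st)
      inputs[st, 4] <- baseline + coh1[k] + stats::rnorm(ns, sd = noise_sd)
      inputs[st, 5] <- baseline - coh1[k] + stats::rnorm(ns, sd = noise_sd)
      inputs[st, 6] <- baseline + coh2[k] + stats::rnorm(ns, sd = noise_sd)
      inputs[st, 7] <- baseline - coh2[k] + stats::rnorm(ns, sd = noise_sd)
      coh_cued <- if (context[k] == 1L) coh1[k] else coh2[k]
      y <- if (coh_cued > 0) 1L else 2L
      targets[lay$dec[[k]], 1] <- y
      mask[lay$dec[[k]]] <- TRUE
    }
  })
  new_task_dataset(inputs, targets, lay$bounds, mask,
                   meta = list(task = "context_dm", n_trials = n_trials,
                               coherences = coherences,
                               epoch_lengths = epoch_lengths,
                               noise_sd = noise_sd, baseline = baseline,
                               labels = c(1L, 2L), seed = seed))
}

#' Memory-capacity task dataset
#'
#' A single input stream u(t) drawn i.i.d. uniform on [-1, 1] and max_lag
#' target channels, the k-th being the input delayed by k steps:
#' y_k(t) = u(t - k). The first \code{washout + max_lag} timesteps are masked
#' out of scoring (reservoir transient + undefined lags). One trial spans the
#' whole series; train/test splitting for this task is contiguous in time.
#'
#' @param T_total total number of timesteps (> max_lag + washout).
#' @param max_lag largest delay to reconstruct (number of target channels).
#' @param washout initial timesteps excluded from scoring.
#' @param seed integer seed.
#' @return a \code{task_dataset}.
#' @export
make_memory_capacity <- function(T_total, max_lag = 20, washout = 100,
                                 seed = 1) {
  if (T_total <= max_lag + washout)
    stop_connrc("T_total (%d) must exceed max_lag + washout (%d)",
                T_total, max_lag + washout, class = "connrc_parameter_error")
  u <- with_seed(seed, stats::runif(T_total, -1, 1))
  targets <- sapply(seq_len(max_lag), function(k)
    c(rep(0, k), u[seq_len(T_total - k)]))
  colnames(targets) <- paste0("lag", seq_len(max_lag))
  mask <- c(rep(FALSE, washout + max_lag),
            rep(TRUE, T_total - washout - max_lag))
  new_task_dataset(matrix(u, ncol = 1, dimnames = list(NULL, "u")),
                   targets,
                   cbind(start = 1, end = T_total + 1), mask,
                   meta = list(task = "memory_capacity", T_total = T_total,
                               max_lag = max_lag, washout = washout,
                               seed = seed))
}

#' Split a task dataset into training and test partitions
#'
#' Multi-trial datasets are split at the trial level (no trial straddles the
#' split); single-trial regression datasets (memory capacity) are split
#' contiguously on the time axis, training first.
#'
#' @param d a \code{task_dataset}.
#' @param frac_train fraction of trials (or time) for training, in (0, 1).
#' @param seed seed for the trial permutation.
#' @return class \code{trial_split}: list with \code{train_trials},
#'   \code{test_trials}, \code{train_rows}, \code{test_rows}, \code{by}.
#' @export
split_trials <- function(d, frac_train = 0.7, seed = 1) {
  stopifnot(inherits(d, "task_dataset"), frac_train > 0, frac_train < 1)
  n_trials <- nrow(d$trial_bounds)
  if (n_trials >= 2) {
    n_train <- round(frac_train * n_trials)
    if (n_train < 1 || n_train >= n_trials)
      stop_connrc("frac_train %.2f yields an empty partition for %d trials",
                  frac_train, n_trials, class = "connrc_parameter_error")
    perm <- with_seed(seed, sample.int(n_trials))
    train_trials <- sort(perm[seq_len(n_train)])
    test_trials <- sort(perm[-seq_len(n_train)])
    structure(list(train_trials = train_trials, test_trials = test_trials,
                   train_rows = which(d$trial_id %in% train_trials),
                   test_rows = which(d$trial_id %in% test_trials),
                   by = "trial"),
              class = "trial_split")
  } else {
    T_ <- nrow(d$inputs)
    cut <- floor(frac_train * T_)
    if (cut < 1 || cut >= T_)
      stop_connrc("frac_train %.2f yields an empty time partition", frac_train,
                  class = "connrc_parameter_error")
    structure(list(train_trials = 1L, test_trials = 1L,
                   train_rows = seq_len(cut), test_rows = seq(cut + 1, T_),
                   by = "time"),
              class = "trial_split")
  }
}

#' Write a task dataset to plain-text files
#'
#' Two CSV tables (inputs, targets) plus a JSON sidecar holding trial bounds,
#' the decision mask and generation metadata. [read_task_dataset()] restores
#' the object; externally produced datasets in the same layout are accepted
#' too, so any supervised input/target pair can drive the pipeline.
#'
#' @param d a \code{task_dataset}.
#' @param dir output directory.
#' @return invisibly, \code{dir}.
#' @export
write_task_dataset <- function(d, dir) {
  stopifnot(inherits(d, "task_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(d$inputs, file.path(dir, "inputs.csv"), row.names = FALSE)
  utils::write.csv(d$targets, file.path(dir, "targets.csv"), row.names = FALSE)
  side <- list(trial_bounds = unname(d$trial_bounds),
               decision_mask = d$decision_mask, meta = d$meta)
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a task dataset written by [write_task_dataset()]
#'
#' @param dir directory holding inputs.csv, targets.csv, sidecar.json.
#' @return a \code{task_dataset}.
#' @export
read_task_dataset <- function(dir) {
  inputs <- as.matrix(utils::read.csv(file.path(dir, "inputs.csv")))
  targets <- as.matrix(utils::read.csv(file.path(dir, "targets.csv")))
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                              simplifyVector = TRUE)
  tb <- side$trial_bounds
  if (!is.matrix(tb)) tb <- matrix(unlist(tb), ncol = 2, byrow = TRUE)
  dimnames(tb) <- list(NULL, c("start", "end"))
  new_task_dataset(inputs, targets, tb, side$decision_mask,
                   meta = as.list(side$meta))
}
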