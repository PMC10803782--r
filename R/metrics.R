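new_score <- function(name, value, n_samples, extras = NULL) {
  structure(list(name = name, value = value, n_samples = n_samples,
                 extras = extras),
            class = "score")
}

#' @export
print.score <- function(x, ...) {
  cat(sprintf("<score> %s = %.4f (n = %d)\n", x$name, x$value, x$n_samples))
  invisible(x)
}

#' Balanced accuracy
#'
#' Mean over true classes of per-class recall; insensitive to class
#' imbalance. True classes with zero samples are excluded with a warning.
#'
#' @param true_labels,pred_labels equal-length label vectors.
#' @return a \code{score} with per-class recalls in \code{extras}.
#' @export
balanced_accuracy <- function(true_labels, pred_labels) {
  stopifnot(length(true_labels) == length(pred_labels))
  classes <- sort(unique(true_labels))
  recall <- vapply(classes, function(cl) {
    idx <- true_labels == cl
    mean(pred_labels[idx] == cl)
  }, numeric(1))
  names(recall) <- classes
  new_score("balanced_accuracy", mean(recall), length(true_labels),
            extras = list(recall = recall))
}

#' F1 score
#'
#' Harmonic mean of precision and recall. \code{average = "binary"} scores
#' the higher of the two labels as the positive class; \code{"macro"}
#' averages per-class F1 over all true classes. A class with zero predicted
#' and zero true positives gets F1 = 0 with a warning.
#'
#' @param true_labels,pred_labels equal-length label vectors.
#' @param average \code{"binary"} or \code{"macro"}.
#' @return a \code{score} with per-class F1 in \code{extras}.
#' @export
f1_score <- function(true_labels, pred_labels,
                     average = c("binary", "macro")) {
  stopifnot(length(true_labels) == length(pred_labels))
  average <- match.arg(average)
  classes <- sort(unique(true_labels))
  per_class <- vapply(classes, function(cl) {
    tp <- sum(true_labels == cl & pred_labels == cl)
    fp <- sum(true_labels != cl & pred_labels == cl)
    fn <- sum(true_labels == cl & pred_labels != cl)
    if (tp == 0 && (fp + fn) == 0) {
      warning(sprintf("class %s has no true or predicted positives; F1 = 0", cl))
      return(0)
    }
    if (tp == 0) return(0)
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  names(per_class) <- classes
  value <- if (average == "binary") {
    if (length(classes) != 2)
      stop_connrc("binary F1 needs exactly 2 true classes, got %d",
                  length(classes), class = "connrc_parameter_error")
    per_class[[2]]
  } else {
    mean(per_class)
  }
  new_score(paste0("f1_", average), value, length(true_labels),
            extras = list(per_class = per_class))
}

#' Memory capacity
#'
#' \deqn{MC = \sum_{k=1}^{K} corr(y_k, \hat y_k)^2,}
#' the sum over lags of the squared Pearson correlation between the k-step
#' delayed input and its readout reconstruction. Bounded by the number of
#' lags K; the per-lag curve is kept in \code{extras}. A zero-variance
#' prediction column contributes 0 with a warning.
#'
#' @param true_targets T x K matrix of lagged input copies.
#' @param preds T x K matrix of readout predictions.
#' @return a \code{score}; \code{extras$per_lag} holds the squared
#'   correlations, \code{extras$mean_per_lag} their mean.
#' @export
memory_capacity <- function(true_targets, preds) {
  Y <- as.matrix(true_targets)
  P <- as.matrix(preds)
  stopifnot(all(dim(Y) == dim(P)))
  per_lag <- vapply(seq_len(ncol(Y)), function(k) {
    if (stats::sd(Y[, k]) == 0)
      stop_connrc("target column %d has zero variance", k,
                  class = "connrc_degenerate_error")
    if (stats::sd(P[, k]) == 0) {
      warning(sprintf("prediction column %d has zero variance; lag contributes 0", k))
      return(0)
    }
    stats::cor(Y[, k], P[, k])^2
  }, numeric(1))
  names(per_lag) <- colnames(Y) %||% paste0("lag", seq_len(ncol(Y)))
  new_score("memory_capacity", sum(per_lag), nrow(Y),
            extras = list(per_lag = per_lag, mean_per_lag = mean(per_lag)))
}

#' Coefficient of determination
#'
#' @param true,pred aligned numeric vectors; \code{true} must have nonzero
#'   variance.
#' @return a \code{score}.
#' @export
r_squared <- function(true, pred) {
  stopifnot(length(true) == length(pred))
  ss_tot <- sum((true - mean(true))^2)
  if (ss_tot == 0)
    stop_connrc("true values have zero variance; R^2 undefined",
                class = "connrc_degenerate_error")
  new_score("r_squared", 1 - sum((true - pred)^2) / ss_tot, length(true))
}

#' Pearson correlation
#'
#' @param true,pred aligned numeric vectors with nonzero variance.
#' @return a \code{score}.
#' @export
pearson_r <- function(true, pred) {
  stopifnot(length(true) == length(pred))
  if (stats::sd(true) == 0 || stats::sd(pred) == 0)
    stop_connrc("zero variance input; correlation undefined",
                class = "connrc_degenerate_error")
  new_score("pearson_r", stats::cor(true, pred), length(true))
}
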