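ridge_solve <- function(Xs, Yc, lambda) {
  # ridge slopes for a standardized design: augmented least squares
  # rbind(Xs, sqrt(lambda) I) — QR path, distinct from the normal equations
  m <- ncol(Xs)
  if (lambda > 0) {
    Xa <- rbind(Xs, diag(sqrt(lambda), m))
    Ya <- rbind(Yc, matrix(0, m, ncol(Yc)))
    qr.coef(qr(Xa), Ya)
  } else {
    qx <- qr(Xs)
    if (qx$rank < m) {
      warning("rank-deficient design with lambda = 0; using pseudoinverse")
      sv <- svd(Xs)
      pos <- sv$d > max(sv$d) * 1e-10
      sv$v[, pos, drop = FALSE] %*%
        (crossprod(sv$u[, pos, drop = FALSE], Yc) / sv$d[pos])
    } else {
      qr.coef(qx, Yc)
    }
  }
}

#' Fit a regularized linear readout
#'
#' The only trained component of the reservoir computer: a ridge model
#' mapping retrieved reservoir states to task targets. Features are z-scored
#' using training-set statistics; the intercept is unpenalized. Regression
#' fits each target column independently; classification fits a ridge
#' regression onto +/-1 indicator targets (one column per class when more
#' than two), with an argmax (sign, for binary) decision rule — the "ridge
#' classifier" construction. Fitting is deterministic.
#'
#' @param states numeric matrix of reservoir states (samples x features),
#'   typically from [retrieve_states()] restricted to decision-mask rows.
#' @param targets numeric matrix (regression) or label vector
#'   (classification) aligned with \code{states} rows.
#' @param mode \code{"regression"} or \code{"classification"}.
#' @param lambda ridge penalty (>= 0); default 1.
#' @return object of class \code{readout_model} with elements
#'   \code{coefficients} ((m+1) x K, intercept first, standardized scale),
#'   \code{center}, \code{scale}, \code{mode}, \code{lambda},
#'   \code{label_set}.
#' @examples
#' X <- matrix(rnorm(200), 50, 4)
#' y <- X %*% c(1, -1, 0, 2) + rnorm(50, sd = 0.1)
#' m <- fit_readout(X, y, "regression", lambda = 0.1)
#' coef(m)
#' @export
fit_readout <- function(states, targets,
                        mode = c("regression", "classification"),
                        lambda = 1) {
  mode <- match.arg(mode)
  X <- as.matrix(states)
  stopifnot(lambda >= 0)
  if (NROW(targets) != nrow(X))
    stop_connrc("states (%d rows) and targets (%d) do not align",
                nrow(X), NROW(targets), class = "connrc_shape_error")
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")

  if (mode == "classification") {
    labels <- as.vector(targets)
    label_set <- sort(unique(labels))
    if (length(label_set) < 2)
      stop_connrc("classification needs >= 2 distinct labels, got %d",
                  length(label_set), class = "connrc_degenerate_error")
    if (length(label_set) == 2) {
      Y <- matrix(ifelse(labels == label_set[2], 1, -1), ncol = 1)
    } else {
      Y <- sapply(label_set, function(l) ifelse(labels == l, 1, -1))
    }
  } else {
    Y <- as.matrix(targets)
    label_set <- NULL
  }
  Yc <- sweep(Y, 2, colMeans(Y))
  beta <- ridge_solve(Xs, Yc, lambda)
  coefficients <- rbind(intercept = colMeans(Y), beta)
  rownames(coefficients) <- c("(intercept)",
                              colnames(X) %||% paste0("f", seq_len(ncol(X))))
  structure(list(coefficients = coefficients, center = center, scale = scl,
                 mode = mode, lambda = lambda, label_set = label_set),
            class = "readout_model")
}

#' @export
print.readout_model <- function(x, ...) {
  cat(sprintf("<readout_model> %s, %d feature(s), %d output(s), lambda = %g\n",
              x$mode, nrow(x$coefficients) - 1, ncol(x$coefficients),
              x$lambda))
  if (!is.null(x$label_set))
    cat("labels:", paste(x$label_set, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.readout_model <- function(object, ...) object$coefficients

#' Predict from a fitted readout
#'
#' @param object a [fit_readout()] model.
#' @param states feature matrix with the same columns as at fit time.
#' @param ... unused.
#' @return list with \code{predictions} (per-sample labels for
#'   classification, real values for regression) and \code{decision_values}
#'   (raw linear scores; for binary classification positive values map to the
#'   higher label, ties to the lower).
#' @export
predict.readout_model <- function(object, states, ...) {
  X <- as.matrix(states)
  if (ncol(X) != nrow(object$coefficients) - 1)
    stop_connrc("expected %d feature(s), got %d",
                nrow(object$coefficients) - 1, ncol(X),
                class = "connrc_shape_error")
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  scores <- cbind(1, Xs) %*% object$coefficients
  if (object$mode == "regression")
    return(list(predictions = scores, decision_values = scores))
  ls <- object$label_set
  if (length(ls) == 2) {
    dv <- scores[, 1]
    pred <- ifelse(dv > 0, ls[2], ls[1])
  } else {
    dv <- scores
    pred <- ls[max.col(scores, ties.method = "first")]
  }
  list(predictions = pred, decision_values = dv)
}

#' Aggregate per-timestep predictions to trial labels
#'
#' Majority vote over each trial's scored timesteps; ties resolve to the
#' lower label (reported via a message).
#'
#' @param pred_labels per-timestep predicted labels.
#' @param trial_ids trial id per timestep (same length).
#' @return named vector of one label per trial, names = trial ids.
#' @export
majority_vote <- function(pred_labels, trial_ids) {
  stopifnot(length(pred_labels) == length(trial_ids))
  n_ties <- 0L
  out <- tapply(pred_labels, trial_ids, function(v) {
    tab <- table(v)
    top <- tab[tab == max(tab)]
    if (length(top) > 1) n_ties <<- n_ties + 1L
    # names are sorted, so the first max is the lower label
    as.numeric(names(top)[1])
  })
  if (n_ties > 0)
    message(sprintf("%d trial(s) had tied votes; resolved to the lower label",
                    n_ties))
  stats::setNames(as.numeric(out), names(out))
}

#' Serialize a readout model to JSON
#' @param m a \code{readout_model}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_readout <- function(m, path) {
  stopifnot(inherits(m, "readout_model"))
  obj <- list(coefficients = unclass(m$coefficients),
              coef_rownames = rownames(m$coefficients),
              center = m$center, scale = m$scale, mode = m$mode,
              lambda = m$lambda, label_set = m$label_set)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a readout model written by [write_readout()]
#' @param path JSON path.
#' @return a \code{readout_model}.
#' @export
read_readout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- as.matrix(obj$coefficients)
  rownames(cf) <- obj$coef_rownames
  label_set <- obj$label_set
  if (is.numeric(label_set)) label_set <- as.numeric(label_set)
  structure(list(coefficients = cf, center = obj$center, scale = obj$scale,
                 mode = obj$mode, lambda = obj$lambda,
                 label_set = label_set),
            class = "readout_model")
}
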