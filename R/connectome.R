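#' Construct a connectome object
#'
#' A connectome is a square, non-negative (by default) weight matrix over a
#' set of named nodes, optionally annotated with a partition of nodes into
#' functional systems (e.g. intrinsic networks). The matrix orientation is
#' \code{weights[i, j]} = connection FROM node i TO node j; all simulators in
#' this package right-multiply state row-vectors by the weight matrix.
#'
#' Self-loops (diagonal entries) are stripped at construction with a message
#' reporting how many were removed; empirical connectomes conventionally lack
#' them. Symmetry is auto-detected when \code{directed} is \code{NULL}: the
#' network is undirected when the matrix equals its transpose within 1e-12.
#'
#' @param weights numeric square matrix, n >= 2, all entries finite.
#' @param node_ids character vector of node names (defaults to
#'   \code{"n1"..."nN"} or matrix dimnames when present).
#' @param directed logical or \code{NULL} (auto-detect from symmetry).
#' @param partition optional named character vector mapping node id to system
#'   label, or a data.frame with columns \code{node_id}, \code{label}.
#' @param allow_negative allow negative weights (default \code{FALSE}; signed
#'   connectomes are rejected otherwise).
#' @return an object of class \code{connectome} with elements \code{weights},
#'   \code{node_ids}, \code{directed}, \code{partition}, \code{n_self_loops}.
#' @examples
#' W <- matrix(c(0, 1, 1, 0), 2, 2)
#' connectome(W)
#' @export
connectome <- function(weights, node_ids = NULL, directed = NULL,
                       partition = NULL, allow_negative = FALSE) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop_connrc("weights must be a numeric matrix", class = "connrc_format_error")
  if (nrow(weights) != ncol(weights))
    stop_connrc("connectivity matrix must be square, got %d x %d",
                nrow(weights), ncol(weights), class = "connrc_format_error")
  n <- nrow(weights)
  if (n < 2)
    stop_connrc("connectome needs at least 2 nodes", class = "connrc_format_error")
  bad <- which(!is.finite(weights), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_connrc("non-finite weights at [%s]%s",
                paste(apply(utils::head(bad, 5), 1, paste, collapse = ","),
                      collapse = "], ["),
                if (nrow(bad) > 5) sprintf(" and %d more", nrow(bad) - 5) else "",
                class = "connrc_validation_error")
  if (!allow_negative && any(weights < 0))
    stop_connrc(paste0("negative weights present (min %g); pass ",
                       "allow_negative = TRUE to accept a signed connectome"),
                min(weights), class = "connrc_validation_error")

  n_self <- sum(diag(weights) != 0)
  if (n_self > 0) {
    message(sprintf("stripped %d self-loop(s) from the diagonal", n_self))
    diag(weights) <- 0
  }

  if (is.null(node_ids)) {
    node_ids <- rownames(weights) %||% paste0("n", seq_len(n))
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n || anyDuplicated(node_ids))
    stop_connrc("node_ids must be %d unique names", n,
                class = "connrc_format_error")
  dimnames(weights) <- list(node_ids, node_ids)

  symmetric <- max(abs(weights - t(weights))) <= 1e-12
  if (is.null(directed)) directed <- !symmetric
  if (!directed && !symmetric)
    stop_connrc("directed = FALSE but matrix is asymmetric (max |W - t(W)| = %g)",
                max(abs(weights - t(weights))), class = "connrc_validation_error")

  if (!is.null(partition)) partition <- as_partition(partition, node_ids)

  structure(list(weights = weights, node_ids = node_ids,
                 directed = isTRUE(directed), partition = partition,
                 n_self_loops = n_self),
            class = "connectome")
}

as_partition <- function(partition, node_ids) {
  if (is.data.frame(partition)) {
    if (!all(c("node_id", "label") %in% names(partition)))
      stop_connrc("partition data.frame needs columns node_id, label",
                  class = "connrc_format_error")
    partition <- stats::setNames(as.character(partition$label),
                                 as.character(partition$node_id))
  }
  if (is.null(names(partition)))
    stop_connrc("partition must be named by node id", class = "connrc_format_error")
  missing_ids <- setdiff(node_ids, names(partition))
  if (length(missing_ids) > 0)
    stop_connrc("partition missing %d node(s), e.g. %s", length(missing_ids),
                missing_ids[1], class = "connrc_validation_error")
  partition[node_ids]
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  ne <- sum(x$weights != 0) / if (x$directed) 1 else 2
  cat(sprintf("<connectome> %d nodes, %d %s edges, density %.3f\n",
              n, ne, if (x$directed) "directed" else "undirected",
              ne / (n * (n - 1) / if (x$directed) 1 else 2)))
  if (!is.null(x$partition))
    cat("systems:", paste(names(table(x$partition)), table(x$partition),
                          sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.connectome <- function(x, ...) {
  graphics::image(t(x$weights)[, rev(seq_len(nrow(x$weights)))],
                  axes = FALSE, main = "connectome weights",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Load a connectome from a dense CSV/TSV matrix file
#'
#' Accepts a dense comma- or tab-separated square matrix, with or without a
#' header row and leading column of node ids (auto-detected). A partition file
#' (columns \code{node_id,label}) may be supplied alongside.
#'
#' @param path path to the matrix file.
#' @param directed logical hint; \code{NULL} auto-detects from symmetry.
#' @param partition_path optional path to a node partition CSV.
#' @param allow_negative see [connectome()].
#' @return a [connectome()] object.
#' @export
load_connectome <- function(path, directed = NULL, partition_path = NULL,
                            allow_negative = FALSE) {
  if (!file.exists(path))
    stop_connrc("file not found: %s", path, class = "connrc_io_error")
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  first <- readLines(path, n = 1)
  cells <- strsplit(first, sep, fixed = TRUE)[[1]]
  # header row iff trailing cells fail numeric parsing (NaN/Inf/NA count as
  # numeric here; they are rejected by validation later, not read as names)
  numeric_like <- !is.na(suppressWarnings(as.numeric(cells[-1]))) |
    toupper(trimws(cells[-1])) %in% c("NAN", "NA", "INF", "-INF")
  has_header <- !all(numeric_like)
  raw <- utils::read.table(path, sep = sep, header = has_header,
                           stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  node_ids <- NULL
  first_col_char <- !is.numeric(raw[[1]])
  if (first_col_char) {
    node_ids <- as.character(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
  } else if (has_header) {
    node_ids <- colnames(raw)
  }
  W <- as.matrix(raw)
  if (!is.numeric(W))
    stop_connrc("non-numeric entries in matrix file %s", path,
                class = "connrc_format_error")
  dimnames(W) <- NULL
  partition <- NULL
  if (!is.null(partition_path)) {
    ptab <- utils::read.csv(partition_path, stringsAsFactors = FALSE)
    partition <- ptab
  }
  connectome(W, node_ids = node_ids, directed = directed,
             partition = partition, allow_negative = allow_negative)
}

#' Binarize connectome weights
#'
#' Weights become 1 where the source weight is nonzero, 0 elsewhere.
#' Idempotent.
#'
#' @param c a [connectome()].
#' @return a binarized [connectome()].
#' @export
binarize <- function(c) {
  stopifnot(inherits(c, "connectome"))
  c$weights[] <- as.numeric(c$weights != 0)
  c
}

#' Normalize connectome weights
#'
#' @param c a [connectome()].
#' @param mode \code{"max"} divides by the maximum absolute weight;
#'   \code{"sum"} by the total weight; \code{"spectral"} by the spectral
#'   radius (largest absolute eigenvalue).
#' @return a rescaled [connectome()].
#' @export
normalize_weights <- function(c, mode = c("max", "sum", "spectral")) {
  stopifnot(inherits(c, "connectome"))
  mode <- match.arg(mode)
  if (all(c$weights == 0))
    stop_connrc("cannot normalize an all-zero matrix",
                class = "connrc_degenerate_error")
  denom <- switch(mode,
                  max = max(abs(c$weights)),
                  sum = sum(c$weights),
                  spectral = spectral_radius(c$weights))
  if (denom == 0)
    stop_connrc("normalization denominator is zero in mode '%s'", mode,
                class = "connrc_degenerate_error")
  c$weights <- c$weights / denom
  c
}

#' Spectral radius of a matrix
#'
#' Largest absolute eigenvalue (not singular value); this is the quantity
#' the spectral-radius parameter alpha is defined against.
#'
#' @param W numeric square matrix.
#' @return non-negative scalar.
#' @export
spectral_radius <- function(W) {
  if (inherits(W, "connectome")) W <- W$weights
  max(Mod(eigen(W, only.values = TRUE)$values))
}

#' Rescale a connectome to a target spectral radius
#'
#' Computes \code{W' = alpha * W / rho(W)} so that the returned matrix has
#' spectral radius \code{alpha} (within 1e-9 relative tolerance). The global
#' dynamical regime of a reservoir built on \code{W'} is stable for
#' \code{alpha < 1}, approximately critical at \code{alpha = 1}, and chaotic
#' for \code{alpha > 1}. Re-scaling a previously scaled matrix targets the new
#' alpha directly (it does not compound).
#'
#' @param c a [connectome()] (or bare matrix).
#' @param alpha positive target spectral radius.
#' @return object of the same type as \code{c}, rescaled.
#' @export
scale_to_alpha <- function(c, alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0)
  W <- if (inherits(c, "connectome")) c$weights else c
  rho <- spectral_radius(W)
  if (rho <= .Machine$double.eps)
    stop_connrc(paste0("spectral radius is zero (nilpotent or empty matrix); ",
                       "spectral scaling is undefined for this network"),
                class = "connrc_degenerate_error")
  W <- W * (alpha / rho)
  if (inherits(c, "connectome")) { c$weights <- W; c } else W
}

#' Select node indices by partition label
#'
#' @param c a [connectome()] with a partition.
#' @param labels character vector of system labels.
#' @param n_sample optionally subsample this many of the matching nodes.
#' @param seed seed for the subsample.
#' @return integer node indices in node order.
#' @export
select_nodes <- function(c, labels, n_sample = NULL, seed = 1) {
  stopifnot(inherits(c, "connectome"))
  if (is.null(c$partition))
    stop_connrc("connectome has no partition", class = "connrc_lookup_error")
  avail <- unique(c$partition)
  unknown <- setdiff(labels, avail)
  if (length(unknown) > 0)
    stop_connrc("unknown label(s) %s; available: %s",
                paste(unknown, collapse = ", "), paste(avail, collapse = ", "),
                class = "connrc_lookup_error")
  idx <- which(c$partition %in% labels)
  if (!is.null(n_sample)) {
    if (n_sample > length(idx))
      stop_connrc("requested %d nodes but only %d match", n_sample, length(idx),
                  class = "connrc_parameter_error")
    idx <- sort(with_seed(seed, sample(idx, n_sample)))
  }
  idx
}
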