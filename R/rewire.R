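#' Degree-preserving rewired null ensemble
#'
#' Builds a family of surrogate networks by Maslov-Sneppen double-edge swaps:
#' each replicate preserves the source network's density (edge count) and its
#' binary degree sequence exactly (in- and out-degree for directed networks),
#' while randomizing higher-order topology. Weighted networks are rewired on
#' their binary topology and the original weight multiset is then permuted
#' onto the rewired edges, so the weight distribution is preserved exactly.
#' Undirected networks are rewired as undirected (swaps mirrored across the
#' diagonal).
#'
#' Swap trials that would create a self-loop or a multi-edge are rejected. A
#' replicate on which no swap succeeded (graphs too small or dense to admit
#' any valid swap) is returned as a weight-permuted copy of the source and
#' flagged, with a warning.
#'
#' @param c a [connectome()] with at least 2 edges.
#' @param n_reps number of null replicates.
#' @param n_swaps_per_edge swap trials per edge (default 10).
#' @param seed master seed; replicate k uses a deterministic child seed, so
#'   ensembles are reproducible and replicates independent.
#' @return object of class \code{null_ensemble}: list with \code{replicates}
#'   (list of weight matrices), \code{generator_name}, \code{seed},
#'   \code{n_swaps_per_edge}, \code{flagged} (logical per replicate).
#' @export
rewire_null <- function(c, n_reps, n_swaps_per_edge = 10, seed = 1) {
  stopifnot(inherits(c, "connectome"), n_reps >= 1)
  W <- c$weights
  mode <- if (c$directed) "directed" else "undirected"
  A <- (W != 0) * 1
  n_edges <- if (c$directed) sum(A) else sum(A) / 2
  if (n_edges < 2)
    stop_connrc("need at least 2 edges to rewire, got %d", n_edges,
                class = "connrc_parameter_error")
  A <- unname(A)
  g0 <- igraph::graph_from_adjacency_matrix(A, mode = mode)
  wvals <- if (c$directed) W[W != 0] else W[upper.tri(W) & W != 0]
  niter <- ceiling(n_swaps_per_edge * n_edges)

  reps <- vector("list", n_reps)
  flagged <- logical(n_reps)
  for (k in seq_len(n_reps)) {
    with_seed(child_seed(seed, 7, k), {
      g <- igraph::rewire(g0, igraph::keeping_degseq(niter = niter,
                                                     loops = FALSE))
      Ak <- unname(as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)))
      if (identical(Ak, A)) flagged[k] <- TRUE
      Wk <- matrix(0, nrow(W), ncol(W))
      if (c$directed) {
        idx <- which(Ak != 0)
        Wk[idx] <- sample(wvals, length(wvals))
      } else {
        idx <- which(Ak != 0 & upper.tri(Ak))
        Wk[idx] <- sample(wvals, length(wvals))
        Wk <- Wk + t(Wk)
      }
      dimnames(Wk) <- dimnames(W)
      reps[[k]] <- Wk
    })
  }
  if (any(flagged))
    warning(sprintf("%d replicate(s) admitted no valid swap; returned as weight-permuted copies",
                    sum(flagged)))
  structure(list(replicates = reps, generator_name = "maslov_sneppen",
                 seed = seed, n_swaps_per_edge = n_swaps_per_edge,
                 directed = c$directed, flagged = flagged),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d %s replicates (%s, seed %d, %d swaps/edge)\n",
              length(x$replicates),
              if (x$directed) "directed" else "undirected",
              x$generator_name, x$seed, x$n_swaps_per_edge))
  if (any(x$flagged)) cat(sum(x$flagged), "replicate(s) flagged un-swappable\n")
  invisible(x)
}

#' Write a null ensemble to a directory
#'
#' One numbered CSV matrix per replicate plus a JSON manifest recording the
#' generator, seed and swap count.
#'
#' @param ens a [rewire_null()] ensemble.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_null_ensemble <- function(ens, dir) {
  stopifnot(inherits(ens, "null_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(ens$replicates)) {
    utils::write.table(ens$replicates[[k]],
                       file.path(dir, sprintf("null_%04d.csv", k)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(generator = ens$generator_name, seed = ens$seed,
                   n_swaps_per_edge = ens$n_swaps_per_edge,
                   n_replicates = length(ens$replicates),
                   directed = ens$directed,
                   flagged = which(ens$flagged))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
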