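#' Generate synthetic connectomes
#'
#' Fixture networks standing in for empirical connectomes: seeded, so every
#' generated network is reproducible.
#'
#' \describe{
#'   \item{random}{directed Erdos-Renyi graph at the given \code{density},
#'     weights i.i.d. uniform on (0, 1).}
#'   \item{modular}{block-structured network with \code{n_blocks} equal
#'     blocks, within-block density \code{within} and between-block density
#'     \code{between}; block membership recorded in the partition as
#'     \code{"block1"}, \code{"block2"}, ...}
#'   \item{delay_line}{directed chain 1 -> 2 -> ... -> n with unit weights
#'     (n - 1 edges); a pure n-1 step delay memory.}
#'   \item{ring}{directed cycle with unit weights; spectral radius exactly 1.}
#' }
#'
#' @param kind one of \code{"random"}, \code{"modular"}, \code{"delay_line"},
#'   \code{"ring"}.
#' @param n number of nodes (>= 2).
#' @param density edge density in (0, 1] for \code{random}.
#' @param within,between block densities for \code{modular}.
#' @param n_blocks number of modules for \code{modular}.
#' @param weighted draw uniform weights (default) or unit weights.
#' @param seed integer seed.
#' @return a [connectome()].
#' @examples
#' make_synthetic("ring", 5)
#' @export
make_synthetic <- function(kind = c("random", "modular", "delay_line", "ring"),
                           n, density = 0.2, within = 0.5, between = 0.05,
                           n_blocks = 2, weighted = TRUE, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n >= 2)
  if (kind %in% c("random", "modular")) {
    dens <- if (kind == "random") density else c(within, between)
    if (any(dens <= 0) || any(dens > 1))
      stop_connrc("density must be in (0, 1], got %s",
                  paste(dens, collapse = ", "),
                  class = "connrc_parameter_error")
  }
  W <- matrix(0, n, n)
  partition <- NULL
  with_seed(seed, {
    if (kind == "random") {
      W[] <- (matrix(stats::runif(n * n), n, n) < density) * 1
    } else if (kind == "modular") {
      block <- rep(seq_len(n_blocks), length.out = n)
      block <- sort(block)
      same <- outer(block, block, "==")
      p <- ifelse(same, within, between)
      W[] <- (matrix(stats::runif(n * n), n, n) < p) * 1
      partition <- stats::setNames(paste0("block", block), paste0("n", seq_len(n)))
    } else if (kind == "delay_line") {
      W[cbind(seq_len(n - 1), seq(2, n))] <- 1
    } else if (kind == "ring") {
      W[cbind(seq_len(n), c(seq(2, n), 1))] <- 1
    }
    diag(W) <- 0
    if (weighted && kind %in% c("random", "modular")) {
      nz <- which(W != 0)
      W[nz] <- stats::runif(length(nz))
    }
  })
  connectome(W, directed = TRUE, partition = partition)
}
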