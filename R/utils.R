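#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global \code{.Random.seed}, so library functions can
#' be reproducible without clobbering the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic seed fan-out. Mixes a master seed with stream/index coordinates
# through iterated Lehmer steps modulo the Mersenne prime 2^31 - 1, so child
# seeds are stable when other coordinates (e.g. n_realizations) change and all
# stay in 32-bit integer range. Multiplications stay below 2^53 (exact doubles).
child_seed <- function(master, ...) {
  m <- 2147483647
  x <- (as.numeric(master) %% (m - 1)) + 1
  for (k in as.numeric(c(...))) {
    x <- (x * 48271) %% m
    x <- ((x + k %% m) %% m)
    if (x == 0) x <- 1
    x <- (x * 48271) %% m
    if (x == 0) x <- 1
  }
  as.integer(x)
}

stop_connrc <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "connrc_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
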