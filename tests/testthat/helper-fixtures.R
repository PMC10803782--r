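# Shared fixtures, built in code at test time.

fixture_random_conn <- function(n = 40, density = 0.2, seed = 3) {
  make_synthetic("random", n, density = density, seed = seed)
}

# Power iteration: independent oracle for the dominant eigenvalue magnitude.
power_iteration_rho <- function(W, iters = 2000, seed = 1) {
  set.seed(seed)
  v <- stats::rnorm(nrow(W))
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(iters)) {
    w <- W %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- w / nw
  }
  sqrt(sum((W %*% v)^2))
}

# Brute-force ridge via the normal equations (independent of the QR path).
ridge_normal_equations <- function(Xs, yc, lambda) {
  solve(crossprod(Xs) + diag(lambda, ncol(Xs)), crossprod(Xs, yc))
}

write_matrix_csv <- function(W, path, node_ids = NULL) {
  if (!is.null(node_ids)) {
    utils::write.table(rbind(node_ids, W), path, sep = ",",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(W, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  path
}
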