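activation_fun <- function(name, slope = 0.1) {
  switch(name,
         linear = identity,
         tanh = base::tanh,
         sigmoid = function(z) 1 / (1 + exp(-z)),
         relu = function(z) pmax(z, 0),
         leaky_relu = function(z) ifelse(z > 0, z, slope * z),
         stop_connrc("unknown activation '%s'", name,
                     class = "connrc_parameter_error"))
}

activation_bounded <- function(name) name %in% c("tanh", "sigmoid")

#' Construct an echo-state reservoir
#'
#' Fixes the recurrent weight matrix (typically a connectome rescaled with
#' [scale_to_alpha()]), the routing of input channels onto input nodes, and
#' the local activation function. The reservoir itself is never trained; only
#' the linear readout is (see [fit_readout()]).
#'
#' The input map defaults to broadcasting: every channel projects with weight
#' 1 onto every input node. A seeded uniform-random input map is available via
#' \code{input_weights = "uniform"}.
#'
#' @param c a [connectome()] or bare weight matrix (orientation
#'   \code{W[i, j]} = i to j).
#' @param input_nodes integer indices of nodes receiving external input.
#' @param n_channels number of input channels C.
#' @param activation \code{"linear"}, \code{"tanh"}, \code{"sigmoid"},
#'   \code{"relu"} or \code{"leaky_relu"}.
#' @param leaky_slope slope of leaky ReLU, in (0, 1).
#' @param input_gain scalar gain on the external input.
#' @param input_weights \code{"ones"} (broadcast, default) or
#'   \code{"uniform"} (i.i.d. U(0,1), seeded).
#' @param leak_rate state leak in (0, 1]; 1 (default) disables leaky
#'   integration and gives the plain update
#'   \code{x(t) = f(x(t-1) W + u(t) M g)}.
#' @param initial_state length-n starting state (default zeros).
#' @param seed seed for the random input map.
#' @return object of class \code{echo_state_reservoir}.
#' @export
echo_state_reservoir <- function(c, input_nodes, n_channels,
                                 activation = c("tanh", "linear", "sigmoid",
                                                "relu", "leaky_relu"),
                                 leaky_slope = 0.1, input_gain = 1,
                                 input_weights = c("ones", "uniform"),
                                 leak_rate = 1, initial_state = NULL,
                                 seed = 1) {
  activation <- match.arg(activation)
  input_weights <- match.arg(input_weights)
  W <- if (inherits(c, "connectome")) c$weights else c
  n <- nrow(W)
  stopifnot(all(input_nodes >= 1), all(input_nodes <= n), n_channels >= 1,
            leak_rate > 0, leak_rate <= 1)
  if (activation == "leaky_relu" && (leaky_slope <= 0 || leaky_slope >= 1))
    stop_connrc("leaky_relu slope must be in (0,1)", class = "connrc_parameter_error")
  M <- matrix(0, n_channels, n)
  vals <- if (input_weights == "ones") 1 else
    with_seed(seed, stats::runif(n_channels * length(input_nodes)))
  M[, input_nodes] <- vals
  if (is.null(initial_state)) initial_state <- numeric(n)
  stopifnot(length(initial_state) == n)
  structure(list(weights = W, input_map = M, input_nodes = input_nodes,
                 activation = activation, leaky_slope = leaky_slope,
                 input_gain = input_gain, leak_rate = leak_rate,
                 initial_state = initial_state),
            class = "echo_state_reservoir")
}

#' @export
print.echo_state_reservoir <- function(x, ...) {
  cat(sprintf("<echo_state_reservoir> %d units, %s activation, rho = %.4g, %d input node(s)\n",
              nrow(x$weights), x$activation, spectral_radius(x$weights),
              length(x$input_nodes)))
  invisible(x)
}

#' Simulate echo-state reservoir dynamics
#'
#' Discrete-time update
#' \deqn{x(t) = f(x(t-1) W + u(t) M g), \quad t = 1..T,}
#' with \code{x(0) = initial_state}. The trace records the state \emph{after}
#' consuming input row t, i.e. row t of the trace pairs with input row t; the
#' initial state is not recorded. With a leak rate a < 1 the update becomes
#' \code{x(t) = (1 - a) x(t-1) + a f(...)}.
#'
#' With unbounded activations (linear, ReLU, leaky ReLU) the simulation
#' aborts with a divergence error if any state magnitude exceeds 1e6,
#' reporting the first offending timestep.
#'
#' @param r an [echo_state_reservoir()].
#' @param inputs T x C matrix of input channel values.
#' @return object of class \code{reservoir_trace}: list with \code{states}
#'   (T x n), \code{activation}, \code{alpha} (spectral radius of the wiring).
#' @export
simulate_esn <- function(r, inputs) {
  stopifnot(inherits(r, "echo_state_reservoir"))
  if (is.vector(inputs)) inputs <- matrix(inputs, ncol = 1)
  if (!all(is.finite(inputs)))
    stop_connrc("non-finite inputs", class = "connrc_validation_error")
  if (ncol(inputs) != nrow(r$input_map))
    stop_connrc("inputs have %d channel(s) but input_map expects %d",
                ncol(inputs), nrow(r$input_map), class = "connrc_shape_error")
  f <- activation_fun(r$activation, r$leaky_slope)
  T_ <- nrow(inputs)
  n <- nrow(r$weights)
  U <- inputs %*% r$input_map * r$input_gain       # T x n external drive
  S <- matrix(0, T_, n)
  x <- matrix(r$initial_state, 1, n)
  W <- r$weights
  a <- r$leak_rate
  check <- !activation_bounded(r$activation)
  for (t in seq_len(T_)) {
    z <- x %*% W + U[t, ]
    x <- if (a == 1) f(z) else (1 - a) * x + a * f(z)
    if (check && max(abs(x)) > 1e6)
      stop_connrc("reservoir state diverged at t = %d (|x| > 1e6) with %s activation",
                  t, r$activation, class = "connrc_divergence_error")
    S[t, ] <- x
  }
  structure(list(states = S, activation = r$activation,
                 alpha = spectral_radius(W)),
            class = "reservoir_trace")
}

#' @export
print.reservoir_trace <- function(x, ...) {
  cat(sprintf("<reservoir_trace> %d timesteps x %d units (%s, rho = %.4g)\n",
              nrow(x$states), ncol(x$states), x$activation, x$alpha))
  invisible(x)
}

#' Retrieve masked readout-node states from a trace
#'
#' @param tr a \code{reservoir_trace} (or bare T x n state matrix).
#' @param readout_nodes integer node indices to read from.
#' @param mask logical length-T vector of rows to keep (default all).
#' @return matrix of masked rows x selected columns, time order preserved.
#' @export
retrieve_states <- function(tr, readout_nodes, mask = NULL) {
  S <- if (inherits(tr, "reservoir_trace")) tr$states else tr
  if (length(readout_nodes) == 0)
    stop_connrc("readout node set is empty", class = "connrc_parameter_error")
  stopifnot(all(readout_nodes >= 1), all(readout_nodes <= ncol(S)))
  if (is.null(mask)) mask <- rep(TRUE, nrow(S))
  stopifnot(length(mask) == nrow(S))
  S[mask, readout_nodes, drop = FALSE]
}
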