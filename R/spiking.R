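#' Leaky-integrate-and-fire parameters
#'
#' Defaults are standard cortical LIF figures; membrane and synaptic time
#' constants may be scalars or per-neuron vectors (heterogeneous synapses).
#'
#' @param dt integration step (ms); must satisfy \code{dt < tau_rise} so the
#'   synaptic kernel is resolved.
#' @param tau_m membrane time constant (ms), scalar or per-neuron.
#' @param v_rest,v_thresh,v_reset resting, threshold and reset potential (mV);
#'   \code{v_thresh > v_reset} required.
#' @param t_ref absolute refractory period (ms).
#' @param tau_rise,tau_decay synaptic kernel rise/decay constants (ms),
#'   scalar or per-neuron; \code{tau_decay > tau_rise > 0}.
#' @param input_current_gain scalar gain converting input-channel amplitude
#'   to injected current (mV equivalent drive).
#' @param inhibitory_mask optional logical per-neuron vector; outgoing
#'   weights of flagged neurons have their sign flipped.
#' @return object of class \code{lif_params}.
#' @export
lif_params <- function(dt = 0.1, tau_m = 20, v_rest = -65, v_thresh = -50,
                       v_reset = -65, t_ref = 2, tau_rise = 0.5,
                       tau_decay = 5, input_current_gain = 1,
                       inhibitory_mask = NULL) {
  if (any(tau_rise <= 0) || any(tau_decay <= tau_rise))
    stop_connrc("need tau_decay > tau_rise > 0", class = "connrc_parameter_error")
  if (v_thresh <= v_reset)
    stop_connrc("need v_thresh > v_reset", class = "connrc_parameter_error")
  if (dt <= 0 || dt >= min(tau_rise))
    stop_connrc("dt must satisfy 0 < dt < tau_rise (kernel under-resolved)",
                class = "connrc_parameter_error")
  structure(list(dt = dt, tau_m = tau_m, v_rest = v_rest, v_thresh = v_thresh,
                 v_reset = v_reset, t_ref = t_ref, tau_rise = tau_rise,
                 tau_decay = tau_decay, input_current_gain = input_current_gain,
                 inhibitory_mask = inhibitory_mask),
            class = "lif_params")
}

#' Simulate a leaky-integrate-and-fire reservoir
#'
#' Euler integration of
#' \deqn{\tau_m dV_i/dt = -(V_i - v_{rest}) + I_{syn,i} + I_{ext,i},}
#' with threshold-reset firing and an absolute refractory period during which
#' the membrane is clamped at \code{v_reset}. Each presynaptic spike of
#' neuron j drives postsynaptic neuron i through a double-exponential kernel
#' \deqn{w_{ji} (e^{-t/\tau_{decay}} - e^{-t/\tau_{rise}}) /
#'       (\tau_{decay} - \tau_{rise}),}
#' implemented with two auxiliary exponential state variables per neuron.
#' Spikes take effect on the following integration step (one-step synaptic
#' latency). External input channels are injected as currents into the input
#' nodes; each task timestep is held for \code{steps_per_input} integration
#' steps, so a task step lasts \code{steps_per_input * dt} ms.
#'
#' @param c a [connectome()]; weights are synaptic efficacies (apply
#'   [normalize_weights()] beforehand as needed).
#' @param p a [lif_params()].
#' @param inputs T x C matrix at task-step resolution.
#' @param input_nodes node indices receiving the input current.
#' @param steps_per_input integration steps per task timestep (default 100).
#' @param record_voltage keep the full voltage trace.
#' @param seed reserved for stochastic extensions; the integration itself is
#'   deterministic.
#' @return object of class \code{spike_trace}: \code{spikes} (Td x n logical),
#'   \code{filtered} (Td x n synaptic trace), optional \code{voltages},
#'   \code{dt}, \code{steps_per_input}, \code{task_rows} (row indices of
#'   task-step boundaries).
#' @export
simulate_lif <- function(c, p, inputs, input_nodes, steps_per_input = 100,
                         record_voltage = FALSE, seed = 1) {
  stopifnot(inherits(c, "connectome"), inherits(p, "lif_params"))
  if (is.vector(inputs)) inputs <- matrix(inputs, ncol = 1)
  if (!all(is.finite(inputs)))
    stop_connrc("non-finite inputs", class = "connrc_validation_error")
  W <- c$weights
  n <- nrow(W)
  if (!is.null(p$inhibitory_mask)) {
    stopifnot(length(p$inhibitory_mask) == n)
    W[p$inhibitory_mask, ] <- -W[p$inhibitory_mask, ]
  }
  M <- matrix(0, ncol(inputs), n)
  M[, input_nodes] <- 1
  Iext_task <- inputs %*% M * p$input_current_gain   # T x n
  T_task <- nrow(inputs)
  Td <- T_task * steps_per_input

  dt <- p$dt
  tau_m <- rep(p$tau_m, length.out = n)
  tau_r <- rep(p$tau_rise, length.out = n)
  tau_d <- rep(p$tau_decay, length.out = n)
  er <- exp(-dt / tau_r)
  ed <- exp(-dt / tau_d)
  knorm <- tau_d - tau_r
  ref_steps <- max(0L, as.integer(round(p$t_ref / dt)))

  V <- rep(p$v_rest, n)
  sd_ <- numeric(n)
  sr_ <- numeric(n)
  ref <- integer(n)
  spk_prev <- numeric(n)

  spikes <- matrix(FALSE, Td, n)
  filtered <- matrix(0, Td, n)
  volts <- if (record_voltage) matrix(0, Td, n) else NULL

  for (t in seq_len(Td)) {
    task_t <- ((t - 1L) %/% steps_per_input) + 1L
    # synaptic filter: spikes from the previous step arrive now
    inc <- if (any(spk_prev != 0)) as.numeric(spk_prev %*% W) else 0
    sd_ <- sd_ * ed + inc
    sr_ <- sr_ * er + inc
    Isyn <- (sd_ - sr_) / knorm
    filtered[t, ] <- Isyn

    active <- ref == 0L
    dV <- (-(V - p$v_rest) + Isyn + Iext_task[task_t, ]) * (dt / tau_m)
    V[active] <- V[active] + dV[active]
    ref[!active] <- ref[!active] - 1L

    fired <- active & (V >= p$v_thresh)
    if (any(fired)) {
      V[fired] <- p$v_reset
      ref[fired] <- ref_steps
      spikes[t, fired] <- TRUE
    }
    spk_prev <- as.numeric(fired)
    if (record_voltage) volts[t, ] <- V
  }
  structure(list(spikes = spikes, filtered = filtered, voltages = volts,
                 dt = dt, steps_per_input = steps_per_input,
                 task_rows = seq_len(T_task) * steps_per_input),
            class = "spike_trace")
}

#' @export
print.spike_trace <- function(x, ...) {
  cat(sprintf("<spike_trace> %d steps x %d neurons, %d spikes (dt = %g ms)\n",
              nrow(x$spikes), ncol(x$spikes), sum(x$spikes), x$dt))
  invisible(x)
}

#' Continuous reservoir states from a spike trace
#'
#' @param tr a \code{spike_trace}.
#' @param mode \code{"filtered"} returns the double-exponential synaptic
#'   trace; \code{"rate"} a causal moving-average spike count divided by the
#'   window length.
#' @param window window length in integration steps for rate mode (>= 1).
#' @param at_task_steps sample rows at task-step boundaries only (matches the
#'   task-step resolution of the inputs).
#' @return numeric matrix of states.
#' @export
states_from_spikes <- function(tr, mode = c("filtered", "rate"), window = 10,
                               at_task_steps = FALSE) {
  stopifnot(inherits(tr, "spike_trace"))
  mode <- match.arg(mode)
  S <- if (mode == "filtered") {
    tr$filtered
  } else {
    if (window < 1) stop_connrc("window must be >= 1",
                                class = "connrc_parameter_error")
    sp <- tr$spikes * 1
    cs <- apply(sp, 2, cumsum)
    cs_lag <- rbind(matrix(0, min(window, nrow(sp)), ncol(sp)),
                    cs[seq_len(max(0, nrow(sp) - window)), , drop = FALSE])
    (cs - cs_lag) / window
  }
  if (at_task_steps) S[tr$task_rows, , drop = FALSE] else S
}

#' Export a spike raster as a two-column table
#'
#' @param tr a \code{spike_trace}.
#' @param path optional CSV output path.
#' @return data.frame with columns \code{time_ms}, \code{neuron_id}.
#' @export
spike_raster <- function(tr, path = NULL) {
  idx <- which(tr$spikes, arr.ind = TRUE)
  out <- data.frame(time_ms = idx[, 1] * tr$dt, neuron_id = idx[, 2])
  out <- out[order(out$time_ms, out$neuron_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
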