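# Two-node connectome with negligible coupling: isolates single-neuron
# dynamics while satisfying the n >= 2 container invariant.
isolated_pair <- function() connectome(rbind(c(0, 1e-12), c(0, 0)),
                                       directed = TRUE)

test_that("a resting neuron with zero input never spikes", {
  tr <- simulate_lif(isolated_pair(), lif_params(), matrix(0, 20, 1),
                     input_nodes = 1)
  expect_equal(sum(tr$spikes), 0)
  expect_true(all(tr$filtered == 0))
})

test_that("constant-current ISI matches the closed-form LIF solution", {
  p <- lif_params()
  Iamp <- 20
  tr <- simulate_lif(isolated_pair(), p, matrix(Iamp, 40, 1), input_nodes = 1)
  st <- which(tr$spikes[, 1])
  expect_gt(length(st), 5)
  isi <- diff(st) * p$dt
  isi_theory <- p$tau_m *
    log((Iamp - (p$v_reset - p$v_rest)) / (Iamp - (p$v_thresh - p$v_rest))) +
    p$t_ref
  expect_lt(abs(mean(isi) - isi_theory), 2 * p$dt)
})

test_that("halving dt changes the ISI estimate by less than 5 percent", {
  est <- vapply(c(0.1, 0.05), function(dt) {
    p <- lif_params(dt = dt)
    tr <- simulate_lif(isolated_pair(), p, matrix(20, 40, 1), input_nodes = 1)
    mean(diff(which(tr$spikes[, 1]))) * dt
  }, numeric(1))
  expect_lt(abs(est[1] - est[2]) / est[2], 0.05)
})

test_that("the synaptic kernel peaks at the double-exponential peak time", {
  p <- lif_params()
  cn <- connectome(rbind(c(0, 1), c(0, 0)), directed = TRUE)
  # a brief strong pulse (3 integration steps) elicits exactly one spike
  u <- matrix(0, 400, 1)
  u[1:3, 1] <- 1500
  tr <- simulate_lif(cn, p, u, input_nodes = 1, steps_per_input = 1)
  st <- which(tr$spikes[, 1])
  expect_length(st, 1)
  arrival <- st + 1  # one-step synaptic latency
  pk <- which.max(tr$filtered[, 2])
  t_peak <- (pk - arrival) * p$dt
  t_theory <- p$tau_rise * p$tau_decay / (p$tau_decay - p$tau_rise) *
    log(p$tau_decay / p$tau_rise)
  expect_lt(abs(t_peak - t_theory), 2 * p$dt)
})

test_that("no neuron spikes inside its refractory window", {
  cn <- fixture_random_conn(15, density = 0.3, seed = 6)
  cnn <- normalize_weights(cn, "max")
  cnn$weights <- cnn$weights * 30   # strong synapses to provoke activity
  p <- lif_params()
  set.seed(8)
  u <- matrix(stats::runif(40, 15, 25), 40, 1)
  tr <- simulate_lif(cnn, p, u, input_nodes = 1:5)
  expect_gt(sum(tr$spikes), 20)
  ref_steps <- round(p$t_ref / p$dt)
  for (i in seq_len(ncol(tr$spikes))) {
    st <- which(tr$spikes[, i])
    if (length(st) > 1) expect_true(all(diff(st) > ref_steps))
  }
})

test_that("heterogeneous synaptic time constants decay at their own rates", {
  # node 1 spikes once into nodes 2 and 3, which filter with different
  # decay constants
  W <- matrix(0, 3, 3)
  W[1, 2] <- 1
  W[1, 3] <- 1
  cn3 <- connectome(W, directed = TRUE)
  p3 <- lif_params(tau_decay = c(5, 5, 12), tau_rise = 0.5)
  u <- matrix(0, 1200, 1)
  u[1:3, 1] <- 1500
  tr <- simulate_lif(cn3, p3, u, input_nodes = 1, steps_per_input = 1)
  expect_length(which(tr$spikes[, 1]), 1)
  for (j in c(2, 3)) {
    f <- tr$filtered[, j]
    pk <- which.max(f)
    tail_idx <- seq(pk + 200, pk + 800)   # late tail: pure tau_decay
    fit <- stats::lm(log(f[tail_idx]) ~ tail_idx)
    slope_per_ms <- unname(stats::coef(fit)[2]) / p3$dt
    expect_equal(slope_per_ms, -1 / p3$tau_decay[j], tolerance = 0.05)
  }
})

test_that("inhibitory neurons hyperpolarize their targets", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- 1
  cn <- connectome(W, directed = TRUE)
  p <- lif_params(inhibitory_mask = c(TRUE, FALSE, FALSE))
  u <- matrix(0, 400, 1)
  u[1:3, 1] <- 1500
  tr <- simulate_lif(cn, p, u, input_nodes = 1, steps_per_input = 1)
  expect_lt(min(tr$filtered[, 2]), 0)
  expect_lte(max(tr$filtered[, 2]), 0)
})

test_that("state extraction modes behave as declared", {
  cn <- fixture_random_conn(10, seed = 2)
  p <- lif_params()
  tr <- simulate_lif(normalize_weights(cn, "max"), p,
                     matrix(20, 10, 1), input_nodes = 1:3,
                     steps_per_input = 20)
  expect_identical(states_from_spikes(tr, "rate", window = 1),
                   tr$spikes * 1)
  r5 <- states_from_spikes(tr, "rate", window = 5)
  expect_true(all(r5 >= 0 & r5 <= 1))
  expect_identical(states_from_spikes(tr, "filtered"), tr$filtered)
  at_task <- states_from_spikes(tr, "filtered", at_task_steps = TRUE)
  expect_identical(nrow(at_task), 10L)
  # non-negative weights give a non-negative synaptic trace
  expect_true(all(tr$filtered >= 0))
})

test_that("parameter validation rejects under-resolved and inverted constants", {
  expect_error(lif_params(dt = 0.6, tau_rise = 0.5),
               class = "connrc_parameter_error")
  expect_error(lif_params(tau_rise = 5, tau_decay = 2),
               class = "connrc_parameter_error")
  expect_error(lif_params(v_thresh = -70, v_reset = -65),
               class = "connrc_parameter_error")
})

test_that("spike rasters export as ordered time/neuron pairs", {
  cn <- fixture_random_conn(8, seed = 3)
  tr <- simulate_lif(normalize_weights(cn, "max"), lif_params(),
                     matrix(20, 10, 1), input_nodes = 1:2,
                     steps_per_input = 20)
  ras <- spike_raster(tr)
  expect_equal(nrow(ras), sum(tr$spikes))
  expect_true(!is.unsorted(ras$time_ms))
  path <- tempfile(fileext = ".csv")
  spike_raster(tr, path)
  expect_identical(names(utils::read.csv(path)), c("time_ms", "neuron_id"))
})
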