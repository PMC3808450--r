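p <- neuron_params()

test_that("parameter validation enforces the voltage ordering and positivity", {
  expect_error(neuron_params(v_rest = -50, v_reset = -55), "v_rest")
  expect_error(neuron_params(tau_m = -1), "time constants")
  expect_error(neuron_params(adp_amp = -5), "adp_amp")
  expect_error(synapse_group(1, 1, -0.5, 1), "weights")
  expect_error(spike_trains(list(c(3, 2)), 10), "increasing")
  expect_error(spike_trains(list(c(2, 12)), 10), "outside")
})

test_that("resting potential is a fixed point of the membrane equation", {
  net <- spiking_network(1, params = p)
  sim <- simulate_network(net, NULL, duration = 100, record_v = 1)
  expect_equal(max(abs(sim$v[, 1] - p$v_rest)), 0)
  expect_length(sim$spikes[[1]], 0)
})

test_that("constant subthreshold conductance drives V to its closed-form value", {
  ge <- 1.5
  vss <- (p$g_l * p$v_rest + ge * p$e_exc) / (p$g_l + ge)
  net <- spiking_network(1, params = p)
  sim <- simulate_network(net, NULL, duration = 500, record_v = 1,
                          const_ge = ge)
  expect_lt(vss, p$v_thr)
  expect_equal(tail(sim$v[, 1], 1), vss, tolerance = 1e-8)
})

test_that("spike shape: peak, linear ramp, reset, and ADP onset", {
  net <- spiking_network(1, params = p)
  sim <- simulate_network(net, NULL, duration = 300, record_v = 1,
                          const_ge = 6)
  ts <- sim$spikes[[1]][1]
  s0 <- as.integer(round(ts / 0.1))
  expect_equal(unname(sim$v[s0, 1]), p$v_peak)
  n_ref <- as.integer(p$tau_ref / 0.1)
  expect_equal(unname(sim$v[s0 + n_ref, 1]), p$v_reset)
  # linear in between
  ramp <- sim$v[s0:(s0 + n_ref), 1]
  expect_equal(diff(ramp), rep(diff(ramp)[1], n_ref), tolerance = 1e-10)
  # voltage never exceeds the spike peak; outside refractory never
  # exceeds threshold at step boundaries
  expect_lte(max(sim$v[, 1]), p$v_peak)
})

test_that("suprathreshold drive gives the closed-form LIF period (ADP off)", {
  p0 <- neuron_params(adp_amp = 0)
  ge <- 6
  gt <- p0$g_l + ge
  vss <- (p0$g_l * p0$v_rest + ge * p0$e_exc) / gt
  tau <- p0$tau_m * p0$g_l / gt
  isi_theory <- p0$tau_ref + tau * log((vss - p0$v_reset) / (vss - p0$v_thr))
  net <- spiking_network(1, params = p0)
  sim <- simulate_network(net, NULL, duration = 2000, const_ge = ge)
  isi <- diff(sim$spikes[[1]])
  expect_equal(mean(isi), isi_theory, tolerance = 0.02)
})

test_that("synaptic delays are honoured exactly at bin resolution", {
  dt <- 0.1
  net <- spiking_network(1, params = p, n_ext = 1,
                         synapses = list(synapse_group(1, 1, 2, 3.7,
                                                       external = TRUE)))
  sim <- simulate_network(net, spike_trains(list(10), 100), duration = 100,
                          record_v = 1)
  # conductance jump perturbs V first at emission bin + round(delay/dt)
  v <- sim$v[, 1]
  first_dev <- which(abs(v - p$v_rest) > 1e-12)[1]
  expect_equal(first_dev, as.integer(10 / dt) + as.integer(round(3.7 / dt)) + 1L)
})

test_that("conductance decay between events is exact exponential", {
  net <- spiking_network(1, params = p, n_ext = 1,
                         synapses = list(synapse_group(1, 1, 2, 0.1,
                                                       external = TRUE)))
  sim <- simulate_network(net, spike_trains(list(5), 60), duration = 60,
                          record_v = 1)
  # infer g_e(t) from the forward-Euler voltage updates
  v <- c(p$v_rest, sim$v[, 1])
  cap <- p$tau_m * p$g_l
  dv <- diff(v) * cap / 0.1
  ge <- (dv - p$g_l * (p$v_rest - v[-length(v)])) /
    (p$e_exc - v[-length(v)])
  on <- which(ge > 1)[1]
  ratio <- ge[on + 10] / ge[on]
  expect_equal(ratio, exp(-1 / p$tau_e), tolerance = 1e-6)
})

test_that("simulation is deterministic given the seed", {
  net <- spiking_network(3, params = p, bg_rate = 300, bg_weight = 2)
  set.seed(99)
  a <- simulate_network(net, NULL, duration = 2000, record_v = 1:3)
  set.seed(99)
  b <- simulate_network(net, NULL, duration = 2000, record_v = 1:3)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$v, b$v)
})

test_that("empty stimulus with no background produces no output spikes", {
  net <- spiking_network(2, params = p, n_ext = 1,
                         synapses = list(synapse_group(1, 1, 2, 1,
                                                       external = TRUE)))
  sim <- simulate_network(net, spike_trains(list(numeric(0)), 500),
                          duration = 500)
  expect_equal(sum(lengths(sim$spikes)), 0)
})

test_that("halving dt changes the background-driven rate by < 5%", {
  net <- spiking_network(1, params = p, bg_rate = 800, bg_weight = 2)
  set.seed(5)
  r1 <- length(simulate_network(net, NULL, 20000, dt = 0.1)$spikes[[1]]) / 20
  set.seed(5)
  r2 <- length(simulate_network(net, NULL, 20000, dt = 0.05)$spikes[[1]]) / 20
  expect_gt(r1, 1)   # regime check: actually firing
  expect_lt(abs(r1 - r2) / r1, 0.05)
})

test_that("recorder and argument validation fail loudly", {
  net <- spiking_network(2, params = p)
  expect_error(simulate_network(net, NULL, 10, record_v = 5), "nonexistent")
  expect_error(simulate_network(net, NULL, 10, dt = 0), "dt")
})
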