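test_that("rate estimate is a first-order filter of the instantaneous rate", {
  ctrl <- rate_controller(10, n = 1)
  # silent neuron: estimate decays towards zero
  for (i in 1:50) ctrl <- update_rate_estimate(ctrl, 0, 1000)
  expect_equal(ctrl$rate_estimate, 10 * exp(-50 / 10), tolerance = 1e-6)
  # steady 10 Hz drive for much longer than t_rate converges to 10
  ctrl <- rate_controller(5, n = 1)
  for (i in 1:200) ctrl <- update_rate_estimate(ctrl, 10, 1000)
  expect_equal(ctrl$rate_estimate, 10, tolerance = 1e-3)
  # 63% of a step after one time constant
  ctrl <- rate_controller(10, n = 1)
  ctrl$rate_estimate <- 0
  for (i in 1:10) ctrl <- update_rate_estimate(ctrl, 10, 1000)
  expect_equal(ctrl$rate_estimate, 10 * (1 - exp(-1)), tolerance = 0.01)
})

test_that("controller is neutral at zero error and scales down when high", {
  ctrl <- rate_controller(10, n = 1)
  cs <- controller_step(ctrl, 1000)
  expect_equal(cs$scale, 1)
  # sustained positive error: cumulative product of multipliers < 1
  ctrl <- rate_controller(10, n = 1)
  ctrl$rate_estimate <- 15
  prod_scale <- 1
  for (i in 1:20) {
    cs <- controller_step(ctrl, 1000)
    ctrl <- cs$ctrl
    prod_scale <- prod_scale * cs$scale
  }
  expect_lt(prod_scale, 1)
  # integral stays within the anti-windup clamp
  expect_lte(abs(ctrl$integral), ctrl$i_clamp[1])
})

test_that("plasticity gate is 1 only at the constraint and decays in |e|, |I|", {
  ctrl <- rate_controller(10, n = 3)
  expect_equal(plasticity_gate(ctrl), rep(1, 3))
  se <- ctrl$gate_width_e[1]
  ctrl$rate_estimate <- ctrl$target + c(-3 * se, 0, 3 * se)
  g <- plasticity_gate(ctrl)
  expect_lt(g[1], 0.02)
  expect_lt(g[3], 0.02)
  expect_equal(g[2], 1)
  expect_equal(g[1], g[3])  # even symmetry
  # strictly decreasing in |I|
  ctrl2 <- rate_controller(10, n = 1)
  ctrl2$integral <- ctrl2$gate_width_i / 2
  expect_lt(plasticity_gate(ctrl2), 1)
})

test_that("closed loop holds a Poisson-driven neuron at its set-point", {
  p <- neuron_params()
  for (target in c(1.5, 10)) {
    rates <- sapply(1:3, function(s) {
      set.seed(s)
      net <- spiking_network(1, params = p, n_ext = 200,
        synapses = list(synapse_group(1:200, 1L, 0.4, 1, plastic = TRUE,
                                      external = TRUE)))
      net$target_rate <- target
      fit <- train_network(net, function(i)
        poisson_spike_trains(matrix(8, 200, 1), 1000, duration = 1000),
        200, rate_only_rule(), scaling_gain = 1e-3)
      mean(tail(fit$diagnostics$rate, 60))
    })
    expect_lt(abs(mean(rates) - target) / target, 0.1)
  }
})

test_that("multiplicative scaling never drives weights negative", {
  set.seed(2)
  net <- spiking_network(1, params = neuron_params(), n_ext = 50,
    synapses = list(synapse_group(1:50, 1L, 5, 1, plastic = TRUE,
                                  external = TRUE)))
  net$target_rate <- 1
  fit <- train_network(net, function(i)
    poisson_spike_trains(matrix(30, 50, 1), 1000, duration = 1000),
    50, rate_only_rule(), scaling_gain = 0.01)
  expect_true(all(fit$net$synapses[[1]]$weight >= 0))
})

test_that("gating suppresses expressed plasticity during a rate perturbation", {
  # single neuron driven far from its rate target: cumulative |dw| with the
  # gate must be a small fraction of the ungated value
  p <- neuron_params()
  run <- function(gated) {
    set.seed(4)
    net <- spiking_network(1, params = p, n_ext = 100,
      synapses = list(synapse_group(1:100, 1L, 1.5, 1, plastic = TRUE,
                                    external = TRUE)))
    net$target_rate <- 1
    w0 <- net$synapses[[1]]$weight
    ctrl <- rate_controller(1, n = 1, scaling_gain = 0)  # no rescaling
    fit <- train_network(net, function(i)
      poisson_spike_trains(matrix(15, 100, 1), 1000, duration = 1000),
      30, convallis_rule(), rate_constraint = gated, controller = ctrl)
    sum(abs(fit$net$synapses[[1]]$weight - w0))
  }
  dw_gated <- run(TRUE)
  dw_free <- run(FALSE)
  expect_gt(dw_free, 0)
  expect_lt(dw_gated, 0.1 * dw_free)
})
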