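test_that("feedforward builder respects connectivity and weight ranges", {
  set.seed(1)
  spec <- feedforward_spec(n_outputs = 10)
  net <- build_feedforward(spec, n_inputs = 200)
  exc <- net$synapses[[1]]; inh <- net$synapses[[2]]
  expect_true(exc$plastic && !exc$inh)
  expect_true(!inh$plastic && inh$inh)
  # binomial bounds on the excitatory in-degree
  indeg <- tabulate(exc$tgt, nbins = 10)
  mu <- 0.5 * 200; sd4 <- 4 * sqrt(200 * 0.25)
  expect_true(all(abs(indeg - mu) < sd4))
  # inhibitory projections from every input, exactly
  expect_equal(sort(unique(inh$src)), 1:200)
  expect_equal(tabulate(inh$tgt, nbins = 10), rep(200L, 10))
  expect_true(all(exc$weight >= spec$exc_init_range[1] &
                    exc$weight <= spec$exc_init_range[2]))
  expect_true(all(exc$delay >= 0.1 & exc$delay <= 5))
  expect_error(build_feedforward(spec, 0), "empty")
})

test_that("recurrent builder: counts, density, no self-connections, tonotopy", {
  set.seed(2)
  spec <- recurrent_spec(n_total = 1000)
  net <- build_recurrent(spec, n_channels = 20)
  expect_equal(net$n_exc, 800)
  expect_equal(net$n_inh, 200)
  exc <- net$synapses[[1]]; inh <- net$synapses[[2]]
  expect_true(exc$plastic && !inh$plastic)
  expect_true(all(exc$src != exc$tgt))
  expect_true(all(inh$src != inh$tgt))
  m <- length(exc$src) + length(inh$src)
  mu <- 1000 * 999 * 0.05
  expect_lt(abs(m - mu), 4 * sqrt(mu))
  expect_true(all(exc$weight >= 0))
  # tonotopic input: most targets within 2.45 sigma of the channel locus
  ing <- net$synapses[[3]]
  d <- vapply(seq_along(ing$src), function(i)
    convallis:::torus_distance(net$positions[ing$tgt[i], , drop = FALSE],
                               net$input_locus[ing$src[i], ]), numeric(1))
  expect_gt(mean(d < 2.45 * spec$tonotopic_sigma), 0.90)
})

test_that("network construction is reproducible from the seed", {
  spec <- recurrent_spec(n_total = 300)
  set.seed(7); a <- build_recurrent(spec)
  set.seed(7); b <- build_recurrent(spec)
  expect_identical(a$synapses, b$synapses)
  expect_identical(a$positions, b$positions)
})

test_that("spontaneous rate decreases with coupling, increases with drive", {
  # monotonicity probes behind the calibration search, at reduced size
  spec <- recurrent_spec(n_total = 800, connection_prob = 225 / 800)
  set.seed(3)
  base <- build_recurrent(spec)
  rate_of <- function(net, dur = 2500) {
    sim <- simulate_network(net, NULL, duration = dur)
    tt <- unlist(sim$spikes, use.names = FALSE)
    sum(tt > 500) / ((dur - 500) / 1000) / net$n_neurons
  }
  weak_inh <- convallis:::scale_recurrent_weights(base, 1, factor_inh = 0.5)
  strong_inh <- convallis:::scale_recurrent_weights(base, 1, factor_inh = 2)
  set.seed(4); r_weak <- rate_of(weak_inh)
  set.seed(4); r_strong <- rate_of(strong_inh)
  expect_gt(r_weak, r_strong)
  # doubling the background rate at fixed conductances raises the rate
  more_bg <- base; more_bg$bg_rate <- base$bg_rate * 2
  set.seed(4); r_bg <- rate_of(more_bg)
  set.seed(4); r_ref <- rate_of(base)
  expect_gt(r_bg, r_ref)
})

test_that("calibration reaches the spontaneous set-point at reduced size", {
  set.seed(5)
  spec <- recurrent_spec(n_total = 800, connection_prob = 225 / 800)
  cal <- calibrate_spontaneous_state(spec, target_rate = 1.5,
                                     probe_duration = 2500,
                                     final_duration = 5000, discard = 500)
  expect_lt(abs(cal$rate - 1.5) / 1.5, 0.15)
  expect_gt(cal$cv_isi, 0.7)   # irregular firing
  expect_lt(abs(cal$correlation), 0.2)  # asynchronous
})
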