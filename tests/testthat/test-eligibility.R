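p <- neuron_params()
rule <- convallis_rule()

# noisy subthreshold voltage trace for eligibility tests
noisy_trace <- function(n, seed) {
  set.seed(seed)
  pmin(p$v_rest + cumsum(rnorm(n, 0, 0.2)), -45)
}

test_that("no presynaptic spikes give zero eligibility", {
  v <- noisy_trace(2000, 1)
  expect_equal(accumulate_eligibility_direct(v, list(numeric(0)), 0, rule, p),
               0)
  expect_equal(accumulate_eligibility_fast(v, list(numeric(0)), 0, rule, p),
               0)
})

test_that("voltage clamped at rest gives the closed-form eligibility", {
  # V clamped: P = gain * g0 * (E - Vrest) * sum_f int e^{-(T-s)/tau_p} eps(s - t_f) ds
  dt <- 0.02; n <- 50000; T <- n * dt
  v <- rep(p$v_rest, n)
  g0 <- gprime(p$v_rest, rule$objective)
  tf <- c(100, 400, 650)
  got <- accumulate_eligibility_direct(v, list(tf), p$e_exc, rule, p,
                                       tau_eff = p$tau_m, dt = dt)
  # closed-form double-exponential integral, truncated at T
  ts <- max(p$tau_e, p$tau_m); tf2 <- min(p$tau_e, p$tau_m)
  tstar <- log(ts / tf2) / (1 / tf2 - 1 / ts)
  peak <- exp(-tstar / ts) - exp(-tstar / tf2)
  ana <- 0
  for (t0 in tf) {
    intexp <- function(tau) {
      # int_{t0}^{T} e^{-(T-s)/tau_p} e^{-(s-t0)/tau} ds
      a <- 1 / rule$tau_p - 1 / tau
      exp(-(T - t0) / rule$tau_p) * (exp(a * (T - t0)) - 1) / a
    }
    ana <- ana + (intexp(ts) - intexp(tf2)) / peak
  }
  expected <- rule$gain * g0 * (p$e_exc - p$v_rest) * ana
  expect_equal(got, expected, tolerance = 5e-3)
})

test_that("two identical synapses with identical spikes get identical P", {
  v <- noisy_trace(5000, 3)
  tf <- sort(runif(6, 0, 480))
  out <- accumulate_eligibility_fast(v, list(tf, tf), 0, rule, p)
  expect_identical(out[1], out[2])
})

test_that("fast backward path equals the direct path on random instances", {
  # the central correctness property of the implementation trick
  set.seed(42)
  for (i in 1:100) {
    n <- 2000 + sample(0:2000, 1)
    v <- noisy_trace(n, i)
    tau_eff <- runif(1, 4, 20)
    arr <- lapply(1:10, function(j) sort(runif(sample(1:8, 1), 0, n * 0.1 - 1)))
    erev <- sample(c(0, -80), 10, replace = TRUE)
    d <- accumulate_eligibility_direct(v, arr, erev, rule, p,
                                       tau_eff = tau_eff)
    f <- accumulate_eligibility_fast(v, arr, erev, rule, p,
                                     tau_eff = tau_eff)
    expect_equal(f, d, tolerance = 1e-6)
  }
})

test_that("fast path agrees with direct on a 2 s noisy-voltage instance", {
  v <- noisy_trace(20000, 7)
  set.seed(8)
  arr <- lapply(1:10, function(j) sort(runif(8, 0, 1999)))
  d <- accumulate_eligibility_direct(v, arr, 0, rule, p)
  f <- accumulate_eligibility_fast(v, arr, 0, rule, p)
  expect_equal(f, d, tolerance = 1e-6)
  expect_gt(max(abs(d)), 0)   # non-degenerate instance
})

test_that("a common time shift of spikes and voltage leaves P unchanged", {
  # prepending silence and shifting everything (trace end included) keeps
  # every pattern-end-relative weight identical
  n <- 6000
  v <- noisy_trace(n, 9)
  shift_steps <- 500
  v2 <- c(rep(p$v_rest, shift_steps), v)
  arr <- list(c(50, 120, 300))
  arr2 <- list(arr[[1]] + shift_steps * 0.1)
  d1 <- accumulate_eligibility_direct(v, arr, 0, rule, p)
  d2 <- accumulate_eligibility_direct(v2, arr2, 0, rule, p)
  f2 <- accumulate_eligibility_fast(v2, arr2, 0, rule, p)
  expect_equal(f2, d2, tolerance = 1e-9)
  expect_equal(d2, d1, tolerance = 1e-9)
})

test_that("arrival times outside the trace are rejected", {
  v <- noisy_trace(1000, 10)
  expect_error(accumulate_eligibility_direct(v, list(200), 0, rule, p),
               "outside")
  expect_error(accumulate_eligibility_fast(v, list(200), 0, rule, p),
               "outside")
})

test_that("zero-everywhere gradient gives zero eligibility for all synapses", {
  # clamp far below rest where both sigmoids vanish
  v <- rep(-200, 3000)
  arr <- lapply(1:5, function(j) sort(runif(4, 0, 290)))
  f <- accumulate_eligibility_fast(v, arr, 0, rule, p)
  expect_equal(f, rep(0, 5), tolerance = 1e-10)
})
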