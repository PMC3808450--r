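test_that("pair STDP closed forms", {
  p <- stdp_rule(a_plus = 0.1, a_minus = 0.12, tau_plus = 17, tau_minus = 34)
  expect_equal(stdp_weight_change(100, 110, p), 0.1 * exp(-10 / 17))
  expect_equal(stdp_weight_change(110, 100, p), -0.12 * exp(-10 / 34))
  expect_equal(stdp_weight_change(numeric(0), c(1, 2), p), 0)
  expect_equal(stdp_weight_change(c(1, 2), numeric(0), p), 0)
})

test_that("all-to-all STDP is additive over disjoint windows", {
  p <- stdp_rule(a_plus = 0.1, a_minus = 0.1, tau_plus = 20, tau_minus = 20)
  set.seed(3)
  pre1 <- sort(runif(10, 0, 400)); post1 <- sort(runif(10, 0, 400))
  pre2 <- sort(runif(10, 5000, 5400)); post2 <- sort(runif(10, 5000, 5400))
  joint <- stdp_weight_change(c(pre1, pre2), c(post1, post2), p)
  parts <- stdp_weight_change(pre1, post1, p) +
    stdp_weight_change(pre2, post2, p)
  # windows 4600 ms apart: cross terms are e^{-230} = 0
  expect_equal(joint, parts, tolerance = 1e-12)
})

test_that("nearest-neighbour mode uses only adjacent pairs", {
  p <- stdp_rule(a_plus = 0.1, a_minus = 0, tau_plus = 20, tau_minus = 20,
                 mode = "nearest_neighbour")
  # two posts after one pre: only the nearest contributes
  expect_equal(stdp_weight_change(100, c(110, 120), p), 0.1 * exp(-10 / 20))
  pa <- stdp_rule(a_plus = 0.1, a_minus = 0, tau_plus = 20, tau_minus = 20)
  expect_equal(stdp_weight_change(100, c(110, 120), pa),
               0.1 * (exp(-10 / 20) + exp(-20 / 20)))
})

test_that("grouped STDP evaluation matches the per-synapse closed form", {
  p <- stdp_rule(a_plus = 0.07, a_minus = 0.09, tau_plus = 18, tau_minus = 25)
  set.seed(11)
  post <- sort(runif(15, 0, 1000))
  pre_list <- lapply(1:20, function(i) sort(runif(sample(0:6, 1), 0, 1000)))
  got <- convallis:::stdp_dw_group(pre_list, post, p)
  want <- vapply(pre_list, stdp_weight_change, numeric(1), post = post, p = p)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("triplet rule reduces to pair STDP at zero triplet amplitudes", {
  tp <- triplet_params(a2_plus = 0.05, a2_minus = 0.06, a3_plus = 0,
                       a3_minus = 0, tau_plus = 16.8, tau_minus = 33.7)
  sp <- stdp_rule(a_plus = 0.05, a_minus = 0.06, tau_plus = 16.8,
                  tau_minus = 33.7)
  set.seed(4)
  pre <- sort(runif(12, 0, 800)); post <- sort(runif(12, 0, 800))
  expect_equal(triplet_weight_change(pre, post, tp),
               stdp_weight_change(pre, post, sp), tolerance = 1e-10)
})

test_that("triplet event computation matches a brute-force trace simulation", {
  p <- triplet_params_visual_cortex()
  set.seed(9)
  pre <- sort(round(runif(8, 10, 700), 1))
  post <- sort(round(runif(8, 10, 700), 1))
  # ODE oracle: integrate the four traces on a 0.01 ms grid
  dt <- 0.01
  n <- as.integer(800 / dt)
  r1 <- r2 <- o1 <- o2 <- 0
  dw <- 0
  pre_steps <- as.integer(round(pre / dt))
  post_steps <- as.integer(round(post / dt))
  for (s in seq_len(n)) {
    r1 <- r1 * (1 - dt / p$tau_plus); r2 <- r2 * (1 - dt / p$tau_x)
    o1 <- o1 * (1 - dt / p$tau_minus); o2 <- o2 * (1 - dt / p$tau_y)
    if (s %in% pre_steps) {
      dw <- dw - o1 * (p$a2_minus + p$a3_minus * r2)
      r1 <- r1 + 1; r2 <- r2 + 1
    }
    if (s %in% post_steps) {
      dw <- dw + r1 * (p$a2_plus + p$a3_plus * o2)
      o1 <- o1 + 1; o2 <- o2 + 1
    }
  }
  got <- triplet_weight_change(pre, post, p)
  # Euler decay error at dt = 0.01 ms is ~1e-6 relative
  expect_equal(got, dw, tolerance = 1e-4)
})

test_that("triplet asymmetry: post-pre-post above pre-post-pre (visual-cortex fit)", {
  p <- triplet_params_visual_cortex()
  t0 <- (0:59) * 1000
  ppp <- triplet_weight_change(t0 + 5, sort(c(t0, t0 + 10)), p)
  ppre <- triplet_weight_change(sort(c(t0, t0 + 10)), t0 + 5, p)
  expect_gt(ppp, ppre)
  # the triplet term is what lifts post-pre-post: removing it collapses
  # the asymmetry towards the additive-STDP prediction
  p0 <- triplet_params(p$a2_plus, p$a2_minus, 0, 0, p$tau_plus,
                       p$tau_minus, p$tau_x, p$tau_y)
  ppp0 <- triplet_weight_change(t0 + 5, sort(c(t0, t0 + 10)), p0)
  expect_gt(ppp - ppp0, 0)
})
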