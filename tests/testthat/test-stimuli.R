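test_that("circular-Gaussian rates peak at the centre and decay with distance", {
  spec <- circular_ensemble_spec(n_excitatory = 200, n_inhibitory = 0)
  set.seed(1)
  cg <- circular_gaussian_rates(spec, 2000)
  expect_equal(ncol(cg$rates), 20)
  for (h in seq_along(cg$centers)) {
    expect_equal(cg$rates[cg$centers[h], h], spec$peak_rate)
    # antipodal position has the closed-form minimum rate
    anti <- ((cg$centers[h] - 1 + 100) %% 200) + 1
    sigma <- spec$profile_width * 200
    expect_equal(cg$rates[anti, h],
                 spec$peak_rate * exp(-100^2 / (2 * sigma^2)))
  }
})

test_that("bump centres are uniform over ring positions", {
  spec <- circular_ensemble_spec(n_excitatory = 50, n_inhibitory = 0)
  set.seed(2)
  cg <- circular_gaussian_rates(spec, 200 * 1000)  # 2000 holds
  tab <- tabulate(cg$centers, nbins = 50)
  pv <- chisq.test(tab)$p.value
  expect_gt(pv, 0.01)
})

test_that("digit ensemble is reproducible and class-structured", {
  spec <- digit_ensemble_spec(n_classes = 4, n_channels = 30,
                              sample_rate = 100, n_speakers_train = 3,
                              n_speakers_test = 2)
  a <- synthesize_digit_ensemble(spec, seed = 3)
  b <- synthesize_digit_ensemble(spec, seed = 3)
  expect_identical(a$utterances, b$utterances)
  # disjoint speaker sets between splits
  spk <- vapply(a$utterances, `[[`, numeric(1), "speaker")
  spl <- vapply(a$utterances, `[[`, character(1), "split")
  expect_length(intersect(spk[spl == "train"], spk[spl == "test"]), 0)
  # zero variability: all utterances of a class identical
  spec0 <- digit_ensemble_spec(n_classes = 3, n_channels = 30,
                               sample_rate = 100, time_warp = 0,
                               channel_jitter = 0, amp_noise = 0)
  z <- synthesize_digit_ensemble(spec0, seed = 4)
  labs <- vapply(z$utterances, `[[`, numeric(1), "label")
  for (k in 1:3) {
    us <- z$utterances[labs == k]
    for (u in us[-1]) expect_equal(u$intensity, us[[1]]$intensity)
  }
  # distinct class templates: cross-class correlation below within-class
  m1 <- as.vector(z$utterances[[1]]$intensity)
  m2 <- as.vector(z$utterances[[2]]$intensity)
  expect_lt(cor(m1, m2), 0.5)
  expect_error(digit_ensemble_spec(n_classes = 1), "classes")
})

test_that("utterance normalization is idempotent and scale invariant", {
  set.seed(5)
  m <- matrix(runif(200), 10)
  n1 <- normalize_utterance(m)
  expect_equal(sum(n1), length(m), tolerance = 1e-9)
  expect_equal(normalize_utterance(n1), n1)
  expect_equal(normalize_utterance(7 * m), n1)
  expect_error(normalize_utterance(matrix(0, 2, 2)), "all-zero")
  expect_error(normalize_utterance(matrix(-1, 2, 2)), "non-negative")
})

test_that("Poisson encoding hits the grand-mean rate and scales linearly", {
  spec <- digit_ensemble_spec(n_classes = 6, n_channels = 40,
                              sample_rate = 100, n_speakers_train = 9,
                              n_speakers_test = 9)
  ens <- synthesize_digit_ensemble(spec, seed = 6)
  set.seed(6)
  enc <- encode_poisson_ensemble(ens, mean_rate = 5)
  expect_gte(length(enc), 100)
  rate <- mean(vapply(enc, function(u)
    sum(lengths(u$spikes)) / 40, numeric(1)))
  expect_lt(abs(rate - 5) / 5, 0.02)
  # zero-intensity channels produce no spikes
  u1 <- ens$utterances[[1]]
  zch <- which(rowSums(u1$intensity) == 0)
  if (length(zch)) {
    e1 <- encode_poisson_ensemble(ens, mean_rate = 5)[[1]]
    expect_equal(sum(lengths(e1$spikes[zch])), 0)
  }
  # doubling the mean rate doubles the expected count
  set.seed(6)
  enc2 <- encode_poisson_ensemble(ens, mean_rate = 10)
  rate2 <- mean(vapply(enc2, function(u)
    sum(lengths(u$spikes)) / 40, numeric(1)))
  expect_lt(abs(rate2 - 10) / 10, 0.02)
})
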