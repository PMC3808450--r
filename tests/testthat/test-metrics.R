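test_that("skewness matches closed-form moments and an independent package", {
  set.seed(1)
  x <- rnorm(1e6)
  expect_lt(abs(subthreshold_skewness(x)), 0.05)
  y <- rexp(1e6)
  expect_equal(subthreshold_skewness(y), 2, tolerance = 0.05)
  # agreement with the moment estimator in e1071
  z <- rexp(5e4)
  expect_equal(subthreshold_skewness(z), e1071::skewness(z, type = 1),
               tolerance = 1e-10)
  # rest-plus-excursion mixture is positively skewed
  mix <- c(rnorm(9500, -65, 1), rnorm(500, -52, 1))
  expect_gt(subthreshold_skewness(mix), 0)
  expect_error(subthreshold_skewness(rep(1, 100)), "constant")
})

test_that("skewness excises spike shapes", {
  p <- neuron_params()
  v <- rep(-65, 10000)
  # plant spike artefacts; with excision the trace is constant -> error
  v[3000:3040] <- 20
  expect_error(subthreshold_skewness(v, spike_times = 300, params = p),
               "constant")
  # without excision the artefact dominates the third moment
  expect_gt(subthreshold_skewness(v), 5)
})

test_that("tuning index spans untuned to perfectly tuned", {
  expect_equal(tuning_index(rep(3, 8)), 0, tolerance = 1e-12)
  r <- rep(0, 8); r[3] <- 5
  expect_equal(tuning_index(r), 1)
  r2 <- rep(0, 8); r2[c(1, 5)] <- 2   # antipodal pair cancels
  expect_equal(tuning_index(r2), 0, tolerance = 1e-12)
  expect_error(tuning_index(rep(0, 4)), "all-zero")
  expect_error(tuning_index(c(-1, 2)), ">= 0")
})

test_that("F-statistic equals the hand computation and anova(lm())", {
  counts <- c(1, 3, 3, 5)
  labels <- c("a", "a", "b", "b")
  expect_equal(f_statistic(counts, labels), 2)
  # identical class means with nonzero within-variance gives F = 0
  expect_equal(f_statistic(c(1, 3, 1, 3), labels), 0)
  # cross-check against the standard linear-model ANOVA on random data
  set.seed(2)
  y <- rpois(30, 6 + 3 * rep(0:2, each = 10))
  g <- rep(letters[1:3], each = 10)
  want <- anova(lm(y ~ factor(g)))$`F value`[1]
  expect_equal(f_statistic(y, g), want, tolerance = 1e-10)
  expect_error(f_statistic(c(1, 2), c("a", "b")), "2 presentations")
  expect_error(f_statistic(c(1, 1, 1, 1), c("a", "a", "b", "b")), "within")
})

test_that("a tuned neuron's F beats its label-permutation null", {
  set.seed(3)
  labels <- rep(1:5, each = 8)
  counts <- rpois(40, lambda = c(2, 2, 2, 2, 12)[labels])
  f0 <- f_statistic(counts, labels)
  null <- replicate(1000, f_statistic(counts, sample(labels)))
  expect_gt(f0, quantile(null, 0.95))
})

test_that("CV-ISI: regular, Poisson, and the hand-computed example", {
  expect_equal(cv_isi(seq(0, 1000, by = 10)), 0)
  set.seed(4)
  tt <- cumsum(rexp(10000, rate = 1 / 50))
  expect_equal(cv_isi(tt), 1, tolerance = 0.05)
  expect_equal(cv_isi(c(0, 1, 4)), sqrt(2) / 2)   # ISIs 1,3; sample sd
  expect_error(cv_isi(c(1, 2)), "3 spikes")
})

test_that("pairwise correlation: independence, identity, common input", {
  set.seed(5)
  dur <- 100 * 1000
  ind <- spike_trains(lapply(1:20, function(i)
    sort(runif(rpois(1, 5 * 100), 0, dur))), dur)
  expect_lt(abs(pairwise_correlation(ind, n_pairs = 500)), 0.01)
  # a duplicated train correlates perfectly with itself
  tt <- sort(runif(500, 0, dur))
  dup <- spike_trains(list(tt, tt), dur)
  expect_equal(pairwise_correlation(dup, n_pairs = 10), 1)
  # thinning a common mother train yields positive correlation rising with p
  mother <- sort(runif(20000, 0, dur))
  thin <- function(pr) spike_trains(lapply(1:10, function(i)
    mother[runif(length(mother)) < pr]), dur)
  c_lo <- pairwise_correlation(thin(0.2), n_pairs = 200)
  c_hi <- pairwise_correlation(thin(0.8), n_pairs = 200)
  expect_gt(c_lo, 0.05)
  expect_gt(c_hi, c_lo)
})

test_that("linear readout separates a separable toy and not shuffled labels", {
  set.seed(6)
  n <- 60
  labels <- rep(1:3, each = n / 3)
  x <- matrix(rpois(n * 10, 3), n) + 8 * outer(labels, 1:10, function(l, j)
    (l == (j %% 3) + 1))
  m <- train_readout(x, labels)
  expect_equal(evaluate_readout(m, x, labels), 0)
  # shuffled training labels: test error near chance
  set.seed(7)
  m2 <- train_readout(x, sample(labels))
  err <- evaluate_readout(m2, x, labels)
  expect_gt(err, 1 - 1 / 3 - 0.25)
  expect_error(train_readout(x, rep(1, n)), "single class")
})

test_that("ridge readout is within a few points of the large-margin model", {
  set.seed(8)
  n <- 120
  labels <- rep(1:4, each = n / 4)
  centers <- matrix(rnorm(4 * 20, sd = 1.2), 4)
  x <- centers[labels, ] + matrix(rnorm(n * 20), n)
  xt <- centers[labels, ] + matrix(rnorm(n * 20), n)
  e_svm <- evaluate_readout(train_readout(x, labels), xt, labels)
  e_ridge <- evaluate_readout(train_readout(x, labels, method = "ridge"),
                              xt, labels)
  expect_lt(abs(e_svm - e_ridge), 0.03 + 1e-9)
})
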