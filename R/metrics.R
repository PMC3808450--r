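#' Skewness of the subthreshold membrane-potential distribution
#'
#' Third standardized moment of the voltage samples after excising the
#' spike shapes: samples in
#' \code{[t_spike - 1, t_spike + tau_ref + exclusion_window]} ms around each
#' spike are removed.  An increase in subthreshold skewness is the
#' signature the plasticity rule optimizes for.
#'
#' @param voltage voltage trace sampled at \code{dt}
#' @param spike_times spike times (ms)
#' @param params \code{\link{neuron_params}} (for the refractory period)
#' @param exclusion_window extra excision after the refractory ramp (ms)
#' @param dt sample spacing (ms)
#' @return skewness (dimensionless)
#' @export
subthreshold_skewness <- function(voltage, spike_times = numeric(0),
                                  params = neuron_params(),
                                  exclusion_window = 5, dt = 0.1) {
  keep <- rep(TRUE, length(voltage))
  for (ts in spike_times) {
    a <- max(1L, as.integer(floor((ts - 1) / dt)))
    b <- min(length(voltage),
             as.integer(ceiling((ts + params$tau_ref + exclusion_window) / dt)))
    if (a <= b) keep[a:b] <- FALSE
  }
  v <- voltage[keep]
  if (length(v) < 3) stop("too few subthreshold samples")
  s <- sd(v)
  if (s == 0) stop("constant voltage trace: skewness undefined")
  mean((v - mean(v))^3) / (mean((v - mean(v))^2))^1.5
}

#' Circular tuning index
#'
#' Resultant-vector length of the rate profile over equally spaced angular
#' positions: 0 for untuned, 1 for a response confined to one position.
#'
#' @param rates mean rate per angular position (non-negative, not all zero);
#'   positions are mapped to angles \code{2 pi (i - 1) / n}
#' @return tuning index in [0, 1]
#' @export
tuning_index <- function(rates) {
  if (any(rates < 0)) stop("rates must be >= 0")
  s <- sum(rates)
  if (s == 0) stop("all-zero rates: tuning undefined")
  theta <- 2 * pi * (seq_along(rates) - 1) / length(rates)
  Mod(sum(rates * exp(1i * theta))) / s
}

#' One-way ANOVA F-statistic for class selectivity
#'
#' Between-class mean square over within-class mean square of per-
#' presentation spike counts; the selectivity measure used for the pattern
#' classes.
#'
#' @param counts numeric vector (one value per presentation) or a
#'   presentations x neurons matrix
#' @param labels class label per presentation
#' @return F value, or a vector of F values for a matrix input
#' @export
f_statistic <- function(counts, labels) {
  if (is.matrix(counts)) {
    return(apply(counts, 2, f_statistic, labels = labels))
  }
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (any(table(labels) < 2)) stop("need at least 2 presentations per class")
  n <- length(counts)
  k <- nlevels(labels)
  mu <- mean(counts)
  mu_c <- tapply(counts, labels, mean)
  n_c <- tabulate(labels)
  ssb <- sum(n_c * (mu_c - mu)^2)
  ssw <- sum((counts - mu_c[labels])^2)
  if (ssw == 0) stop("zero within-class variance: F undefined")
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Coefficient of variation of inter-spike intervals
#'
#' Sample (n-1 denominator) standard deviation of the ISIs divided by the
#' mean ISI: 0 for a regular train, about 1 for Poisson firing.
#'
#' @param spikes sorted spike times (ms)
#' @return CV-ISI; requires at least 3 spikes
#' @export
cv_isi <- function(spikes) {
  if (length(spikes) < 3) stop("need at least 3 spikes for a CV of ISIs")
  isi <- diff(spikes)
  sd(isi) / mean(isi)
}

#' Mean pairwise spike-count correlation
#'
#' Pearson correlation of binned spike counts for randomly sampled distinct
#' neuron pairs; pairs containing a zero-variance count vector are
#' resampled.
#'
#' @param trains a \code{\link{spike_trains}} object
#' @param n_pairs number of random pairs
#' @param bin_size count bin (ms)
#' @param t_min,t_max analysis window (ms); defaults to the full duration
#' @return mean correlation coefficient over the sampled pairs
#' @export
pairwise_correlation <- function(trains, n_pairs = 2000, bin_size = 5,
                                 t_min = 0, t_max = attr(trains, "duration")) {
  stopifnot(inherits(trains, "spike_trains"))
  n <- length(trains)
  if (n < 2) stop("need at least 2 neurons")
  breaks <- seq(t_min, t_max, by = bin_size)
  nb <- length(breaks) - 1
  counts <- vapply(trains, function(tt) {
    tt <- tt[tt >= t_min & tt < t_max]
    tabulate(findInterval(tt, breaks), nbins = nb)
  }, integer(nb))
  active <- which(apply(counts, 2, var) > 0)
  if (length(active) < 2) stop("fewer than 2 neurons with variable counts")
  cc <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    pair <- sample(active, 2)
    cc[k] <- cor(counts[, pair[1]], counts[, pair[2]])
  }
  mean(cc)
}

#' Spike-count matrix over an encoded ensemble
#'
#' Presents each utterance to a network (from rest, no carry-over between
#' utterances) and records per-neuron spike counts.
#'
#' @param net a \code{\link{spiking_network}}
#' @param encoded list of encoded utterances from
#'   \code{\link{encode_poisson_ensemble}}
#' @param neurons which neurons to count (default all)
#' @return list with \code{counts} (utterances x neurons) and \code{labels}
#' @export
count_matrix <- function(net, encoded, neurons = seq_len(net$n_neurons)) {
  counts <- matrix(0L, length(encoded), length(neurons))
  labels <- integer(length(encoded))
  for (i in seq_along(encoded)) {
    sim <- simulate_network(net, encoded[[i]]$spikes,
                            duration = attr(encoded[[i]]$spikes, "duration"))
    counts[i, ] <- lengths(sim$spikes)[neurons]
    labels[i] <- encoded[[i]]$label
  }
  list(counts = counts, labels = labels)
}

#' Spike-count responses over an intensity ensemble with repetitions
#'
#' Encodes every utterance of the requested split \code{reps} times as
#' fresh inhomogeneous Poisson realizations, presents each to the network
#' from rest and sums the per-neuron counts.  At low set-point rates the
#' per-presentation counts are few and Poisson-noisy; a handful of
#' repetitions recovers the count signal-to-noise a much larger population
#' would provide.
#'
#' @param net a \code{\link{spiking_network}}
#' @param ensemble an \code{intensity_ensemble}
#' @param which "train", "test" or "all"
#' @param reps independent presentations summed per utterance
#' @return list with \code{counts} (utterances x neurons) and \code{labels}
#' @export
ensemble_counts <- function(net, ensemble, which = "all", reps = 1) {
  stopifnot(inherits(ensemble, "intensity_ensemble"))
  total <- NULL; labels <- NULL
  for (r in seq_len(reps)) {
    enc <- encode_poisson_ensemble(ensemble, which = which)
    cm <- count_matrix(net, enc)
    if (is.null(total)) { total <- cm$counts; labels <- cm$labels }
    else total <- total + cm$counts
  }
  list(counts = total, labels = labels)
}

#' Linear spike-count readout
#'
#' One-vs-rest multi-class linear support vector machine on spike counts
#' (timing information discarded), cost parameter 0.01; prediction is the
#' argmax over per-class decision values.  A closed-form multi-response
#' ridge regression onto one-hot class targets is available as an
#' alternative (\code{method = "ridge"}).
#'
#' @param counts presentations x neurons count matrix
#' @param labels class labels per presentation
#' @param cost SVM cost parameter
#' @param method "svm" or "ridge"
#' @param lambda ridge penalty
#' @return object of class \code{readout_model}
#' @export
train_readout <- function(counts, labels, cost = 0.01,
                          method = c("svm", "ridge"), lambda = 1) {
  method <- match.arg(method)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("training set has a single class")
  classes <- levels(labels)
  counts <- as.matrix(counts)
  if (method == "svm") {
    machines <- lapply(classes, function(cl) {
      y <- factor(ifelse(labels == cl, "yes", "no"), levels = c("yes", "no"))
      e1071::svm(counts, y, kernel = "linear", cost = cost, scale = FALSE)
    })
    structure(list(method = "svm", machines = machines, classes = classes),
              class = "readout_model")
  } else {
    x <- cbind(1, counts)
    y <- outer(labels, classes, "==") * 1
    w <- solve(crossprod(x) + lambda * diag(ncol(x)), crossprod(x, y))
    structure(list(method = "ridge", w = w, classes = classes),
              class = "readout_model")
  }
}

#' @rdname train_readout
#' @param model a trained \code{readout_model}
#' @param counts_test,labels_test test counts and labels (speaker-disjoint
#'   from training)
#' @return classification error rate (fraction misclassified)
#' @export
evaluate_readout <- function(model, counts_test, labels_test) {
  stopifnot(inherits(model, "readout_model"))
  counts_test <- as.matrix(counts_test)
  if (model$method == "svm") {
    scores <- vapply(model$machines, function(m) {
      dv <- attr(predict(m, counts_test, decision.values = TRUE),
                 "decision.values")
      # e1071 orients the decision value towards whichever class it saw
      # first; normalize so positive always means "yes"
      flip <- if (startsWith(colnames(dv)[1], "no")) -1 else 1
      flip * as.numeric(dv)
    }, numeric(nrow(counts_test)))
    if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  } else {
    scores <- cbind(1, counts_test) %*% model$w
  }
  pred <- model$classes[max.col(scores, ties.method = "first")]
  mean(pred != as.character(labels_test))
}
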