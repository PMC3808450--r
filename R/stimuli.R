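#' Circular-Gaussian stimulus ensemble
#'
#' Specification of the artificial input ensemble used for the basic
#' feature-learning task: a ring of excitatory Poisson sources whose rate
#' profile is a wrapped Gaussian bump re-centred at a uniformly random ring
#' position every \code{hold_duration} ms, plus a constant-rate inhibitory
#' background population.
#'
#' @param n_excitatory,n_inhibitory population sizes
#' @param hold_duration time each bump position is held (ms)
#' @param profile_width bump standard deviation as a fraction of the ring
#' @param peak_rate rate at the bump centre (Hz)
#' @param inhibitory_rate constant inhibitory source rate (Hz)
#' @return object of class \code{circular_ensemble_spec}
#' @export
circular_ensemble_spec <- function(n_excitatory = 1000, n_inhibitory = 250,
                                   hold_duration = 100, profile_width = 0.05,
                                   peak_rate = 30, inhibitory_rate = 10) {
  stopifnot(n_excitatory > 0, n_inhibitory >= 0, hold_duration > 0,
            profile_width > 0, profile_width < 0.5,
            peak_rate >= 0, inhibitory_rate >= 0)
  structure(list(n_excitatory = as.integer(n_excitatory),
                 n_inhibitory = as.integer(n_inhibitory),
                 hold_duration = hold_duration,
                 profile_width = profile_width, peak_rate = peak_rate,
                 inhibitory_rate = inhibitory_rate),
            class = "circular_ensemble_spec")
}

#' Piecewise-constant rates of the circular-Gaussian ensemble
#'
#' For each hold of \code{hold_duration} ms a centre is drawn uniformly
#' over the ring positions and the excitatory rate of input i is
#' \code{peak_rate * exp(-d(i, centre)^2 / (2 sigma^2))} with circular
#' distance d and \code{sigma = profile_width * n_excitatory}.
#'
#' @param spec a \code{\link{circular_ensemble_spec}}
#' @param duration total duration (ms)
#' @return list with \code{rates} (inputs x holds matrix, Hz),
#'   \code{centers} (1-based centre position per hold) and
#'   \code{hold_duration}
#' @export
circular_gaussian_rates <- function(spec, duration) {
  stopifnot(inherits(spec, "circular_ensemble_spec"))
  n <- spec$n_excitatory
  n_holds <- max(1L, as.integer(ceiling(duration / spec$hold_duration)))
  centers <- sample.int(n, n_holds, replace = TRUE)
  sigma <- spec$profile_width * n
  pos <- seq_len(n)
  rates <- vapply(centers, function(cc) {
    d <- abs(pos - cc)
    d <- pmin(d, n - d)
    spec$peak_rate * exp(-d^2 / (2 * sigma^2))
  }, numeric(n))
  list(rates = rates, centers = centers, hold_duration = spec$hold_duration)
}

#' Synthetic multi-class spatiotemporal intensity ensemble
#'
#' Specification for a cochleogram-like labelled ensemble: each class is a
#' distinct smooth template of band-limited ridges over channels x time;
#' each "speaker" applies a systematic time warp and channel jitter, and
#' each utterance adds multiplicative amplitude noise.  Train and test
#' splits use disjoint speaker sets.  A deterministic stand-in for a
#' licensed speech corpus processed through a cochlear filterbank, matching
#' its output format (93 channels, 1 s epochs sampled at 500 Hz).
#'
#' @param n_classes number of pattern classes
#' @param n_channels number of frequency channels
#' @param epoch_length epoch duration (ms)
#' @param sample_rate intensity sampling rate (Hz)
#' @param n_speakers_train,n_speakers_test disjoint speaker counts
#' @param time_warp per-speaker uniform time-warp half-range (fraction)
#' @param channel_jitter per-speaker channel shift half-range (channels)
#' @param amp_noise per-utterance multiplicative amplitude noise half-range
#' @param mean_input_rate grand-mean Poisson rate after encoding (Hz)
#' @return object of class \code{digit_ensemble_spec}
#' @export
digit_ensemble_spec <- function(n_classes = 11, n_channels = 93,
                                epoch_length = 1000, sample_rate = 500,
                                n_speakers_train = 8, n_speakers_test = 6,
                                time_warp = 0.35, channel_jitter = 8,
                                amp_noise = 0.60, mean_input_rate = 5) {
  if (n_classes < 2) stop("need at least 2 classes")
  stopifnot(n_channels >= 2, epoch_length > 0, sample_rate > 0,
            n_speakers_train >= 1, n_speakers_test >= 1,
            time_warp >= 0, channel_jitter >= 0, amp_noise >= 0,
            mean_input_rate > 0)
  structure(list(n_classes = as.integer(n_classes),
                 n_channels = as.integer(n_channels),
                 epoch_length = epoch_length, sample_rate = sample_rate,
                 n_speakers_train = as.integer(n_speakers_train),
                 n_speakers_test = as.integer(n_speakers_test),
                 time_warp = time_warp, channel_jitter = channel_jitter,
                 amp_noise = amp_noise, mean_input_rate = mean_input_rate),
            class = "digit_ensemble_spec")
}

# Smooth ridge template for one class.  Ridge channel positions are drawn
# from a pool shared by all classes of the ensemble, so the per-channel
# activity marginals are similar across classes and class identity lives
# mainly in the temporal arrangement of the ridges -- the structure a
# spike-count readout of the raw channels cannot fully resolve but
# coincidence-driven learning can.
digit_template <- function(spec, n_ridges, channel_pool) {
  nb <- as.integer(spec$epoch_length / 1000 * spec$sample_rate)
  nc <- spec$n_channels
  m <- matrix(0, nc, nb)
  tgrid <- seq(0, 1, length.out = nb)
  for (r in seq_len(n_ridges)) {
    c0 <- sample(channel_pool, 1)
    t0 <- runif(1, 0.2, 0.8)
    slope <- runif(1, -0.4, 0.4) * nc      # channel drift per unit time
    sc <- runif(1, 0.03, 0.08) * nc        # channel width
    st <- runif(1, 0.05, 0.15)             # time width
    a <- runif(1, 0.7, 1.3)
    centre <- c0 + slope * (tgrid - t0)
    for (b in seq_len(nb)) {
      m[, b] <- m[, b] + a * exp(-((seq_len(nc) - centre[b])^2) / (2 * sc^2) -
                                   (tgrid[b] - t0)^2 / (2 * st^2))
    }
  }
  m
}

warp_time <- function(m, factor) {
  nb <- ncol(m)
  src <- (seq_len(nb) - (nb + 1) / 2) / factor + (nb + 1) / 2
  lo <- pmin(pmax(floor(src), 1), nb)
  hi <- pmin(lo + 1, nb)
  w <- pmin(pmax(src - lo, 0), 1)
  m[, lo, drop = FALSE] * rep(1 - w, each = nrow(m)) +
    m[, hi, drop = FALSE] * rep(w, each = nrow(m))
}

shift_channels <- function(m, k) {
  if (k == 0) return(m)
  nc <- nrow(m)
  out <- matrix(0, nc, ncol(m))
  src <- seq_len(nc) - k
  ok <- src >= 1 & src <= nc
  out[ok, ] <- m[src[ok], ]
  out
}

#' Generate the synthetic labelled intensity ensemble
#'
#' @param spec a \code{\link{digit_ensemble_spec}}
#' @param seed RNG seed; the ensemble is reproducible bit-for-bit from
#'   (spec, seed)
#' @return object of class \code{intensity_ensemble}: a list of utterances,
#'   each with elements \code{intensity} (channels x time, normalized so
#'   every utterance has the same summed activity with unit mean),
#'   \code{label} (1-based class), \code{speaker} and \code{split}
#'   ("train"/"test")
#' @export
synthesize_digit_ensemble <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "digit_ensemble_spec"))
  set.seed(seed)
  n_ridges <- sample(4:6, spec$n_classes, replace = TRUE)
  pool <- round(seq(0.12, 0.88, length.out = 8) * spec$n_channels)
  templates <- lapply(seq_len(spec$n_classes), function(k)
    digit_template(spec, n_ridges[k], pool))
  n_spk <- spec$n_speakers_train + spec$n_speakers_test
  spk_warp <- runif(n_spk, 1 - spec$time_warp, 1 + spec$time_warp)
  spk_jit <- sample(seq(-spec$channel_jitter, spec$channel_jitter),
                    n_spk, replace = TRUE)
  utter <- list()
  for (s in seq_len(n_spk)) {
    split <- if (s <= spec$n_speakers_train) "train" else "test"
    for (k in seq_len(spec$n_classes)) {
      m <- templates[[k]]
      m <- warp_time(m, spk_warp[s])
      m <- shift_channels(m, spk_jit[s])
      if (spec$amp_noise > 0)
        m <- m * matrix(runif(length(m), 1 - spec$amp_noise,
                              1 + spec$amp_noise), nrow(m))
      m <- normalize_utterance(m, target_sum = length(m))
      utter[[length(utter) + 1]] <-
        list(intensity = m, label = k, speaker = s, split = split)
    }
  }
  structure(list(utterances = utter, spec = spec, seed = seed),
            class = "intensity_ensemble")
}

#' @export
print.intensity_ensemble <- function(x, ...) {
  labs <- vapply(x$utterances, `[[`, numeric(1), "label")
  cat(sprintf(
    "intensity_ensemble: %d utterances, %d classes, %d channels x %d bins\n",
    length(x$utterances), length(unique(labs)),
    nrow(x$utterances[[1]]$intensity), ncol(x$utterances[[1]]$intensity)))
  invisible(x)
}

#' Equalize the summed activity of an intensity matrix
#'
#' Scales a non-negative intensity matrix so its total sum equals a common
#' target, making summed activity equal across utterances.  Idempotent and
#' invariant to input scale.
#'
#' @param m non-negative matrix with positive sum
#' @param target_sum the common total (default: one per cell, i.e. unit
#'   mean intensity)
#' @return rescaled matrix
#' @export
normalize_utterance <- function(m, target_sum = length(m)) {
  if (any(m < 0)) stop("intensity must be non-negative")
  s <- sum(m)
  if (s <= 0) stop("cannot normalize an all-zero intensity matrix")
  m * (target_sum / s)
}

#' Encode an intensity ensemble as inhomogeneous Poisson spike trains
#'
#' Per-channel rate proportional to intensity, globally scaled so the grand
#' mean rate across the (normalized) ensemble equals \code{mean_rate}.
#'
#' @param ensemble an \code{intensity_ensemble}
#' @param mean_rate grand-mean firing rate (Hz)
#' @param which "train", "test" or "all"
#' @return list of encoded utterances, each with \code{spikes}
#'   (\code{\link{spike_trains}}), \code{label}, \code{speaker},
#'   \code{split}
#' @export
encode_poisson_ensemble <- function(ensemble,
                                    mean_rate = ensemble$spec$mean_input_rate,
                                    which = "all") {
  stopifnot(inherits(ensemble, "intensity_ensemble"))
  sel <- ensemble$utterances
  if (which != "all")
    sel <- Filter(function(u) u$split == which, sel)
  bin_w <- 1000 / ensemble$spec$sample_rate
  lapply(sel, function(u) {
    rates <- u$intensity / mean(u$intensity) * mean_rate
    list(spikes = poisson_spike_trains(rates, bin_w,
                                       duration = ensemble$spec$epoch_length),
         label = u$label, speaker = u$speaker, split = u$split)
  })
}
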