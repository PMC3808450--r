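#' Feedforward architecture specification and builder
#'
#' Each output neuron receives plastic excitatory synapses from a random
#' half of the input channels (initial conductances uniform on
#' \code{exc_init_range}) and static inhibitory synapses from all channels
#' (uniform on \code{inh_init_range}); all delays uniform on
#' \code{delay_range}.
#'
#' @param n_outputs number of output neurons
#' @param exc_connection_prob probability an input contacts an output with a
#'   plastic excitatory synapse
#' @param exc_init_range,inh_init_range initial weight ranges (nS).  The
#'   inhibitory default keeps the static all-channel inhibition weak enough
#'   that the rate controller can hold the outputs at their set-point by
#'   scaling the plastic excitatory weights within their bounds
#' @param delay_range conduction delay range (ms)
#' @param target_rate homeostatic rate set-point for the outputs (Hz)
#' @return object of class \code{feedforward_spec}
#' @export
feedforward_spec <- function(n_outputs = 20, exc_connection_prob = 0.5,
                             exc_init_range = c(0, 10),
                             inh_init_range = c(0, 4),
                             delay_range = c(0.1, 5), target_rate = 1.5) {
  stopifnot(n_outputs >= 1, exc_connection_prob >= 0,
            exc_connection_prob <= 1, diff(exc_init_range) >= 0,
            diff(inh_init_range) >= 0, diff(delay_range) >= 0,
            target_rate > 0)
  structure(list(n_outputs = as.integer(n_outputs),
                 exc_connection_prob = exc_connection_prob,
                 exc_init_range = exc_init_range,
                 inh_init_range = inh_init_range,
                 delay_range = delay_range, target_rate = target_rate),
            class = "feedforward_spec")
}

#' @rdname feedforward_spec
#' @param spec a \code{feedforward_spec}
#' @param n_inputs number of external input channels
#' @param params a \code{\link{neuron_params}} set
#' @return a \code{\link{spiking_network}} whose first synapse group is the
#'   plastic excitatory feedforward projection
#' @export
build_feedforward <- function(spec, n_inputs, params = neuron_params()) {
  stopifnot(inherits(spec, "feedforward_spec"))
  if (n_inputs < 1) stop("empty input population")
  no <- spec$n_outputs
  src <- integer(0); tgt <- integer(0)
  for (o in seq_len(no)) {
    sel <- which(runif(n_inputs) < spec$exc_connection_prob)
    src <- c(src, sel); tgt <- c(tgt, rep.int(o, length(sel)))
  }
  exc <- synapse_group(src, tgt,
                       weight = runif(length(src), spec$exc_init_range[1],
                                      spec$exc_init_range[2]),
                       delay = runif(length(src), spec$delay_range[1],
                                     spec$delay_range[2]),
                       inh = FALSE, plastic = TRUE, external = TRUE)
  isrc <- rep(seq_len(n_inputs), times = no)
  itgt <- rep(seq_len(no), each = n_inputs)
  inh <- synapse_group(isrc, itgt,
                       weight = runif(length(isrc), spec$inh_init_range[1],
                                      spec$inh_init_range[2]),
                       delay = runif(length(isrc), spec$delay_range[1],
                                     spec$delay_range[2]),
                       inh = TRUE, plastic = FALSE, external = TRUE)
  net <- spiking_network(no, params = params, synapses = list(exc, inh),
                         n_ext = n_inputs)
  net$target_rate <- spec$target_rate
  net
}

#' Build the circular-Gaussian single-neuron task network
#'
#' One output neuron with plastic excitatory synapses from every ring input
#' and static inhibitory synapses from the background population.  Initial
#' weights are Gaussian with standard deviation one third of the mean,
#' truncated at zero.
#'
#' @param spec a \code{\link{circular_ensemble_spec}}
#' @param mean_exc,mean_inh initial mean conductances (nS)
#' @param delay_range conduction delay range (ms)
#' @param params a \code{\link{neuron_params}} set
#' @return a \code{\link{spiking_network}} with one neuron
#' @export
build_gaussian_task <- function(spec, mean_exc = 1, mean_inh = 1,
                                delay_range = c(0.1, 5),
                                params = neuron_params()) {
  stopifnot(inherits(spec, "circular_ensemble_spec"))
  ne <- spec$n_excitatory; ni <- spec$n_inhibitory
  exc <- synapse_group(seq_len(ne), rep(1L, ne),
                       weight = pmax(rnorm(ne, mean_exc, mean_exc / 3), 0),
                       delay = runif(ne, delay_range[1], delay_range[2]),
                       inh = FALSE, plastic = TRUE, external = TRUE)
  groups <- list(exc)
  if (ni > 0) {
    inh <- synapse_group(ne + seq_len(ni), rep(1L, ni),
                         weight = pmax(rnorm(ni, mean_inh, mean_inh / 3), 0),
                         delay = runif(ni, delay_range[1], delay_range[2]),
                         inh = TRUE, plastic = FALSE, external = TRUE)
    groups <- c(groups, list(inh))
  }
  spiking_network(1, params = params, synapses = groups, n_ext = ne + ni)
}

#' Recurrent architecture specification and builder
#'
#' A sheet of neurons (4:1 excitatory:inhibitory) on the unit square with
#' periodic boundaries, uniform sparse recurrent connectivity (no
#' self-connections), Gaussian-initialized weights truncated at zero with
#' standard deviation one third of the mean, per-neuron independent Poisson
#' background drive, and tonotopically organized external input: channel c
#' at torus position (c/n_channels, 0.5) contacts network neurons with
#' probability proportional to a Gaussian of torus distance.
#' Only recurrent excitatory synapses are plastic.
#'
#' @param n_total total neuron count
#' @param ei_ratio excitatory:inhibitory ratio
#' @param connection_prob recurrent connection probability
#' @param mean_exc,mean_inh initial mean recurrent conductances (nS)
#' @param delay_range delay range (ms)
#' @param background_rate per-neuron background Poisson rate (Hz)
#' @param background_weight background synapse conductance (nS)
#' @param tonotopic_sigma width of the input projection profile (torus units)
#' @param input_fraction fraction of network neurons contacted per channel
#' @param target_rate homeostatic set-point used during training (Hz)
#' @return object of class \code{recurrent_spec}
#' @export
recurrent_spec <- function(n_total = 4500, ei_ratio = 4,
                           connection_prob = 0.05, mean_exc = 0.2,
                           mean_inh = 1.2, delay_range = c(0.1, 5),
                           background_rate = 300, background_weight = 1.75,
                           tonotopic_sigma = 0.2, input_fraction = 0.05,
                           target_rate = 1.5) {
  stopifnot(n_total >= 10, ei_ratio > 0, connection_prob > 0,
            connection_prob < 1, mean_exc > 0, mean_inh > 0)
  structure(list(n_total = as.integer(n_total), ei_ratio = ei_ratio,
                 connection_prob = connection_prob, mean_exc = mean_exc,
                 mean_inh = mean_inh, delay_range = delay_range,
                 background_rate = background_rate,
                 background_weight = background_weight,
                 tonotopic_sigma = tonotopic_sigma,
                 input_fraction = input_fraction,
                 target_rate = target_rate),
            class = "recurrent_spec")
}

torus_distance <- function(p, q) {
  d <- abs(sweep(p, 2, q))
  d <- pmin(d, 1 - d)
  sqrt(rowSums(d^2))
}

#' @rdname recurrent_spec
#' @param spec a \code{recurrent_spec}
#' @param n_channels number of external (tonotopic) input channels; 0 for a
#'   spontaneously active network only
#' @param input_weight_mean mean conductance of external input synapses
#'   (nS); defaults to the recurrent excitatory mean
#' @param params a \code{\link{neuron_params}} set
#' @return a \code{\link{spiking_network}} with fields \code{n_exc},
#'   \code{n_inh}, \code{positions} and \code{target_rate}
#' @export
build_recurrent <- function(spec, n_channels = 0,
                            input_weight_mean = spec$mean_exc,
                            params = neuron_params()) {
  stopifnot(inherits(spec, "recurrent_spec"))
  n <- spec$n_total
  n_exc <- as.integer(round(n * spec$ei_ratio / (spec$ei_ratio + 1)))
  n_inh <- n - n_exc
  pos <- cbind(runif(n), runif(n))

  # uniform sparse recurrent connectivity, no self-connections: draw the
  # Bernoulli connection count exactly, then that many distinct ordered
  # pairs from the n(n-1) admissible ones
  m <- rbinom(1, n * (n - 1), spec$connection_prob)
  idx <- sample(n * (n - 1), m)
  src <- (idx - 1L) %/% (n - 1L) + 1L
  off <- (idx - 1L) %% (n - 1L) + 1L
  tgt <- off + (off >= src)
  is_inh_src <- src > n_exc
  w <- ifelse(is_inh_src,
              pmax(rnorm(length(src), spec$mean_inh, spec$mean_inh / 3), 0),
              pmax(rnorm(length(src), spec$mean_exc, spec$mean_exc / 3), 0))
  dl <- runif(length(src), spec$delay_range[1], spec$delay_range[2])
  exc_g <- synapse_group(src[!is_inh_src], tgt[!is_inh_src],
                         w[!is_inh_src], dl[!is_inh_src],
                         inh = FALSE, plastic = TRUE, external = FALSE)
  inh_g <- synapse_group(src[is_inh_src], tgt[is_inh_src],
                         w[is_inh_src], dl[is_inh_src],
                         inh = TRUE, plastic = FALSE, external = FALSE)
  groups <- list(exc_g, inh_g)

  input_locus <- NULL
  if (n_channels > 0) {
    input_locus <- cbind((seq_len(n_channels) - 0.5) / n_channels, 0.5)
    isrc <- integer(0); itgt <- integer(0)
    n_tgt <- max(1L, as.integer(round(spec$input_fraction * n)))
    for (ch in seq_len(n_channels)) {
      d <- torus_distance(pos, input_locus[ch, ])
      pr <- exp(-d^2 / (2 * spec$tonotopic_sigma^2))
      sel <- sample.int(n, n_tgt, prob = pr)
      isrc <- c(isrc, rep.int(ch, n_tgt)); itgt <- c(itgt, sel)
    }
    ing <- synapse_group(isrc, itgt,
                         weight = pmax(rnorm(length(isrc), input_weight_mean,
                                             input_weight_mean / 3), 0),
                         delay = runif(length(isrc), spec$delay_range[1],
                                       spec$delay_range[2]),
                         inh = FALSE, plastic = FALSE, external = TRUE)
    groups <- c(groups, list(ing))
  }

  net <- spiking_network(n, params = params, synapses = groups,
                         n_ext = n_channels, bg_rate = spec$background_rate,
                         bg_weight = spec$background_weight,
                         positions = pos)
  net$n_exc <- n_exc; net$n_inh <- n_inh
  net$target_rate <- spec$target_rate
  net$input_locus <- input_locus
  net
}

scale_recurrent_weights <- function(net, factor_exc, factor_inh = factor_exc) {
  for (i in seq_along(net$synapses)) {
    g <- net$synapses[[i]]
    if (g$external) next
    net$synapses[[i]]$weight <- g$weight *
      (if (g$inh) factor_inh else factor_exc)
  }
  net
}

#' Calibrate the spontaneous asynchronous-irregular state
#'
#' Bisects the mean inhibitory recurrent conductance (excitatory mean held
#' fixed) until the spontaneous population rate of the network, driven only
#' by its Poisson background, falls within tolerance of the target.
#' Reports the firing rate, the mean coefficient of variation of
#' inter-spike intervals and the mean pairwise spike-count correlation of
#' the found state.
#'
#' The inhibitory mean, not a common scale on both means, is the search
#' variable: in the balanced regime the spontaneous rate is nearly
#' invariant to a common rescaling of all recurrent weights (the balance
#' fixed point moves with the ratio of drives, not their magnitude), so
#' only the excitation/inhibition ratio gives a monotone, effective lever.
#'
#' @param spec a \code{\link{recurrent_spec}}; its \code{mean_exc} /
#'   \code{mean_inh} serve as the starting point
#' @param target_rate spontaneous population rate target (Hz)
#' @param tol relative tolerance on the rate
#' @param probe_duration duration of each probe simulation (ms); the first
#'   \code{discard} ms are dropped as transient
#' @param final_duration duration of the final characterization run (ms)
#' @param discard transient to discard (ms)
#' @param max_iter bisection iteration cap
#' @param params a \code{\link{neuron_params}} set
#' @return list with the calibrated \code{mean_exc}, \code{mean_inh}, the
#'   calibrated \code{net}, and the measured \code{rate}, \code{cv_isi},
#'   \code{correlation} of the final probe
#' @export
calibrate_spontaneous_state <- function(spec, target_rate = 1.5, tol = 0.1,
                                        probe_duration = 4000,
                                        final_duration = 10000,
                                        discard = 1000, max_iter = 12,
                                        params = neuron_params()) {
  stopifnot(inherits(spec, "recurrent_spec"), target_rate > 0)
  base <- build_recurrent(spec, n_channels = 0, params = params)

  probe_rate <- function(factor, duration) {
    net <- scale_recurrent_weights(base, 1, factor_inh = factor)
    sim <- simulate_network(net, NULL, duration = duration)
    tt <- unlist(sim$spikes, use.names = FALSE)
    sum(tt > discard) / ((duration - discard) / 1000) / net$n_neurons
  }

  # spontaneous rate decreases monotonically with the inhibitory mean
  lo <- 0.5; hi <- 2
  r_lo <- probe_rate(lo, probe_duration)
  r_hi <- probe_rate(hi, probe_duration)
  it <- 0
  while (r_lo < target_rate && lo > 1e-2 && it < 8) {
    hi <- lo; r_hi <- r_lo
    lo <- lo / 2; r_lo <- probe_rate(lo, probe_duration)
    it <- it + 1
  }
  while (r_hi > target_rate && hi < 64 && it < 16) {
    lo <- hi; r_lo <- r_hi
    hi <- hi * 2; r_hi <- probe_rate(hi, probe_duration)
    it <- it + 1
  }
  if (!(r_lo >= target_rate && r_hi <= target_rate))
    stop(sprintf(
      "calibration failed: rate %.3g Hz at inhibitory factor %.3g, %.3g Hz at %.3g; ",
      r_lo, lo, r_hi, hi),
      "target outside the reachable range")
  factor <- sqrt(lo * hi)
  for (i in seq_len(max_iter)) {
    r <- probe_rate(factor, probe_duration)
    if (abs(r - target_rate) <= tol * target_rate) break
    if (r > target_rate) lo <- factor else hi <- factor
    factor <- sqrt(lo * hi)
  }

  net <- scale_recurrent_weights(base, 1, factor_inh = factor)
  sim <- simulate_network(net, NULL, duration = final_duration)
  trains <- lapply(sim$spikes, function(tt) tt[tt > discard])
  eff <- (final_duration - discard) / 1000
  rate <- sum(lengths(trains)) / eff / net$n_neurons
  cvs <- vapply(trains, function(tt)
    if (length(tt) >= 5) cv_isi(tt) else NA_real_, numeric(1))
  st <- spike_trains(trains, final_duration)
  corr <- pairwise_correlation(st, n_pairs = 500, bin_size = 5,
                               t_min = discard)
  list(mean_exc = spec$mean_exc, mean_inh = spec$mean_inh * factor,
       factor = factor, net = net, rate = rate,
       cv_isi = mean(cvs, na.rm = TRUE), correlation = corr)
}
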