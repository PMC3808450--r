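# In vitro plasticity protocol harness: two-cell (or few-synapse) circuits
# with postsynaptic spikes forced at prescribed times by suprathreshold
# commands, the homeostatic rate constraint turned off, and the weight
# change read out after the protocol plus a tail of silence that lets the
# eligibility decay.

# Run one protocol on a network with a single postsynaptic neuron.
# pre_times: list over external channels of presynaptic spike times (ms,
# global); post_times: forced postsynaptic spike times (ms, global).
run_protocol <- function(net, pre_times, post_times, rule,
                         dt = 0.1, tail_ms = 2000, pattern_length = 1000) {
  stopifnot(inherits(net, "spiking_network"), net$n_neurons == 1)
  T <- pattern_length
  t_max <- max(c(unlist(pre_times), post_times, 0))
  n_pat <- ceiling((t_max + tail_ms) / T)
  plastic_idx <- which(vapply(net$synapses, `[[`, logical(1), "plastic"))
  elig <- lapply(net$synapses[plastic_idx],
                 function(g) numeric(length(g$src)))
  gbar_run <- 0
  cap <- net$params$tau_m * net$params$g_l
  state <- NULL
  need_v <- rule$kind == "convallis"
  n_steps <- as.integer(round(T / dt))

  for (k in seq_len(n_pat)) {
    t0 <- (k - 1) * T
    stim <- spike_trains(lapply(pre_times, function(tt) {
      tt <- tt[tt >= t0 & tt < t0 + T] - t0
      tt[tt >= T] <- T - dt
      tt
    }), T)
    post_rel <- post_times[post_times >= t0 & post_times < t0 + T] - t0
    sim <- simulate_network(net, stim, duration = T, dt = dt,
                            record_v = if (need_v) 1L else integer(0),
                            state = state,
                            forced_spikes = list(post_rel))
    state <- sim$state

    if (need_v) {
      gbar_run <- fold_gbar(gbar_run, sim$gbar[1], T, rule$g_avg_time)
      tau_eff <- cap / (net$params$g_l + gbar_run)
      H <- matrix(gprime(sim$v[, 1], rule$objective), ncol = 1)
      kap <- kappa_backward(H, max(tau_eff, net$params$tau_e),
                            min(tau_eff, net$params$tau_e),
                            rule$tau_p, dt)[, 1]
      decay <- exp(-T / rule$tau_p)
      for (gi in seq_along(plastic_idx)) {
        g <- net$synapses[[plastic_idx[gi]]]
        ar <- group_arrivals(g, stim, sim$spikes, dt, n_steps)
        inc <- numeric(length(g$src))
        if (length(ar$syn)) {
          rs <- rowsum(kap[ar$step + 1L], ar$syn)
          inc[as.integer(rownames(rs))] <- rs[, 1]
        }
        e_rev <- if (g$inh) net$params$e_inh else net$params$e_exc
        elig[[gi]] <- elig[[gi]] * decay +
          rule$gain * (e_rev - net$params$v_rest) * inc
        net$synapses[[plastic_idx[gi]]]$weight <- apply_weight_updates(
          g$weight, elig[[gi]], rule$eta, 1,
          rule$theta_d, rule$theta_p, rule$w_min, rule$w_max)
      }
    } else if (rule$kind %in% c("stdp", "triplet")) {
      post_obs <- sim$spikes[[1]]
      for (gi in seq_along(plastic_idx)) {
        g <- net$synapses[[plastic_idx[gi]]]
        ar <- group_arrivals(g, stim, sim$spikes, dt, n_steps)
        pre_list <- split(ar$step * dt,
                          factor(ar$syn, levels = seq_along(g$src)))
        dw <- if (rule$kind == "stdp") {
          stdp_dw_group(pre_list, post_obs, rule)
        } else {
          rule$lr * vapply(pre_list, triplet_weight_change, numeric(1),
                           post = post_obs, p = rule$params)
        }
        net$synapses[[plastic_idx[gi]]]$weight <-
          pmin(pmax(g$weight + dw, rule$w_min), rule$w_max)
      }
    }
  }
  net
}

# single plastic synapse onto one neuron; delay = one time step
pairing_net <- function(w0 = 2, params = neuron_params(), dt = 0.1) {
  spiking_network(1, params = params, n_ext = 1,
                  synapses = list(synapse_group(1L, 1L, w0, dt,
                                                inh = FALSE, plastic = TRUE,
                                                external = TRUE)))
}

#' Spike-pairing (STDP) protocol
#'
#' Repeated pre/post spike pairings on a two-cell circuit with one plastic
#' connection; postsynaptic spikes are forced at the prescribed times and
#' the rate constraint is off.  \code{dt > 0} means pre before post.
#'
#' @param dts pairing intervals Delta-t (ms)
#' @param n_pairs pairings per interval
#' @param rep_freq pairing repetition frequency (Hz)
#' @param rule plasticity rule object
#' @param w0 initial synaptic strength (nS)
#' @param params \code{\link{neuron_params}}
#' @return data.frame with \code{dt} and the percent weight change
#'   \code{dw_percent} relative to \code{w0}
#' @export
run_pairing_curve <- function(dts = seq(-40, 40, by = 5), n_pairs = 60,
                              rep_freq = 1, rule = convallis_rule(),
                              w0 = 2, params = neuron_params()) {
  out <- vapply(dts, function(d) {
    pre <- 200 + (seq_len(n_pairs) - 1) * 1000 / rep_freq
    post <- pre + d
    net <- pairing_net(w0, params)
    net <- run_protocol(net, list(pre), post, rule)
    100 * (net$synapses[[1]]$weight - w0) / w0
  }, numeric(1))
  data.frame(dt = dts, dw_percent = out)
}

#' Frequency-dependent tetanic stimulation protocol
#'
#' A group of excitatory and inhibitory afferent synapses onto one neuron
#' is stimulated with \code{n_pulses} pulses at each frequency; on each
#' pulse every synapse is active with probability one half.  Reports the
#' mean percent change of the excitatory weights, averaged over seeds.
#'
#' @param frequencies stimulation frequencies (Hz)
#' @param n_pulses pulses per run
#' @param n_seeds independent repetitions
#' @param rule plasticity rule object
#' @param n_exc,n_inh afferent counts
#' @param exc_w,inh_w afferent conductances (nS)
#' @param params \code{\link{neuron_params}}
#' @return data.frame with \code{frequency} and mean \code{dw_percent}
#' @export
run_tetanus <- function(frequencies = c(0.5, 3, 5, 10, 20, 50, 100),
                        n_pulses = 100, n_seeds = 20,
                        rule = convallis_rule(), n_exc = 20, n_inh = 5,
                        exc_w = 1.6, inh_w = 4, params = neuron_params()) {
  dt <- 0.1
  res <- vapply(frequencies, function(f) {
    pulse_t <- 100 + (seq_len(n_pulses) - 1) * 1000 / f
    dws <- vapply(seq_len(n_seeds), function(s) {
      exc <- synapse_group(seq_len(n_exc), rep(1L, n_exc), exc_w, dt,
                           inh = FALSE, plastic = TRUE, external = TRUE)
      inh <- synapse_group(n_exc + seq_len(n_inh), rep(1L, n_inh), inh_w,
                           dt, inh = TRUE, plastic = FALSE, external = TRUE)
      net <- spiking_network(1, params = params, n_ext = n_exc + n_inh,
                             synapses = list(exc, inh))
      pre <- lapply(seq_len(n_exc + n_inh), function(j)
        pulse_t[runif(n_pulses) < 0.5])
      net <- run_protocol(net, pre, numeric(0), rule)
      mean(100 * (net$synapses[[1]]$weight - exc_w) / exc_w)
    }, numeric(1))
    mean(dws)
  }, numeric(1))
  data.frame(frequency = frequencies, dw_percent = res)
}

#' Spike-triplet protocol
#'
#' Repeated pre-post-pre or post-pre-post spike triplets on the two-cell
#' circuit.
#'
#' @param ordering \code{"post_pre_post"} or \code{"pre_post_pre"}
#' @param intervals the two inter-spike intervals (ms)
#' @param n_reps triplet repetitions
#' @param rep_freq repetition frequency (Hz)
#' @param rule plasticity rule object
#' @param w0 initial weight (nS)
#' @param params \code{\link{neuron_params}}
#' @return percent weight change
#' @export
run_triplet <- function(ordering = c("post_pre_post", "pre_post_pre"),
                        intervals = c(5, 5), n_reps = 60, rep_freq = 1,
                        rule = convallis_rule(), w0 = 2,
                        params = neuron_params()) {
  ordering <- match.arg(ordering)
  t0 <- 200 + (seq_len(n_reps) - 1) * 1000 / rep_freq
  if (ordering == "post_pre_post") {
    post <- sort(c(t0, t0 + intervals[1] + intervals[2]))
    pre <- t0 + intervals[1]
  } else {
    pre <- sort(c(t0, t0 + intervals[1] + intervals[2]))
    post <- t0 + intervals[1]
  }
  net <- pairing_net(w0, params)
  net <- run_protocol(net, list(pre), post, rule)
  100 * (net$synapses[[1]]$weight - w0) / w0
}

#' Pairing-repetition-frequency protocol
#'
#' Interdigitated bursts of five pre/post pairings at a given pairing
#' frequency, repeated at a slow rate (0.1 Hz), for both signs of the
#' pairing interval.
#'
#' @param dt_pair pairing interval (ms; positive = pre before post)
#' @param frequencies within-burst pairing frequencies (Hz)
#' @param n_bursts burst repetitions
#' @param burst_len pairings per burst
#' @param rep_freq burst repetition frequency (Hz)
#' @param rule plasticity rule object
#' @param w0 initial weight (nS)
#' @param params \code{\link{neuron_params}}
#' @return data.frame with \code{frequency} and \code{dw_percent}
#' @export
run_pairing_frequency <- function(dt_pair = 10,
                                  frequencies = c(0.1, 1, 10, 20, 40, 50),
                                  n_bursts = 15, burst_len = 5,
                                  rep_freq = 0.1, rule = convallis_rule(),
                                  w0 = 2, params = neuron_params()) {
  out <- vapply(frequencies, function(f) {
    starts <- 200 + (seq_len(n_bursts) - 1) * 1000 / rep_freq
    anchor <- sort(unique(as.vector(outer(starts,
                                          (seq_len(burst_len) - 1) * 1000 / f,
                                          "+"))))
    if (dt_pair >= 0) { pre <- anchor; post <- anchor + dt_pair }
    else { post <- anchor; pre <- anchor - dt_pair }
    net <- pairing_net(w0, params)
    net <- run_protocol(net, list(sort(pre)), sort(post), rule)
    100 * (net$synapses[[1]]$weight - w0) / w0
  }, numeric(1))
  data.frame(frequency = frequencies, dw_percent = out)
}

#' Relate recurrent weights to stimulus preference
#'
#' Groups the existing recurrent excitatory weights of a trained network by
#' whether the pre- and postsynaptic neurons share the same preferred
#' class, and compares the group means (optionally with a permutation test
#' on the difference).
#'
#' @param net a recurrent \code{\link{spiking_network}}
#' @param preference per-neuron preferred class (argmax response)
#' @param n_perm permutations for the p-value (0 to skip)
#' @param normalize \code{"target"} divides each weight by its target
#'   neuron's mean excitatory input weight before comparing.  This cancels
#'   the per-neuron homeostatic scaling factor exactly (which itself
#'   correlates with stimulus preference through the neuron's firing rate)
#'   and isolates the synapse-specific selection the plasticity rule
#'   performs; \code{"none"} compares raw conductances
#' @return list with \code{mean_same}, \code{mean_diff}, group sizes and
#'   optionally \code{p_value}
#' @export
connectivity_tuning_analysis <- function(net, preference, n_perm = 0,
                                         normalize = c("target", "none")) {
  normalize <- match.arg(normalize)
  g <- NULL
  for (gg in net$synapses)
    if (!gg$external && !gg$inh) { g <- gg; break }
  if (is.null(g)) stop("no recurrent excitatory synapses")
  if (normalize == "target") {
    mean_in <- rowsum(g$weight, g$tgt)[, 1] /
      tabulate(g$tgt, nbins = max(g$tgt))[sort(unique(g$tgt))]
    scale_tgt <- rep(1, max(g$tgt))
    scale_tgt[sort(unique(g$tgt))] <- pmax(mean_in, 1e-12)
    g$weight <- g$weight / scale_tgt[g$tgt]
  }
  same <- preference[g$src] == preference[g$tgt]
  if (sum(same) < 10 || sum(!same) < 10)
    stop("fewer than 10 synapse pairs in a preference group")
  res <- list(mean_same = mean(g$weight[same]),
              mean_diff = mean(g$weight[!same]),
              n_same = sum(same), n_diff = sum(!same))
  if (n_perm > 0) {
    obs <- res$mean_same - res$mean_diff
    null <- replicate(n_perm, {
      pp <- sample(preference)
      sm <- pp[g$src] == pp[g$tgt]
      mean(g$weight[sm]) - mean(g$weight[!sm])
    })
    res$p_value <- mean(null >= obs)
  }
  res
}
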