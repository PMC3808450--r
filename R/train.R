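# Pattern-by-pattern training loop shared by all plasticity rules.
#
# The simulation is stopped at the end of every input pattern (default 1 s);
# the rule-specific update is computed from the recorded voltage traces /
# spike trains of that pattern, gated by the homeostatic controller, applied
# with hard weight bounds, and the controller then rescales the plastic
# excitatory inputs.  Eligibility (for the voltage-valley rule) carries
# across patterns with decay exp(-T/tau_p).

# per-synapse presynaptic ARRIVAL steps (emission + delay) within a pattern
group_arrivals <- function(g, stim, sim_spikes, dt, n_steps) {
  if (g$external) {
    src_times <- unclass(stim)[g$src]
    emit_step <- lapply(src_times, function(tt) as.integer(floor(tt / dt + 1e-9)))
  } else {
    src_times <- unclass(sim_spikes)[g$src]
    emit_step <- lapply(src_times, function(tt) as.integer(round(tt / dt)) - 1L)
  }
  nsp <- lengths(emit_step)
  syn <- rep.int(seq_along(g$src), nsp)
  step <- unlist(emit_step, use.names = FALSE) +
    rep.int(as.integer(round(g$delay / dt)), nsp)
  keep <- step >= 0L & step < n_steps
  list(syn = syn[keep], step = step[keep])
}

#' Train a network with a plasticity rule under the rate constraint
#'
#' Runs the pattern-update training loop: each call to \code{stimulus_fn}
#' provides the external spike trains for one pattern, the network is
#' simulated with state carried across patterns, and the chosen rule's
#' weight update is applied at the pattern boundary, gated and stabilized by
#' the per-neuron homeostatic PI controller.
#'
#' @param net a \code{\link{spiking_network}}; groups flagged
#'   \code{plastic} are trained
#' @param stimulus_fn function(pattern index) returning a
#'   \code{\link{spike_trains}} over the external channels (or NULL)
#' @param n_patterns number of training patterns
#' @param rule a plasticity rule object (\code{\link{convallis_rule}},
#'   \code{\link{stdp_rule}}, \code{\link{triplet_rule}} or
#'   \code{\link{rate_only_rule}})
#' @param target_rate homeostatic set-point (Hz); defaults to
#'   \code{net$target_rate}
#' @param rate_constraint logical: run the homeostatic controller?
#' @param controller optionally a pre-built \code{\link{rate_controller}}
#' @param scaling_gain controller scaling gain (ignored if
#'   \code{controller} given)
#' @param pattern_length pattern duration T (ms)
#' @param dt integration step (ms)
#' @param snapshot_every record full plastic weight vectors every k patterns
#'   (NULL: never)
#' @return list with the trained \code{net}, the \code{controller}, the
#'   final per-group \code{eligibility}, a \code{diagnostics} data.frame
#'   (per-pattern mean rate, gate, mean plastic weight), optional weight
#'   \code{snapshots}, and the final simulator \code{state}
#' @export
train_network <- function(net, stimulus_fn, n_patterns, rule,
                          target_rate = net$target_rate,
                          rate_constraint = TRUE, controller = NULL,
                          scaling_gain = 2e-4, pattern_length = 1000,
                          dt = 0.1) {
  stopifnot(inherits(net, "spiking_network"),
            inherits(rule, "plasticity_rule"))
  n <- net$n_neurons
  plastic_idx <- which(vapply(net$synapses, `[[`, logical(1), "plastic"))
  plastic_tgts <- sort(unique(unlist(
    lapply(net$synapses[plastic_idx], `[[`, "tgt"))))
  need_v <- rule$kind == "convallis"
  n_steps <- as.integer(round(pattern_length / dt))

  if (rate_constraint && is.null(controller)) {
    if (is.null(target_rate)) stop("no target rate for the controller")
    controller <- rate_controller(target_rate, n = n,
                                  scaling_gain = scaling_gain)
  }

  elig <- lapply(net$synapses[plastic_idx],
                 function(g) numeric(length(g$src)))
  gbar_run <- numeric(length(plastic_tgts))
  cap <- net$params$tau_m * net$params$g_l
  state <- NULL
  diag_rate <- diag_gate <- diag_w <- numeric(n_patterns)

  for (k in seq_len(n_patterns)) {
    stim <- stimulus_fn(k)
    sim <- simulate_network(net, stim, duration = pattern_length, dt = dt,
                            record_v = if (need_v) plastic_tgts else integer(0),
                            state = state)
    state <- sim$state
    counts <- lengths(sim$spikes)

    gate <- rep(1, n)
    if (rate_constraint) {
      controller <- update_rate_estimate(controller, counts, pattern_length)
      gate <- plasticity_gate(controller)
    }

    if (need_v && length(plastic_tgts)) {
      gbar_run <- fold_gbar(gbar_run, sim$gbar[plastic_tgts],
                            pattern_length, rule$g_avg_time)
      tau_eff <- cap / (net$params$g_l + gbar_run)
      H <- gprime(sim$v, rule$objective)
      if (is.null(dim(H))) H <- matrix(H, ncol = 1)
      kap <- kappa_backward(H, pmax(tau_eff, net$params$tau_e),
                            pmin(tau_eff, net$params$tau_e),
                            rule$tau_p, dt)
      decay <- exp(-pattern_length / rule$tau_p)
      for (gi in seq_along(plastic_idx)) {
        g <- net$synapses[[plastic_idx[gi]]]
        ar <- group_arrivals(g, stim, sim$spikes, dt, n_steps)
        inc <- numeric(length(g$src))
        if (length(ar$syn)) {
          col <- match(g$tgt, plastic_tgts)
          vals <- kap[cbind(ar$step + 1L, col[ar$syn])]
          rs <- rowsum(vals, ar$syn)
          inc[as.integer(rownames(rs))] <- rs[, 1]
        }
        e_rev <- if (g$inh) net$params$e_inh else net$params$e_exc
        elig[[gi]] <- elig[[gi]] * decay +
          rule$gain * (e_rev - net$params$v_rest) * inc
        net$synapses[[plastic_idx[gi]]]$weight <- apply_weight_updates(
          g$weight, elig[[gi]], rule$eta, gate[g$tgt],
          rule$theta_d, rule$theta_p, rule$w_min, rule$w_max)
      }
    } else if (rule$kind %in% c("stdp", "triplet") && length(plastic_idx)) {
      for (gi in seq_along(plastic_idx)) {
        g <- net$synapses[[plastic_idx[gi]]]
        ar <- group_arrivals(g, stim, sim$spikes, dt, n_steps)
        pre_list <- split(ar$step * dt,
                          factor(ar$syn, levels = seq_along(g$src)))
        dw <- numeric(length(g$src))
        for (tg in unique(g$tgt)) {
          post <- sim$spikes[[tg]]
          sel <- which(g$tgt == tg)
          if (rule$kind == "stdp") {
            dw[sel] <- stdp_dw_group(pre_list[sel], post, rule)
          } else {
            dw[sel] <- rule$lr * vapply(pre_list[sel],
                                        triplet_weight_change,
                                        numeric(1), post = post,
                                        p = rule$params)
          }
        }
        w <- g$weight + gate[g$tgt] * dw
        net$synapses[[plastic_idx[gi]]]$weight <-
          pmin(pmax(w, rule$w_min), rule$w_max)
      }
    }

    if (rate_constraint) {
      cs <- controller_step(controller, pattern_length)
      controller <- cs$ctrl
      for (gi in seq_along(plastic_idx)) {
        g <- net$synapses[[plastic_idx[gi]]]
        if (g$inh) next
        w <- g$weight * cs$scale[g$tgt]
        net$synapses[[plastic_idx[gi]]]$weight <-
          pmin(pmax(w, rule$w_min), rule$w_max)
      }
    }

    diag_rate[k] <- mean(counts[plastic_tgts]) / (pattern_length / 1000)
    diag_gate[k] <- mean(gate[plastic_tgts])
    diag_w[k] <- mean(unlist(lapply(net$synapses[plastic_idx],
                                    `[[`, "weight")))
  }

  list(net = net, controller = controller, eligibility = elig,
       diagnostics = data.frame(pattern = seq_len(n_patterns),
                                rate = diag_rate, gate = diag_gate,
                                mean_weight = diag_w),
       state = state)
}

#' Run the circular-Gaussian single-neuron learning task
#'
#' Builds the ring-input network, trains it with the requested rule under a
#' firing-rate constraint, and (optionally) measures the trained neuron:
#' subthreshold skewness, circular tuning index and mean output rate over a
#' measurement phase with plasticity frozen.
#'
#' @param rule plasticity rule object
#' @param spec a \code{\link{circular_ensemble_spec}}
#' @param n_patterns training patterns (1 s each)
#' @param target_rate homeostatic set-point (Hz)
#' @param seed RNG seed
#' @param scaling_gain controller scaling gain
#' @param measure_patterns patterns used for post-training measurement
#'   (0 to skip)
#' @param params \code{\link{neuron_params}}
#' @return list with the trained network, per-pattern \code{diagnostics},
#'   and (if measured) \code{skewness}, \code{tuning}, \code{rate}
#' @export
run_gaussian_task <- function(rule = convallis_rule(),
                              spec = circular_ensemble_spec(),
                              n_patterns = 100, target_rate = 10, seed = 1,
                              scaling_gain = 1e-2, measure_patterns = 10,
                              params = neuron_params()) {
  set.seed(seed)
  net <- build_gaussian_task(spec, params = params)
  net$target_rate <- target_rate
  ne <- spec$n_excitatory; ni <- spec$n_inhibitory
  T <- 1000

  make_stim <- function(k) {
    cg <- circular_gaussian_rates(spec, T)
    exc <- poisson_spike_trains(cg$rates, cg$hold_duration, duration = T)
    inh <- poisson_spike_trains(matrix(spec$inhibitory_rate, ni, 1), T,
                                duration = T)
    st <- spike_trains(c(unclass(exc), unclass(inh)), T)
    attr(st, "centers") <- cg$centers
    st
  }

  fit <- train_network(net, make_stim, n_patterns, rule,
                       scaling_gain = scaling_gain)
  out <- list(net = fit$net, diagnostics = fit$diagnostics,
              controller = fit$controller)

  if (measure_patterns > 0) {
    hold <- spec$hold_duration
    centers_all <- integer(0)
    hold_counts <- integer(0)
    vs <- list(); sp_all <- list()
    state <- fit$state
    for (k in seq_len(measure_patterns)) {
      stim <- make_stim(k)
      sim <- simulate_network(fit$net, stim, duration = T, record_v = 1,
                              state = state)
      state <- sim$state
      spikes <- sim$spikes[[1]]
      hl <- findInterval(spikes, seq(0, T, by = hold),
                         rightmost.closed = TRUE)
      hold_counts <- c(hold_counts,
                       tabulate(hl, nbins = length(attr(stim, "centers"))))
      centers_all <- c(centers_all, attr(stim, "centers"))
      vs[[k]] <- sim$v[, 1]
      sp_all[[k]] <- spikes
    }
    v <- unlist(vs, use.names = FALSE)
    sp <- unlist(lapply(seq_along(sp_all),
                        function(k) sp_all[[k]] + (k - 1) * T))
    out$skewness <- subthreshold_skewness(v, sp, params = params)
    # mean rate per ring position bin (angle), for the tuning index
    nbin <- 20
    pos_bin <- pmin(ceiling(centers_all / ne * nbin), nbin)
    r_theta <- vapply(seq_len(nbin), function(b) {
      sel <- pos_bin == b
      if (!any(sel)) 0 else mean(hold_counts[sel]) / (hold / 1000)
    }, numeric(1))
    out$tuning <- if (sum(r_theta) > 0) tuning_index(r_theta) else 0
    out$rate <- length(sp) / (measure_patterns * T / 1000)
    out$rate_profile <- r_theta
  }
  out
}

#' Train a feedforward population on the synthetic digit ensemble
#'
#' Builds (or reuses) the feedforward architecture, then trains it with
#' repeated passes over freshly Poisson-encoded training utterances in
#' shuffled order.
#'
#' @param rule plasticity rule object
#' @param ensemble an \code{intensity_ensemble}
#' @param ffspec a \code{\link{feedforward_spec}}
#' @param passes presentations of the full training set
#' @param seed RNG seed
#' @param scaling_gain controller scaling gain
#' @param params \code{\link{neuron_params}}
#' @param net optionally a pre-built feedforward network
#' @return as \code{\link{train_network}}, plus the presented labels
#' @export
train_feedforward_digits <- function(rule = convallis_rule(),
                                     ensemble,
                                     ffspec = feedforward_spec(),
                                     passes = 10, seed = 1,
                                     scaling_gain = 1e-2,
                                     params = neuron_params(),
                                     net = NULL) {
  set.seed(seed)
  train_utt <- Filter(function(u) u$split == "train", ensemble$utterances)
  if (is.null(net))
    net <- build_feedforward(ffspec, ensemble$spec$n_channels,
                             params = params)
  bin_w <- 1000 / ensemble$spec$sample_rate
  mr <- ensemble$spec$mean_input_rate
  order_tab <- unlist(lapply(seq_len(passes), function(p)
    sample(seq_along(train_utt))))
  labels <- vapply(train_utt, `[[`, numeric(1), "label")[order_tab]

  make_stim <- function(k) {
    u <- train_utt[[order_tab[k]]]
    rates <- u$intensity / mean(u$intensity) * mr
    poisson_spike_trains(rates, bin_w,
                         duration = ensemble$spec$epoch_length)
  }

  fit <- train_network(net, make_stim, length(order_tab), rule,
                       target_rate = net$target_rate,
                       scaling_gain = scaling_gain,
                       pattern_length = ensemble$spec$epoch_length)
  fit$labels <- labels
  fit
}

#' Train the recurrent network on the synthetic digit ensemble
#'
#' Presents freshly Poisson-encoded training utterances through the
#' tonotopic input channels in shuffled order; only the recurrent
#' excitatory synapses are plastic, with the per-neuron rate constraint at
#' the network's set-point.
#'
#' @param net a recurrent \code{\link{spiking_network}} built with
#'   \code{\link{build_recurrent}} (with \code{n_channels} matching the
#'   ensemble)
#' @param ensemble an \code{intensity_ensemble}
#' @param rule plasticity rule object
#' @param passes presentations of the full training set
#' @param seed RNG seed
#' @param scaling_gain controller scaling gain
#' @return as \code{\link{train_network}}
#' @export
train_recurrent_digits <- function(net, ensemble,
                                   rule = convallis_rule(),
                                   passes = 2, seed = 1,
                                   scaling_gain = 1e-2) {
  set.seed(seed)
  train_utt <- Filter(function(u) u$split == "train", ensemble$utterances)
  bin_w <- 1000 / ensemble$spec$sample_rate
  mr <- ensemble$spec$mean_input_rate
  order_tab <- unlist(lapply(seq_len(passes), function(p)
    sample(seq_along(train_utt))))
  make_stim <- function(k) {
    u <- train_utt[[order_tab[k]]]
    rates <- u$intensity / mean(u$intensity) * mr
    poisson_spike_trains(rates, bin_w,
                         duration = ensemble$spec$epoch_length)
  }
  train_network(net, make_stim, length(order_tab), rule,
                target_rate = net$target_rate,
                scaling_gain = scaling_gain,
                pattern_length = ensemble$spec$epoch_length)
}

#' Characterize network dynamics during stimulus-driven activity
#'
#' Presents a fixed sequence of encoded utterances (state carried across
#' them) and summarizes the population dynamics: mean firing rate across
#' neurons, mean CV-ISI over neurons with at least 5 spikes, and the mean
#' pairwise spike-count correlation.
#'
#' @param net a \code{\link{spiking_network}}
#' @param encoded list of encoded utterances
#' @param n_pairs pairs for the correlation estimate
#' @param bin_size correlation count bin (ms)
#' @return list with \code{rate}, \code{cv_isi}, \code{correlation}
#' @export
characterize_dynamics <- function(net, encoded, n_pairs = 500,
                                  bin_size = 5) {
  state <- NULL
  offs <- 0
  trains <- replicate(net$n_neurons, numeric(0), simplify = FALSE)
  for (u in encoded) {
    dur <- attr(u$spikes, "duration")
    sim <- simulate_network(net, u$spikes, duration = dur, state = state)
    state <- sim$state
    for (i in seq_len(net$n_neurons))
      trains[[i]] <- c(trains[[i]], sim$spikes[[i]] + offs)
    offs <- offs + dur
  }
  st <- spike_trains(trains, offs)
  cvs <- vapply(trains, function(tt)
    if (length(tt) >= 5) cv_isi(tt) else NA_real_, numeric(1))
  list(rate = sum(lengths(trains)) / (offs / 1000) / net$n_neurons,
       cv_isi = mean(cvs, na.rm = TRUE),
       correlation = pairwise_correlation(st, n_pairs = n_pairs,
                                          bin_size = bin_size))
}

#' Preferred stimulus class per neuron
#'
#' @param counts utterances x neurons count matrix
#' @param labels class label per utterance
#' @return integer vector: argmax-response class per neuron
#' @export
preferred_class <- function(counts, labels) {
  means <- rowsum(as.matrix(counts), labels) /
    as.vector(table(labels))
  cls <- as.integer(rownames(means))
  cls[max.col(t(means), ties.method = "first")]
}
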