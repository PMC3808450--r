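#' Parameters of the voltage-valley plasticity rule
#'
#' The rule accumulates, per synapse, the product of the objective gradient
#' evaluated on the postsynaptic voltage and the postsynaptic-potential
#' kernel triggered by presynaptic arrivals, through a slowly decaying
#' exponential (the eligibility \code{P}).  At the end of each input pattern
#' the eligibility is passed through a soft-threshold shrinkage with a dead
#' zone \code{[theta_d, theta_p]} so that isolated coincidences produce no
#' weight change, and the shrunk value is expressed as a weight update
#' scaled by the learning rate and the homeostatic gate.
#'
#' @param eta learning rate (nS per unit of shrunk eligibility)
#' @param tau_p eligibility decay time constant (ms)
#' @param theta_d,theta_p depression and potentiation thresholds of the
#'   shrinkage dead zone (dimensionless, \code{theta_d < 0 < theta_p})
#' @param w_min,w_max hard weight bounds (nS)
#' @param gain dimensionless scale applied to the eligibility increments
#'   (absorbs the kernel amplitude convention); calibrated once against the
#'   in vitro pairing protocol together with \code{eta}
#' @param pattern_length update cadence T (ms): eligibility is expressed and
#'   the homeostatic controller stepped once per pattern
#' @param g_avg_time averaging time for the running mean synaptic
#'   conductance that sets the effective membrane time constant (ms)
#' @param objective an \code{\link{objective_params}} object
#' @return object of class \code{convallis_rule}
#' @export
convallis_rule <- function(eta = 1e-4, tau_p = 1000, theta_d = -10,
                           theta_p = 50, w_min = 0, w_max = 15,
                           gain = 1.25, pattern_length = 1000,
                           g_avg_time = 5000,
                           objective = objective_params()) {
  stopifnot(theta_d < 0, theta_p > 0, w_min < w_max, tau_p > 0, eta >= 0,
            inherits(objective, "objective_params"))
  structure(list(kind = "convallis", eta = eta, tau_p = tau_p,
                 theta_d = theta_d, theta_p = theta_p, w_min = w_min,
                 w_max = w_max, gain = gain,
                 pattern_length = pattern_length, g_avg_time = g_avg_time,
                 objective = objective),
            class = c("convallis_rule", "plasticity_rule"))
}

#' Update the running mean synaptic conductance and effective time constant
#'
#' Folds a total-conductance trace into an exponential running average and
#' recomputes the effective membrane time constant
#' \code{tau_eff = C / (g_l + gbar)}, which shortens as the mean synaptic
#' conductance grows (high-conductance state).
#'
#' @param state list with elements \code{gbar} (nS) and \code{tau_eff} (ms),
#'   or NULL to initialize at \code{gbar = 0}
#' @param g_total numeric vector: total synaptic conductance samples (nS)
#' @param dt sample spacing of \code{g_total} (ms)
#' @param averaging_time time constant of the running average (ms)
#' @param params a \code{\link{neuron_params}} object
#' @return updated state list
#' @export
update_mean_conductance <- function(state, g_total, dt, averaging_time,
                                    params = neuron_params()) {
  if (any(g_total < 0)) stop("g_total must be >= 0")
  gbar <- if (is.null(state)) 0 else state$gbar
  a <- exp(-dt / averaging_time)
  for (g in g_total) gbar <- a * gbar + (1 - a) * g
  cap <- params$tau_m * params$g_l
  list(gbar = gbar, tau_eff = cap / (params$g_l + gbar))
}

# per-pattern fold of the engine's mean conductance into the running average
fold_gbar <- function(gbar, pattern_mean, pattern_length, averaging_time) {
  a <- exp(-pattern_length / averaging_time)
  a * gbar + (1 - a) * pattern_mean
}

#' Eligibility accumulation, direct reference path
#'
#' Computes, by direct summation on the time grid, the end-of-pattern
#' eligibility of each synapse:
#' \deqn{P_j(T) = \gamma (E_j - V_{rest}) \sum_s \Delta t \,
#'   e^{-(T - s)/\tau_p} g'(V(s)) \sum_f \varepsilon(s - t_f)}
#' where \eqn{t_f} are the presynaptic arrival times (emission + delay) of
#' synapse j.  This is the reference semantics for
#' \code{\link{accumulate_eligibility_fast}}; cost O(spikes x steps).
#'
#' @param voltage postsynaptic voltage trace sampled at \code{dt}, covering
#'   one pattern
#' @param arrivals list of numeric vectors: presynaptic arrival times (ms)
#'   per synapse
#' @param e_rev reversal potential per synapse (mV, recycled)
#' @param rule a \code{\link{convallis_rule}}
#' @param params a \code{\link{neuron_params}}
#' @param tau_eff effective membrane time constant (ms); defaults to
#'   \code{tau_m} (no synaptic load)
#' @param dt sample spacing (ms)
#' @return numeric vector of eligibility increments, one per synapse
#' @export
accumulate_eligibility_direct <- function(voltage, arrivals, e_rev,
                                          rule = convallis_rule(),
                                          params = neuron_params(),
                                          tau_eff = params$tau_m,
                                          dt = 0.1) {
  n <- length(voltage)
  T <- n * dt
  e_rev <- rep_len(e_rev, length(arrivals))
  H <- gprime(voltage, rule$objective)
  wp <- exp(-((n - 1) - (seq_len(n) - 1)) * dt / rule$tau_p)
  grid <- (seq_len(n) - 1) * dt
  out <- numeric(length(arrivals))
  for (j in seq_along(arrivals)) {
    acc <- 0
    for (tf in arrivals[[j]]) {
      if (tf < 0 || tf > T) stop("arrival time outside the voltage trace")
      # arrivals are binned to the clock grid, as in the simulator
      tfb <- floor(tf / dt + 1e-9) * dt
      acc <- acc + sum(dt * wp * H *
                         epsp_kernel(grid - tfb, params$tau_e, tau_eff))
    }
    out[j] <- rule$gain * (e_rev[j] - params$v_rest) * acc
  }
  out
}

#' Eligibility accumulation, fast backward-in-time path
#'
#' Computes the same quantity as
#' \code{\link{accumulate_eligibility_direct}} via a per-neuron lookup table
#' kappa(t) obtained from two backward first-order recursions over the
#' voltage trace (one per exponential of the kernel, composed with the
#' eligibility accumulator), so the cost is O(steps + total spikes) instead
#' of O(synapses x steps).  Valid as long as the kernel support is short
#' compared to the pattern length.
#'
#' @inheritParams accumulate_eligibility_direct
#' @return numeric vector of eligibility increments, one per synapse
#' @export
accumulate_eligibility_fast <- function(voltage, arrivals, e_rev,
                                        rule = convallis_rule(),
                                        params = neuron_params(),
                                        tau_eff = params$tau_m,
                                        dt = 0.1) {
  n <- length(voltage)
  T <- n * dt
  e_rev <- rep_len(e_rev, length(arrivals))
  if (3 * max(params$tau_e, tau_eff) > rule$tau_p)
    warning("EPSP kernel support is not short relative to tau_p; ",
            "the backward-pass truncation may be inaccurate")
  H <- matrix(gprime(voltage, rule$objective), ncol = 1)
  kap <- kappa_backward(H, max(params$tau_e, tau_eff),
                        min(params$tau_e, tau_eff), rule$tau_p, dt)[, 1]
  out <- numeric(length(arrivals))
  for (j in seq_along(arrivals)) {
    tf <- arrivals[[j]]
    if (length(tf)) {
      if (any(tf < 0 | tf > T)) stop("arrival time outside the voltage trace")
      steps <- pmin(as.integer(floor(tf / dt + 1e-9)) + 1L, n)
      out[j] <- rule$gain * (e_rev[j] - params$v_rest) * sum(kap[steps])
    }
  }
  out
}

#' Shrinkage: soft-threshold with a dead zone
#'
#' Maps accumulated eligibility inside \code{[theta_d, theta_p]} to zero and
#' shifts values outside towards zero by the corresponding threshold, so
#' that only repeated, reliable pre/post coincidences are expressed as
#' weight changes.  Continuous, monotone non-decreasing, 1-Lipschitz.
#'
#' @param p eligibility values (vectorized)
#' @param theta_d,theta_p dead-zone bounds (\code{theta_d < 0 < theta_p})
#' @return shrunk values
#' @export
shrink <- function(p, theta_d = -10, theta_p = 50) {
  stopifnot(theta_d < 0, theta_p > 0)
  ifelse(p > theta_p, p - theta_p, ifelse(p < theta_d, p - theta_d, 0))
}

#' Apply gated, shrunk eligibility as clipped weight updates
#'
#' \code{w <- clip(w + eta * gate * shrink(P), w_min, w_max)}; only synapses
#' flagged plastic change.
#'
#' @param weights current weights (nS)
#' @param eligibility per-synapse eligibility P
#' @param eta learning rate (nS per unit shrunk eligibility)
#' @param gate homeostatic gate in [0, 1] (scalar or per synapse)
#' @param theta_d,theta_p shrinkage dead zone
#' @param w_min,w_max hard bounds (nS)
#' @param plastic logical mask (recycled)
#' @return updated weights
#' @export
apply_weight_updates <- function(weights, eligibility, eta, gate = 1,
                                 theta_d = -10, theta_p = 50,
                                 w_min = 0, w_max = 15, plastic = TRUE) {
  stopifnot(all(gate >= 0 & gate <= 1), w_min < w_max)
  plastic <- rep_len(plastic, length(weights))
  upd <- weights + eta * gate * shrink(eligibility, theta_d, theta_p)
  upd <- pmin(pmax(upd, w_min), w_max)
  ifelse(plastic, upd, weights)
}
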