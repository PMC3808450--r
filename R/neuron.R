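#' Membrane and synapse parameters for the conductance-based neuron model
#'
#' Defines the leaky integrate-and-fire neuron used throughout the package:
#' conductance-based synapses with instantaneous rise and exponential decay,
#' a "soft" reset in which the voltage is set to a spike peak after threshold
#' crossing and decays linearly to a reset value over the refractory period,
#' followed by an exponentially decaying after-depolarizing (ADP) current.
#' The high reset value plus ADP mimic the post-spike behaviour of cortical
#' pyramidal cells, which do not return to rest after an action potential.
#'
#' Membrane capacitance is implied: \code{C = tau_m * g_l} (pF).
#'
#' @param tau_m membrane time constant (ms)
#' @param g_l leak conductance (nS); the default corresponds to an input
#'   resistance of roughly 300 MOhm, typical of juvenile cortical cells
#' @param v_rest resting potential (mV)
#' @param v_thr spike threshold (mV)
#' @param v_peak voltage imposed at threshold crossing (mV)
#' @param v_reset value reached at the end of the linear spike ramp (mV)
#' @param tau_ref refractory period / spike-shape duration (ms)
#' @param adp_amp initial magnitude of the after-depolarizing current (pA)
#' @param tau_adp ADP decay time constant (ms)
#' @param tau_e,tau_i excitatory / inhibitory synaptic decay constants (ms)
#' @param e_exc,e_inh synaptic reversal potentials (mV)
#' @return an object of class \code{neuron_params}
#' @export
neuron_params <- function(tau_m = 20, g_l = 10, v_rest = -70, v_thr = -50,
                          v_peak = 20, v_reset = -55, tau_ref = 3,
                          adp_amp = 50, tau_adp = 20, tau_e = 5, tau_i = 10,
                          e_exc = 0, e_inh = -80) {
  p <- list(tau_m = tau_m, g_l = g_l, v_rest = v_rest, v_thr = v_thr,
            v_peak = v_peak, v_reset = v_reset, tau_ref = tau_ref,
            adp_amp = adp_amp, tau_adp = tau_adp, tau_e = tau_e,
            tau_i = tau_i, e_exc = e_exc, e_inh = e_inh)
  tcs <- c(tau_m, tau_ref, tau_adp, tau_e, tau_i)
  if (any(!is.finite(unlist(p)))) stop("neuron parameters must be finite")
  if (any(tcs <= 0)) stop("time constants and refractory period must be > 0")
  if (g_l <= 0) stop("leak conductance must be > 0")
  if (adp_amp < 0) stop("adp_amp must be >= 0")
  if (!(v_rest < v_reset && v_reset < v_thr && v_thr < v_peak))
    stop("require v_rest < v_reset < v_thr < v_peak")
  structure(p, class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("Conductance-based LIF neuron parameters\n")
  cat(sprintf("  tau_m %.3g ms, g_l %.3g nS (C = %.3g pF), V_rest %.4g mV\n",
              x$tau_m, x$g_l, x$tau_m * x$g_l, x$v_rest))
  cat(sprintf("  threshold %.4g mV, spike peak %.4g mV, reset %.4g mV over %.3g ms\n",
              x$v_thr, x$v_peak, x$v_reset, x$tau_ref))
  cat(sprintf("  ADP %.3g pA (tau %.3g ms); tau_e %.3g ms, tau_i %.3g ms; E_exc %.4g, E_inh %.4g mV\n",
              x$adp_amp, x$tau_adp, x$tau_e, x$tau_i, x$e_exc, x$e_inh))
  invisible(x)
}

#' Connection list between two neuron populations
#'
#' A group of synapses sharing a reversal class and plasticity flag.
#' Weights are non-negative conductances; the sign of the synaptic effect is
#' carried by the reversal potential of the class. \code{external = TRUE}
#' marks groups whose sources are stimulus channels rather than simulated
#' neurons.
#'
#' @param src,tgt 1-based source and target indices (equal length)
#' @param weight synaptic conductances (nS, non-negative)
#' @param delay conduction delays (ms)
#' @param inh logical: inhibitory reversal class?
#' @param plastic logical: subject to activity-dependent plasticity?
#' @param external logical: sources are external stimulus channels?
#' @return object of class \code{synapse_group}
#' @export
synapse_group <- function(src, tgt, weight, delay, inh = FALSE,
                          plastic = FALSE, external = FALSE) {
  m <- length(src)
  tgt <- rep_len(tgt, m)
  weight <- rep_len(weight, m); delay <- rep_len(delay, m)
  if (m > 0 && any(weight < 0)) stop("synaptic weights must be >= 0")
  if (m > 0 && any(delay < 0)) stop("delays must be >= 0")
  structure(list(src = as.integer(src), tgt = as.integer(tgt),
                 weight = as.numeric(weight), delay = as.numeric(delay),
                 inh = isTRUE(inh), plastic = isTRUE(plastic),
                 external = isTRUE(external)),
            class = "synapse_group")
}

#' Per-neuron ordered spike times
#'
#' The universal currency between stimulus generators, the simulator and the
#' analysis metrics: a list with one strictly increasing numeric vector of
#' spike times (ms) per neuron/channel, with a recorded duration.
#'
#' @param times list of numeric vectors (ms)
#' @param duration total duration (ms); spikes must lie in [0, duration]
#' @return object of class \code{spike_trains}
#' @export
spike_trains <- function(times, duration) {
  stopifnot(is.list(times), is.numeric(duration), duration >= 0)
  for (i in seq_along(times)) {
    tt <- times[[i]]
    if (length(tt) == 0) { times[[i]] <- numeric(0); next }
    if (any(!is.finite(tt))) stop("spike times must be finite")
    if (any(diff(tt) <= 0))
      stop(sprintf("spike times must be strictly increasing (train %d)", i))
    if (tt[1] < 0 || tt[length(tt)] > duration)
      stop(sprintf("spike times outside [0, duration] (train %d)", i))
    times[[i]] <- as.numeric(tt)
  }
  structure(times, duration = duration, class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  n <- length(x)
  ns <- sum(lengths(x))
  cat(sprintf("spike_trains: %d trains, %d spikes over %.4g ms\n",
              n, ns, attr(x, "duration")))
  invisible(x)
}

#' Total spike counts per train
#' @param x a \code{spike_trains} object
#' @return integer vector of counts
#' @export
spike_counts <- function(x) {
  stopifnot(inherits(x, "spike_trains"))
  lengths(x)
}
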