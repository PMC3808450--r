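#' Homeostatic firing-rate controller
#'
#' Per-neuron proportional-integral (PI) controller that holds the long-run
#' firing rate at a target value by multiplicative scaling of the neuron's
#' plastic excitatory input weights, and gates activity-dependent plasticity
#' off while the rate constraint is violated (projection onto the
#' constraint, rather than a penalty term).
#'
#' The rate estimate is an exponential running average of the instantaneous
#' rate with time constant \code{t_rate}.  With error \code{e = rate - target}
#' and integral \code{I}, each controller step multiplies the excitatory
#' weights by \code{1 - scaling_gain * (e + gamma * I) * dt}, floored at
#' \code{mult_floor}, and the plasticity gate is
#' \code{exp(-e^2 / (2 se^2) - I^2 / (2 sI^2))}: equal to 1 only when both
#' the error and its integral are zero.
#'
#' @param target_rate target firing rate r0 (Hz), scalar or per neuron
#' @param n number of controlled neurons
#' @param t_rate time constant of the rate running average (ms)
#' @param gamma weight of the integral term (dimensionless)
#' @param gate_width_e gate width in the error (Hz); default
#'   \code{0.2 * target + 0.3}.  The additive floor keeps the intrinsic
#'   Poisson noise of the rate estimate (sd about \code{sqrt(r/2T)} Hz) from
#'   closing the gate at low set-points
#' @param gate_width_i gate width in the integral (Hz s); default
#'   \code{2 * gate_width_e * t_rate} (t_rate in seconds)
#' @param scaling_gain multiplicative scaling gain (per Hz per s)
#' @param mult_floor lower bound of a single scale multiplier
#' @param i_clamp anti-windup clamp on the integral (Hz s); default two gate
#'   widths, so a long silent or saturated transient can neither wind the
#'   controller up nor hold the gate shut after the rate recovers
#' @return object of class \code{rate_controller}
#' @export
rate_controller <- function(target_rate, n = 1, t_rate = 10000, gamma = 0.01,
                            gate_width_e = 0.2 * target_rate + 0.3,
                            gate_width_i = 2 * gate_width_e * t_rate / 1000,
                            scaling_gain = 2e-4, mult_floor = 0.1,
                            i_clamp = 2 * gate_width_i) {
  stopifnot(all(target_rate > 0), all(gate_width_e > 0),
            all(gate_width_i > 0), t_rate > 0)
  structure(list(target = rep_len(target_rate, n),
                 rate_estimate = rep_len(target_rate, n),
                 integral = rep_len(0, n),
                 n = n, t_rate = t_rate, gamma = gamma,
                 gate_width_e = rep_len(gate_width_e, n),
                 gate_width_i = rep_len(gate_width_i, n),
                 scaling_gain = scaling_gain, mult_floor = mult_floor,
                 i_clamp = rep_len(i_clamp, n)),
            class = "rate_controller")
}

#' Update the running firing-rate estimate
#'
#' @param ctrl a \code{\link{rate_controller}}
#' @param spike_count spikes observed in the window, per neuron
#' @param dt window length (ms)
#' @return updated controller
#' @export
update_rate_estimate <- function(ctrl, spike_count, dt) {
  stopifnot(inherits(ctrl, "rate_controller"), dt > 0)
  a <- exp(-dt / ctrl$t_rate)
  inst <- rep_len(spike_count, ctrl$n) / (dt / 1000)
  ctrl$rate_estimate <- a * ctrl$rate_estimate + (1 - a) * inst
  ctrl
}

#' One PI controller step
#'
#' Advances the integral term and returns the multiplicative scale factor to
#' apply to each neuron's plastic excitatory input weights over this window.
#'
#' @param ctrl a \code{\link{rate_controller}}
#' @param dt window length (ms)
#' @return list with \code{scale} (per-neuron multiplier) and \code{ctrl}
#' @export
controller_step <- function(ctrl, dt) {
  stopifnot(inherits(ctrl, "rate_controller"))
  e <- ctrl$rate_estimate - ctrl$target
  ctrl$integral <- pmin(pmax(ctrl$integral + e * dt / 1000, -ctrl$i_clamp),
                        ctrl$i_clamp)
  u <- e + ctrl$gamma * ctrl$integral
  scale <- pmax(1 - ctrl$scaling_gain * u * dt / 1000, ctrl$mult_floor)
  list(scale = scale, ctrl = ctrl)
}

#' Homeostatic plasticity gate
#'
#' @param ctrl a \code{\link{rate_controller}}
#' @return per-neuron gate in (0, 1]; 1 iff both the rate error and its
#'   integral are zero
#' @export
plasticity_gate <- function(ctrl) {
  stopifnot(inherits(ctrl, "rate_controller"))
  e <- ctrl$rate_estimate - ctrl$target
  exp(-e^2 / (2 * ctrl$gate_width_e^2) -
        ctrl$integral^2 / (2 * ctrl$gate_width_i^2))
}
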