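#' Parameters of the valley-shaped voltage objective
#'
#' The plasticity rule performs gradient ascent on an objective of the
#' subthreshold membrane potential that rewards time spent near rest or near
#' spike threshold and penalizes intermediate depolarizations.  Its
#' derivative is a difference of two non-negative sigmoids,
#' \deqn{g'(V) = \mathrm{logistic}((V - V_1)/\sigma_1) -
#'   c \, \mathrm{logistic}((V - V_0)/\sigma_0),}
#' so that the objective itself is a difference of scaled softplus terms.
#' The low-threshold component (half-activation \code{v0}) drives
#' depression, the high-threshold component (\code{v1}) potentiation.
#'
#' @param v0 half-activation voltage of the depression component (mV)
#' @param v1 half-activation voltage of the potentiation component (mV)
#' @param sigma0,sigma1 slopes of the two components (mV)
#' @param ltd_weight relative amplitude c of the depression component.  Must
#'   keep the valley: too small and no voltage range is penalized, too large
#'   and near-threshold potentials are no longer rewarded more than rest.
#'   The default was calibrated once so the spike-pairing protocol yields
#'   depression at -10 ms and potentiation at +10 ms.
#' @return object of class \code{objective_params}
#' @export
objective_params <- function(v0 = -55, v1 = -52, sigma0 = 4, sigma1 = 2,
                             ltd_weight = 0.32) {
  stopifnot(sigma0 > 0, sigma1 > 0, v0 < v1, ltd_weight > 0)
  structure(list(v0 = v0, v1 = v1, sigma0 = sigma0, sigma1 = sigma1,
                 ltd_weight = ltd_weight),
            class = "objective_params")
}

logistic <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' Voltage objective g(V)
#'
#' @param v membrane potential (mV), vectorized
#' @param p an \code{\link{objective_params}} object
#' @return objective values (dimensionless)
#' @export
objective_g <- function(v, p = objective_params()) {
  p$sigma1 * softplus((v - p$v1) / p$sigma1) -
    p$ltd_weight * p$sigma0 * softplus((v - p$v0) / p$sigma0)
}

#' Analytic derivative g'(V) of the voltage objective
#'
#' Positive near spike threshold (potentiation drive), negative at
#' intermediate depolarization (depression drive), close to zero at rest.
#'
#' @inheritParams objective_g
#' @return derivative values (dimensionless per mV)
#' @export
gprime <- function(v, p = objective_params()) {
  logistic((v - p$v1) / p$sigma1) -
    p$ltd_weight * logistic((v - p$v0) / p$sigma0)
}

#' Decompose g' into potentiation and depression coincidence detectors
#'
#' Returns the two non-negative, monotonically non-decreasing sigmoids whose
#' difference is exactly \code{\link{gprime}}: a high-threshold component
#' (NMDA-like potentiation detector) and a low-threshold component
#' (T-type/mGluR-like depression detector).
#'
#' @param p an \code{\link{objective_params}} object
#' @return list with functions \code{phi_plus} and \code{phi_minus} and
#'   their half-activation voltages \code{v_half_plus}, \code{v_half_minus}
#' @export
decompose_gprime <- function(p = objective_params()) {
  force(p)
  list(phi_plus = function(v) logistic((v - p$v1) / p$sigma1),
       phi_minus = function(v) p$ltd_weight * logistic((v - p$v0) / p$sigma0),
       v_half_plus = p$v1, v_half_minus = p$v0)
}

#' Postsynaptic-potential kernel
#'
#' Causal, peak-normalized shape of the membrane response to a unitary
#' conductance event: a difference of decaying exponentials with rise
#' governed by the faster and decay by the slower of the synaptic and
#' effective membrane time constants.  In the equal-constant limit the
#' alpha function \eqn{(t/\tau) e^{1 - t/\tau}} is used.
#'
#' @param t time since the presynaptic arrival (ms), vectorized; the kernel
#'   is zero for t < 0
#' @param tau_syn synaptic decay constant (ms)
#' @param tau_eff effective membrane time constant (ms)
#' @return kernel values in [0, 1]
#' @export
epsp_kernel <- function(t, tau_syn, tau_eff) {
  stopifnot(tau_syn > 0, tau_eff > 0)
  out <- numeric(length(t))
  pos <- t >= 0
  if (abs(tau_syn - tau_eff) <= 1e-9 * tau_syn) {
    tau <- tau_syn
    out[pos] <- (t[pos] / tau) * exp(1 - t[pos] / tau)
  } else {
    ts <- max(tau_syn, tau_eff); tf <- min(tau_syn, tau_eff)
    tstar <- log(ts / tf) / (1 / tf - 1 / ts)
    peak <- exp(-tstar / ts) - exp(-tstar / tf)
    out[pos] <- (exp(-t[pos] / ts) - exp(-t[pos] / tf)) / peak
  }
  out
}

#' Time of the kernel peak
#' @inheritParams epsp_kernel
#' @return peak time (ms)
#' @export
epsp_kernel_peak_time <- function(tau_syn, tau_eff) {
  if (abs(tau_syn - tau_eff) <= 1e-9 * tau_syn) return(tau_syn)
  ts <- max(tau_syn, tau_eff); tf <- min(tau_syn, tau_eff)
  log(ts / tf) / (1 / tf - 1 / ts)
}
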