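#' Baseline spike-timing-dependent plasticity rules
#'
#' Comparison rules sharing the per-pattern update contract of the main
#' voltage-valley rule, each composable with the homeostatic rate
#' controller: classical additive all-to-all STDP (rcSTDP when combined with
#' the rate constraint), nearest-neighbour STDP, and the pair+triplet trace
#' rule with the published visual-cortex parameter fit.
#'
#' @param a_plus,a_minus potentiation / depression amplitudes (nS)
#' @param tau_plus,tau_minus exponential window time constants (ms)
#' @param mode \code{"all_to_all"} or \code{"nearest_neighbour"}
#' @param w_min,w_max hard weight bounds (nS)
#' @return a plasticity-rule object usable with \code{\link{train_network}}
#' @export
stdp_rule <- function(a_plus = 0.02, a_minus = 0.024, tau_plus = 20,
                      tau_minus = 20, mode = c("all_to_all",
                                               "nearest_neighbour"),
                      w_min = 0, w_max = 15) {
  mode <- match.arg(mode)
  stopifnot(tau_plus > 0, tau_minus > 0, w_min < w_max)
  structure(list(kind = "stdp", a_plus = a_plus, a_minus = a_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus, mode = mode,
                 w_min = w_min, w_max = w_max),
            class = c("stdp_rule", "plasticity_rule"))
}

#' @rdname stdp_rule
#' @param params a \code{\link{triplet_params}} set
#' @param lr overall learning-rate multiplier applied to the published
#'   amplitudes
#' @export
triplet_rule <- function(params = triplet_params_visual_cortex(), lr = 1,
                         w_min = 0, w_max = 15) {
  stopifnot(inherits(params, "triplet_params"), w_min < w_max)
  structure(list(kind = "triplet", params = params, lr = lr,
                 w_min = w_min, w_max = w_max),
            class = c("triplet_rule", "plasticity_rule"))
}

#' @rdname stdp_rule
#' @export
rate_only_rule <- function(w_min = 0, w_max = 15) {
  structure(list(kind = "none", w_min = w_min, w_max = w_max),
            class = c("rate_only_rule", "plasticity_rule"))
}

#' Pair + triplet trace rule parameters
#'
#' Amplitudes and time constants of the pair and triplet terms.  The
#' \code{triplet_params_visual_cortex()} preset is the published all-to-all
#' fit to visual-cortex pairing-frequency data; the pair-potentiation
#' amplitude of that fit is essentially zero, potentiation being carried by
#' the triplet term.
#'
#' @param a2_plus,a2_minus pair term amplitudes
#' @param a3_plus,a3_minus triplet term amplitudes
#' @param tau_plus,tau_minus pair trace time constants (ms)
#' @param tau_x,tau_y triplet (doublet) trace time constants (ms)
#' @return object of class \code{triplet_params}
#' @export
triplet_params <- function(a2_plus, a2_minus, a3_plus, a3_minus,
                           tau_plus = 16.8, tau_minus = 33.7,
                           tau_x = 101, tau_y = 125) {
  stopifnot(tau_plus > 0, tau_minus > 0, tau_x > 0, tau_y > 0)
  structure(list(a2_plus = a2_plus, a2_minus = a2_minus,
                 a3_plus = a3_plus, a3_minus = a3_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus,
                 tau_x = tau_x, tau_y = tau_y),
            class = "triplet_params")
}

#' @rdname triplet_params
#' @export
triplet_params_visual_cortex <- function() {
  triplet_params(a2_plus = 5e-10, a2_minus = 7e-3,
                 a3_plus = 6.2e-3, a3_minus = 2.3e-4,
                 tau_plus = 16.8, tau_minus = 33.7,
                 tau_x = 101, tau_y = 125)
}

#' Weight change from additive exponential-window STDP
#'
#' All-to-all mode sums an exponential kernel over every pre/post spike
#' pair; nearest-neighbour mode restricts each presynaptic spike to its
#' nearest postsynaptic neighbour on each side.  Returns the raw change
#' before any clipping or homeostatic gating.
#'
#' @param pre,post sorted spike time vectors (ms)
#' @param p an \code{\link{stdp_rule}} object (its amplitudes, windows and
#'   mode are used)
#' @return weight change (nS)
#' @export
stdp_weight_change <- function(pre, post, p = stdp_rule()) {
  if (length(pre) == 0 || length(post) == 0) return(0)
  if (is.unsorted(pre) || is.unsorted(post)) stop("spike times must be sorted")
  if (p$mode == "all_to_all") {
    d <- outer(post, pre, "-")   # >0: pre before post
    pos <- d > 0
    sum(p$a_plus * exp(-d[pos] / p$tau_plus)) -
      sum(p$a_minus * exp(d[!pos & d != 0] / p$tau_minus))
  } else {
    dw <- 0
    for (tp in pre) {
      after <- post[post > tp]
      before <- post[post < tp]
      if (length(after))
        dw <- dw + p$a_plus * exp(-(after[1] - tp) / p$tau_plus)
      if (length(before))
        dw <- dw - p$a_minus * exp(-(tp - before[length(before)]) / p$tau_minus)
    }
    dw
  }
}

#' Weight change from the pair + triplet trace rule
#'
#' Event-based evaluation of the all-to-all pair+triplet interaction: at
#' each presynaptic spike the weight is depressed by
#' \code{o1 (A2m + A3m r2)} and at each postsynaptic spike potentiated by
#' \code{r1 (A2p + A3p o2)}, where r1/r2 (presynaptic) and o1/o2
#' (postsynaptic) are exponentially decaying spike traces and the doublet
#' traces r2/o2 are read out just before their own update.  Coincident
#' pre/post spikes process the presynaptic event first.  With zero triplet
#' amplitudes the rule reduces to all-to-all pair STDP.
#'
#' @param pre,post sorted spike time vectors (ms)
#' @param p a \code{\link{triplet_params}} set
#' @return weight change (same units as the amplitudes)
#' @export
triplet_weight_change <- function(pre, post, p = triplet_params_visual_cortex()) {
  if (length(pre) == 0 && length(post) == 0) return(0)
  ev_t <- c(pre, post)
  ev_is_pre <- c(rep(TRUE, length(pre)), rep(FALSE, length(post)))
  o <- order(ev_t, !ev_is_pre)   # ties: pre first
  ev_t <- ev_t[o]; ev_is_pre <- ev_is_pre[o]
  r1 <- r2 <- o1 <- o2 <- 0
  t_last <- ev_t[1]
  dw <- 0
  for (k in seq_along(ev_t)) {
    dt_ev <- ev_t[k] - t_last
    if (dt_ev > 0) {
      r1 <- r1 * exp(-dt_ev / p$tau_plus)
      r2 <- r2 * exp(-dt_ev / p$tau_x)
      o1 <- o1 * exp(-dt_ev / p$tau_minus)
      o2 <- o2 * exp(-dt_ev / p$tau_y)
      t_last <- ev_t[k]
    }
    if (ev_is_pre[k]) {
      dw <- dw - o1 * (p$a2_minus + p$a3_minus * r2)
      r1 <- r1 + 1; r2 <- r2 + 1
    } else {
      dw <- dw + r1 * (p$a2_plus + p$a3_plus * o2)
      o1 <- o1 + 1; o2 <- o2 + 1
    }
  }
  dw
}

# Vectorized per-pattern STDP updates for all synapses converging on the
# same postsynaptic neuron (shared post train), used by the training loop.
# pre_list: list of arrival-time vectors, one per synapse.
stdp_dw_group <- function(pre_list, post, p) {
  if (length(post) == 0 || length(pre_list) == 0)
    return(numeric(length(pre_list)))
  if (p$mode == "nearest_neighbour" || length(post) > 400) {
    return(vapply(pre_list, stdp_weight_change, numeric(1), post = post, p = p))
  }
  npre <- lengths(pre_list)
  if (sum(npre) == 0) return(numeric(length(pre_list)))
  syn <- rep.int(seq_along(pre_list), npre)
  tp <- unlist(pre_list, use.names = FALSE)
  post <- sort(post)
  # suffix/prefix exponential sums over the shared post train
  sfx <- rev(cumsum(rev(exp(-post / p$tau_plus))))
  pfx <- cumsum(exp(post / p$tau_minus))
  idx_after <- findInterval(tp, post) + 1L       # first post strictly later
  idx_before <- findInterval(tp - 1e-12, post)   # last post strictly earlier
  s_plus <- ifelse(idx_after <= length(post),
                   exp(tp / p$tau_plus) * sfx[pmin(idx_after, length(post))], 0)
  s_minus <- ifelse(idx_before >= 1,
                    exp(-tp / p$tau_minus) * pfx[pmax(idx_before, 1L)], 0)
  contrib <- p$a_plus * s_plus - p$a_minus * s_minus
  agg <- numeric(length(pre_list))
  rs <- rowsum(contrib, syn)
  agg[as.integer(rownames(rs))] <- rs[, 1]
  agg
}

#' Grid search calibrating the rcSTDP rule
#'
#' Replicates the calibration procedure for the rate-constrained STDP
#' baseline: a grid over the STDP learning rate and the homeostatic scaling
#' gain, scored by the final skewness of the subthreshold membrane-potential
#' distribution on the circular-Gaussian task (higher is better).
#'
#' @param a_plus_grid candidate potentiation amplitudes (nS)
#' @param scaling_gain_grid candidate controller scaling gains
#' @param n_patterns training patterns per cell of the grid
#' @param spec a \code{\link{circular_ensemble_spec}} (reduced sizes make
#'   the search affordable)
#' @param seed RNG seed
#' @return data.frame with one row per grid cell and a \code{skewness}
#'   score; the best row first
#' @export
stdp_grid_search <- function(a_plus_grid = c(0.005, 0.01, 0.02),
                             scaling_gain_grid = c(1e-4, 2e-4, 5e-4),
                             n_patterns = 30,
                             spec = circular_ensemble_spec(n_excitatory = 200,
                                                           n_inhibitory = 50),
                             seed = 1) {
  grid <- expand.grid(a_plus = a_plus_grid, scaling_gain = scaling_gain_grid)
  grid$skewness <- NA_real_
  for (i in seq_len(nrow(grid))) {
    res <- run_gaussian_task(
      rule = stdp_rule(a_plus = grid$a_plus[i],
                       a_minus = 1.2 * grid$a_plus[i]),
      spec = spec, n_patterns = n_patterns, seed = seed,
      scaling_gain = grid$scaling_gain[i], measure_patterns = 5)
    grid$skewness[i] <- res$skewness
  }
  grid[order(-grid$skewness), ]
}
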