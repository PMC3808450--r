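#' Assemble a spiking network object
#'
#' A network is a set of simulated neurons sharing one parameter set, a list
#' of \code{\link{synapse_group}}s (internal and external), the number of
#' external stimulus channels, and an optional per-neuron independent Poisson
#' background drive delivered through a fixed excitatory synapse.
#'
#' @param n_neurons number of simulated neurons
#' @param params a \code{\link{neuron_params}} object
#' @param synapses list of \code{\link{synapse_group}}s
#' @param n_ext number of external stimulus channels
#' @param bg_rate per-neuron background Poisson rate (Hz)
#' @param bg_weight conductance jump per background spike (nS)
#' @param positions optional n x 2 matrix of positions on the unit torus
#' @return object of class \code{spiking_network}
#' @export
spiking_network <- function(n_neurons, params = neuron_params(),
                            synapses = list(), n_ext = 0,
                            bg_rate = 0, bg_weight = 0, positions = NULL) {
  stopifnot(inherits(params, "neuron_params"), n_neurons >= 1)
  for (g in synapses) {
    stopifnot(inherits(g, "synapse_group"))
    if (any(g$tgt < 1L | g$tgt > n_neurons))
      stop("synapse target outside network")
    nsrc <- if (g$external) n_ext else n_neurons
    if (any(g$src < 1L | g$src > nsrc))
      stop("synapse source outside its population")
  }
  structure(list(n_neurons = as.integer(n_neurons), params = params,
                 synapses = synapses, n_ext = as.integer(n_ext),
                 bg_rate = bg_rate, bg_weight = bg_weight,
                 positions = positions),
            class = "spiking_network")
}

#' @export
print.spiking_network <- function(x, ...) {
  cat(sprintf("spiking_network: %d neurons, %d external channels\n",
              x$n_neurons, x$n_ext))
  for (g in x$synapses)
    cat(sprintf("  group: %d synapses, %s%s%s\n", length(g$src),
                if (g$inh) "inhibitory" else "excitatory",
                if (g$plastic) ", plastic" else "",
                if (g$external) ", external" else ""))
  if (x$bg_rate > 0)
    cat(sprintf("  background: %.4g Hz x %.3g nS per neuron\n",
                x$bg_rate, x$bg_weight))
  invisible(x)
}

flatten_groups <- function(net, external) {
  gs <- Filter(function(g) g$external == external, net$synapses)
  if (length(gs) == 0)
    return(list(src = integer(0), tgt = integer(0), w = numeric(0),
                delay = numeric(0), inh = logical(0)))
  list(src = unlist(lapply(gs, `[[`, "src"), use.names = FALSE),
       tgt = unlist(lapply(gs, `[[`, "tgt"), use.names = FALSE),
       w = unlist(lapply(gs, `[[`, "weight"), use.names = FALSE),
       delay = unlist(lapply(gs, `[[`, "delay"), use.names = FALSE),
       inh = unlist(lapply(gs, function(g) rep(g$inh, length(g$src))),
                    use.names = FALSE))
}

#' Simulate a network for a fixed duration
#'
#' Clock-driven integration at a fixed time step (default 0.1 ms): exact
#' exponential updates for the synaptic conductances and the ADP current,
#' forward Euler for the membrane equation.  Spike delivery is binned:
#' arrival bin = emission bin + round(delay/dt).  The call is deterministic
#' given the stimulus, the network and the R random seed (the background
#' drive is the only source of randomness).
#'
#' @param net a \code{\link{spiking_network}}
#' @param stimulus \code{\link{spike_trains}} for the external channels, or
#'   NULL for none
#' @param duration simulated time (ms)
#' @param dt integration step (ms)
#' @param record_v integer vector of neuron indices whose voltage trace to
#'   record at dt resolution
#' @param state carry-over state from a previous call (element \code{state}
#'   of a previous result), or NULL to start from rest
#' @param forced_spikes optional list (neuron index -> spike command times in
#'   ms) used by the in vitro protocol harness; a command triggers a spike at
#'   the given step unless the neuron is refractory
#' @param const_ge,const_gi constant clamped conductances per neuron (nS)
#' @param i_inject constant injected current per neuron (pA)
#' @return list with \code{spikes} (a \code{spike_trains} over the simulated
#'   neurons), \code{v} (steps x recorded matrix, or NULL), \code{gbar}
#'   (per-neuron mean total synaptic conductance over the call), and
#'   \code{state} for chaining
#' @export
simulate_network <- function(net, stimulus = NULL, duration, dt = 0.1,
                             record_v = integer(0), state = NULL,
                             forced_spikes = NULL,
                             const_ge = 0, const_gi = 0, i_inject = 0) {
  stopifnot(inherits(net, "spiking_network"))
  if (dt <= 0) stop("dt must be > 0")
  n <- net$n_neurons
  rec <- flatten_groups(net, external = FALSE)
  ext <- flatten_groups(net, external = TRUE)

  ev_src <- integer(0); ev_step <- integer(0)
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "spike_trains"))
    if (length(stimulus) != net$n_ext)
      stop("stimulus has wrong number of channels")
    ns <- lengths(stimulus)
    ev_src <- rep.int(seq_along(stimulus), ns) - 1L
    tt <- unlist(stimulus, use.names = FALSE)
    if (length(tt) && max(tt) > duration)
      stop("stimulus spikes outside [0, duration]")
    ev_step <- pmin(as.integer(floor(tt / dt + 1e-9)),
                    as.integer(round(duration / dt)) - 1L)
    o <- order(ev_step)
    ev_src <- ev_src[o]; ev_step <- ev_step[o]
  }

  f_id <- integer(0); f_step <- integer(0)
  if (!is.null(forced_spikes)) {
    for (i in seq_along(forced_spikes)) {
      tt <- forced_spikes[[i]]
      if (length(tt) == 0) next
      if (any(tt < 0 | tt > duration)) stop("forced spike outside duration")
      f_id <- c(f_id, rep(i - 1L, length(tt)))
      f_step <- c(f_step, as.integer(floor(tt / dt + 1e-9)))
    }
    o <- order(f_step)
    f_id <- f_id[o]; f_step <- f_step[o]
  }

  if (length(record_v) && any(record_v < 1 | record_v > n))
    stop("record_v targets a nonexistent neuron")

  out <- engine_run(unclass(net$params), n,
                    rec$src - 1L, rec$tgt - 1L, rec$w,
                    as.integer(round(rec$delay / dt)), rec$inh,
                    net$n_ext,
                    ext$src - 1L, ext$tgt - 1L, ext$w,
                    as.integer(round(ext$delay / dt)), ext$inh,
                    ev_src, ev_step,
                    net$bg_rate, net$bg_weight,
                    duration, dt, state,
                    f_id, f_step, as.integer(record_v) - 1L,
                    rep_len(as.numeric(const_ge), n),
                    rep_len(as.numeric(const_gi), n),
                    rep_len(as.numeric(i_inject), n))

  times <- split(out$spike_time, factor(out$spike_id, levels = seq_len(n)))
  v <- if (length(record_v)) out$v else NULL
  if (!is.null(v)) {
    colnames(v) <- as.character(record_v)
    attr(v, "dt") <- dt
  }
  list(spikes = spike_trains(times, duration), v = v,
       gbar = out$gbar, state = out$state)
}

#' Generate (in)homogeneous Poisson spike trains from a rate grid
#'
#' Each source is an independent inhomogeneous Poisson process whose rate is
#' piecewise constant on the supplied time grid.  Sampling is exact per
#' segment: the count in a segment is Poisson with mean rate x width and
#' spike times are uniform within the segment.
#'
#' @param rates sources x bins matrix of rates (Hz), or a vector for a
#'   single constant-rate grid of one bin
#' @param bin_width width of each bin (ms)
#' @param duration optional total duration (ms); defaults to
#'   \code{ncol(rates) * bin_width}
#' @return a \code{\link{spike_trains}} object
#' @export
poisson_spike_trains <- function(rates, bin_width, duration = NULL) {
  if (is.vector(rates)) rates <- matrix(rates, ncol = 1)
  if (any(rates < 0)) stop("rates must be >= 0")
  n <- nrow(rates); nb <- ncol(rates)
  if (is.null(duration)) duration <- nb * bin_width
  trains <- vector("list", n)
  # counts drawn bin-by-bin across all sources at once
  counts <- matrix(rpois(n * nb, rates * bin_width / 1000), n, nb)
  tot <- rowSums(counts)
  src <- rep.int(seq_len(n), tot)
  binv <- unlist(lapply(seq_len(n), function(i)
    rep.int(seq_len(nb), counts[i, ])), use.names = FALSE)
  tt <- (binv - 1) * bin_width + runif(length(binv)) * bin_width
  tt <- pmin(tt, duration)
  for (i in seq_len(n)) trains[[i]] <- sort(tt[src == i])
  # guard against coincident draws breaking strict ordering
  trains <- lapply(trains, function(x) {
    while (any(d <- diff(x) <= 0)) x[which(d)[1] + 1] <- x[which(d)[1] + 1] + 1e-7
    x
  })
  spike_trains(trains, duration)
}
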