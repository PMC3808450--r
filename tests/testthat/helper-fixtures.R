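# Shared heavy fixtures for the acceptance-style tests: computed lazily,
# once per test run, and cached so several test blocks can assert against
# the same trained networks.  All sizes here are the suite's single-CPU
# working sizes (see the methods vignette); the acceptance script runs the
# full configurations.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, compute) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, compute(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# --- digit-task fixture: one ensemble, three rules, pooled error/F ------
digit_fixture <- function() {
  fixture("digits", function() {
    ens <- synthesize_digit_ensemble(digit_ensemble_spec(), seed = 404)
    set.seed(404)
    etr <- encode_poisson_ensemble(ens, which = "train")
    ete <- encode_poisson_ensemble(ens, which = "test")
    raw_counts <- function(e)
      t(vapply(e, function(u) lengths(u$spikes),
               integer(ens$spec$n_channels)))
    lab_tr <- vapply(etr, `[[`, numeric(1), "label")
    lab_te <- vapply(ete, `[[`, numeric(1), "label")
    m_raw <- train_readout(raw_counts(etr), lab_tr)
    err_raw <- evaluate_readout(m_raw, raw_counts(ete), lab_te)

    # untrained network F-statistic baseline ("before training"): the
    # random initial weights, statically rescaled onto the 1.5 Hz
    # operating point so the comparison is at matched output rate
    set.seed(1)
    net0 <- build_feedforward(feedforward_spec(n_outputs = 48),
                              ens$spec$n_channels)
    set.seed(51)
    probe <- encode_poisson_ensemble(ens, which = "train")[1:6]
    for (i in 1:6) {
      cm <- count_matrix(net0, probe)
      r <- mean(cm$counts)
      if (abs(r - 1.5) < 0.15) break
      net0$synapses[[1]]$weight <- net0$synapses[[1]]$weight *
        (1.5 / max(r, 0.2))^0.5
    }
    cm0 <- ensemble_counts(net0, ens, "train", reps = 2)
    keep0 <- apply(cm0$counts, 2, var) > 0
    f_before <- mean(f_statistic(cm0$counts[, keep0, drop = FALSE],
                                 cm0$labels))

    out <- list(err_raw = err_raw, f_before = f_before, ens = ens)
    for (rn in c("convallis", "stdp", "rate")) {
      rule <- switch(rn, convallis = convallis_rule(), stdp = stdp_rule(),
                     rate = rate_only_rule())
      errs <- c(); fs <- c(); rates <- c()
      for (s in 1:2) {
        fit <- train_feedforward_digits(rule = rule, ensemble = ens,
                                        ffspec = feedforward_spec(n_outputs = 48),
                                        passes = 8, seed = s)
        rates <- c(rates, mean(tail(fit$diagnostics$rate, 88)))
        set.seed(50 + s)
        ctr <- ensemble_counts(fit$net, ens, "train", reps = 2)
        cte <- ensemble_counts(fit$net, ens, "test", reps = 2)
        mm <- train_readout(ctr$counts, ctr$labels)
        errs <- c(errs, evaluate_readout(mm, cte$counts, cte$labels))
        keep <- apply(ctr$counts, 2, var) > 0
        fs <- c(fs, mean(f_statistic(ctr$counts[, keep, drop = FALSE],
                                     ctr$labels)))
      }
      out[[rn]] <- list(err = mean(errs), f = mean(fs), rate = mean(rates))
    }
    out
  })
}

# --- ring-task fixture: three rules, skewness/tuning/rate ---------------
ring_fixture <- function() {
  fixture("ring", function() {
    out <- list()
    for (rn in c("convallis", "stdp", "rate")) {
      rule <- switch(rn, convallis = convallis_rule(), stdp = stdp_rule(),
                     rate = rate_only_rule())
      res <- run_gaussian_task(rule = rule, n_patterns = 250,
                               target_rate = 10, seed = 11,
                               measure_patterns = 8)
      out[[rn]] <- list(rate = mean(tail(res$diagnostics$rate, 100)),
                        skewness = res$skewness, tuning = res$tuning)
    }
    out
  })
}

# --- recurrent fixture: calibrated net, trained two ways ----------------
recurrent_fixture <- function() {
  fixture("recurrent", function() {
    set.seed(31)
    spec <- recurrent_spec(n_total = 800, connection_prob = 225 / 800)
    cal <- calibrate_spontaneous_state(spec, probe_duration = 2500,
                                       final_duration = 4000, discard = 500)
    spec$mean_exc <- cal$mean_exc
    spec$mean_inh <- cal$mean_inh
    set.seed(32)
    net <- build_recurrent(spec, n_channels = 93)
    ens <- synthesize_digit_ensemble(digit_ensemble_spec(), seed = 32)
    set.seed(33)
    probe <- encode_poisson_ensemble(ens, which = "test")[1:8]
    pre_dyn <- characterize_dynamics(net, probe)
    set.seed(34)
    cm0 <- ensemble_counts(net, ens, "test", reps = 1)
    exc_idx <- seq_len(net$n_exc)
    pref0 <- preferred_class(cm0$counts[, exc_idx], cm0$labels)

    set.seed(35)
    fit <- train_recurrent_digits(net, ens, rule = convallis_rule(),
                                  passes = 1, seed = 35)
    post_dyn <- characterize_dynamics(fit$net, probe)
    set.seed(36)
    cm1 <- ensemble_counts(fit$net, ens, "test", reps = 1)
    pref1 <- preferred_class(cm1$counts[, exc_idx], cm1$labels)

    set.seed(37)
    fit_rc <- train_recurrent_digits(net, ens, rule = rate_only_rule(),
                                     passes = 1, seed = 35)
    set.seed(38)
    cm2 <- ensemble_counts(fit_rc$net, ens, "test", reps = 1)
    pref2 <- preferred_class(cm2$counts[, exc_idx], cm2$labels)

    list(cal = cal, net0 = net, fit = fit, fit_rc = fit_rc,
         pre_dyn = pre_dyn, post_dyn = post_dyn,
         pref0 = c(pref0, rep(0L, net$n_inh)),
         pref1 = c(pref1, rep(0L, net$n_inh)),
         pref2 = c(pref2, rep(0L, net$n_inh)))
  })
}
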