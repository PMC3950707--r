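# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own implementation paths.

# Brute-force event-by-event CTMC simulator: one exponential draw at a
# time, no chunking, no vectorized binning.
brute_force_ctmc <- function(k_eff_on, k_off, duration, seed,
                             start_bound = FALSE) {
  set.seed(seed)
  t_now <- 0
  bound <- start_bound
  times <- numeric(0)
  states <- logical(0)
  repeat {
    rate <- if (bound) k_off else k_eff_on
    if (rate <= 0) break
    t_now <- t_now + rexp(1, rate)
    if (t_now >= duration) break
    bound <- !bound
    times <- c(times, t_now)
    states <- c(states, bound)
  }
  list(times = times, entered_bound = states, start_bound = start_bound)
}

# Frame labels by explicit per-frame occupancy integration on the oracle's
# event list (fine-grained interval walk, independent of the package's
# rowsum-based binning).
brute_force_bin <- function(ev, duration, dt) {
  n <- floor(duration / dt + 1e-9)
  labels <- character(n)
  bounds_at <- function(t) {
    k <- sum(ev$times <= t)
    xor(ev$start_bound, k %% 2 == 1)
  }
  for (f in seq_len(n)) {
    lo <- (f - 1) * dt
    hi <- f * dt
    cuts <- sort(unique(c(lo, ev$times[ev$times > lo & ev$times < hi], hi)))
    occ <- 0
    for (j in seq_len(length(cuts) - 1)) {
      mid <- (cuts[j] + cuts[j + 1]) / 2
      if (bounds_at(mid)) occ <- occ + (cuts[j + 1] - cuts[j])
    }
    labels[f] <- if (occ >= dt / 2) "bound" else "unbound"
  }
  labels
}

# Complete dwell durations straight from a ground-truth event list: dwells
# bracketed by two recorded events (the first dwell starts at the window
# edge and the last has no closing event, so both are censored).
oracle_complete_dwells <- function(path, state) {
  ev <- path$event_times
  d <- diff(ev$time)           # dwell k runs from event k to event k+1
  st <- ev$state[-nrow(ev)]
  d <- d[st == state]
  if (nrow(ev) >= 1L && ev$state[1L] == state && length(d)) d <- d[-1L]
  d
}

# Joint log-likelihood of a fixed state sequence under a Gaussian HMM.
hmm_path_loglik <- function(obs, states, model) {
  stopifnot(length(obs) == length(states))
  idx <- states + 1L  # 0-based component index
  ll <- log(model$init[idx[1L]]) +
    sum(dnorm(obs, model$mu[idx], model$sd[idx], log = TRUE))
  if (length(idx) > 1L)
    ll <- ll + sum(log(model$trans[cbind(idx[-length(idx)], idx[-1L])]))
  ll
}

# Simulate, render and idealize one molecule; returns truth and inference.
make_idealized <- function(cfg, conc, seed, initial_state = NULL, ...) {
  set.seed(seed)
  p <- simulate_state_path(cfg$k_on * conc, cfg$k_off, cfg$duration, cfg$dt,
                           initial_state = initial_state)
  cfg$tf_concentration <- conc
  tr <- render_trace(p, cfg)
  list(path = p, trace = tr, ideal = idealize_two_state(tr, ...))
}
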