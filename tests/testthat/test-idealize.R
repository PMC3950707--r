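# idealization: HMM fitting, bleach detection, molecule selection

test_that("noiseless traces are idealized exactly", {
  cfg <- sim_config(noise_sd = 0, bleach_rate = 0, duration = 100,
                    k_on = 0.05, k_off = 0.05, tf_concentration = 1)
  for (s in 1:3) {
    p <- simulate_state_path(0.05, 0.05, 100, 0.05, seed = s)
    if (nrow(transitions(p)) == 0) next
    tr <- render_trace(p, cfg, seed = s + 10)
    id <- idealize_two_state(tr)
    expect_identical(id$path$labels, p$labels)
  }
})

test_that("constant-level traces yield zero transitions, not an error", {
  cfg <- sim_config(duration = 60, bleach_rate = 0)
  p <- simulate_state_path(0, 1e-9, 60, 0.05, seed = 1)
  tr <- render_trace(p, cfg, seed = 2)
  id <- idealize_two_state(tr)
  expect_equal(nrow(transitions(id$path)), 0L)
  expect_true(id$model$degenerate)
})

test_that("SNR-3 cohorts: misclassification < 2%, transitions within 10%", {
  cfg <- sim_config(duration = 200, k_on = 0.05, k_off = 0.1,
                    tf_concentration = 4, bleach_rate = 0,
                    noise_sd = 500 / 3)  # PIFE separation 500 => SNR 3
  mis <- 0; n_frames <- 0; ev_true <- 0; ev_inf <- 0
  for (s in 1:25) {
    r <- make_idealized(cfg, 4, seed = s)
    mis <- mis + sum(r$ideal$path$labels != r$path$labels)
    n_frames <- n_frames + length(r$path$labels)
    ev_true <- ev_true + nrow(transitions(r$path))
    ev_inf <- ev_inf + nrow(transitions(r$ideal$path))
  }
  expect_lt(mis / n_frames, 0.02)
  expect_lt(abs(ev_inf - ev_true) / ev_true, 0.1)
})

test_that("bleach detection finds the dark transition within 2 frames", {
  cfg <- sim_config(duration = 100, k_on = 0.2, k_off = 0.2,
                    tf_concentration = 1)
  p <- simulate_state_path(0.2, 0.2, 100, 0.05, seed = 3)
  for (s in 1:5) {
    tr <- render_trace(p, cfg, seed = s, bleach_time = 1000 * 0.05)
    expect_lt(abs(detect_bleach(tr) - 1001), 3)
  }
  tr_none <- render_trace(p, cfg, seed = 1, bleach_time = Inf)
  expect_null(detect_bleach(tr_none))
  tr_dark <- render_trace(p, cfg, seed = 1, bleach_time = 0)
  expect_equal(detect_bleach(tr_dark), 1L)
})

test_that("early bleaching does not fabricate binding events", {
  cfg <- sim_config(duration = 2000, k_on = 0.05, k_off = 3.4e-3,
                    tf_concentration = 1)
  p <- simulate_state_path(0, 0, 2000, 0.05, seed = 1,
                           initial_state = "bound")
  for (s in 1:5) {
    tr <- render_trace(p, cfg, seed = s, bleach_time = 100)
    id <- idealize_two_state(tr)
    expect_equal(nrow(transitions(id$path)), 0L)
  }
})

test_that("idealization is invariant to intensity rescaling", {
  cfg <- sim_config(duration = 100, k_on = 0.1, k_off = 0.1,
                    tf_concentration = 1, bleach_rate = 0)
  p <- simulate_state_path(0.1, 0.1, 100, 0.05, seed = 8)
  tr <- render_trace(p, cfg, seed = 9)
  id1 <- idealize_two_state(tr)
  tr_scaled <- tr
  tr_scaled$channels$cy3 <- tr$channels$cy3 * 37.5
  id2 <- idealize_two_state(tr_scaled)
  expect_identical(id1$path$labels, id2$path$labels)

  cfgF <- sim_config(modality = "FRET", duration = 100, k_on = 0.1,
                     k_off = 0.1, tf_concentration = 1, bleach_rate = 0)
  trF <- render_trace(p, cfgF, seed = 10)
  idF <- idealize_two_state(trF)
  trF2 <- trF
  trF2$channels$donor <- trF$channels$donor * 4
  trF2$channels$acceptor <- trF$channels$acceptor * 4
  expect_identical(idealize_two_state(trF2)$path$labels, idF$path$labels)
})

test_that("Viterbi decoding is optimal (exhaustive enumeration, n <= 12)", {
  set.seed(21)
  model <- list(mu = c(0, 1), sd = c(0.5, 0.5),
                trans = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
                init = c(0.6, 0.4))
  for (rep in 1:5) {
    n <- 10
    truth <- integer(n); truth[1] <- rbinom(1, 1, model$init[2])
    for (t in 2:n)
      truth[t] <- rbinom(1, 1, model$trans[truth[t - 1] + 1, 2])
    obs <- rnorm(n, model$mu[truth + 1], model$sd[truth + 1])
    vit <- smkinetics:::hmm_viterbi_cpp(obs, model$mu, model$sd,
                                        model$trans, model$init)
    ll_vit <- hmm_path_loglik(obs, vit, model)
    # exhaustive maximum over all 2^n labelings
    grid <- as.matrix(expand.grid(rep(list(0:1), n)))
    ll_all <- apply(grid, 1, function(s) hmm_path_loglik(obs, s, model))
    expect_equal(ll_vit, max(ll_all), tolerance = 1e-10)
    expect_gte(ll_vit, hmm_path_loglik(obs, truth, model) - 1e-10)
  }
})

test_that("select_molecules applies colocalization and fluctuation filters", {
  cfg <- sim_config(duration = 100, k_on = 0.2, k_off = 0.2,
                    tf_concentration = 1, bleach_rate = 0)
  traces <- list(); ideals <- list()
  for (s in 1:6) {
    r <- make_idealized(cfg, 1, seed = s)
    r$trace$molecule_id <- paste0("mol_", s)
    traces[[s]] <- r$trace; ideals[[s]] <- r$ideal
  }
  traces[[2]]$colocalized_acceptor <- FALSE
  sel <- select_molecules(traces, ideals)
  expect_equal(sel$n_colocalized, 5L)
  expect_false(any(vapply(sel$traces, function(t)
    identical(t$molecule_id, traces[[2]]$molecule_id), TRUE)))
  expect_true("no_colocalized_acceptor" %in% sel$excluded$reason)
  expect_error(select_molecules(list(), list()), "empty")
})

test_that("inactive fraction 0.75 gives ~25% selected (PIFE bookkeeping)", {
  cfg <- sim_config(duration = 200, k_on = 0.2, k_off = 0.5,
                    tf_concentration = 1, inactive_fraction = 0.75,
                    bleach_rate = 0)
  co <- simulate_cohort(cfg, 1, 200, seed = 31)
  ideals <- lapply(co, idealize_two_state)
  sel <- select_molecules(co, ideals)
  expect_lt(abs(sel$fluctuating_fraction - 0.25),
            3 * sqrt(0.25 * 0.75 / 200))

  cfg_all <- sim_config(duration = 200, k_on = 0.2, k_off = 0.5,
                        tf_concentration = 1, bleach_rate = 0)
  co2 <- simulate_cohort(cfg_all, 1, 40, seed = 32)
  sel2 <- select_molecules(co2, lapply(co2, idealize_two_state))
  expect_equal(sel2$fluctuating_fraction, 1.0)
})

test_that("inferred and true dwell taus agree within 2 combined SEs", {
  # mean dwells >= 4 dt in both states
  cfg <- sim_config(modality = "FRET", duration = 200, k_on = 1e-4,
                    k_off = 2, tf_concentration = 2500, bleach_rate = 0)
  tabs_t <- list(); tabs_i <- list()
  for (s in 1:30) {
    r <- make_idealized(cfg, 2500, seed = 300 + s)
    tabs_t[[s]] <- extract_dwells(r$trace$ground_truth)
    tabs_i[[s]] <- extract_dwells(r$ideal$path)
  }
  tt <- bind_dwells(tabs_t); ti <- bind_dwells(tabs_i)
  ftb <- fit_exponential_censored(tt, "bound")
  ftu <- fit_exponential_censored(tt, "unbound")
  fib <- fit_exponential_censored(ti, "bound", truncation = 0.075)
  fiu <- fit_exponential_censored(ti, "unbound", truncation = 0.075)
  # inferred estimates carry missed-event inflation that the pipeline
  # inverts; compare after the same documented correction
  corr <- correct_missed_events(fib$tau, fiu$tau, deadtime = 0.075)
  expect_lt(abs(corr$tau_bound - ftb$tau),
            3 * sqrt(ftb$tau_se^2 + fib$tau_se^2))
  expect_lt(abs(corr$tau_unbound - ftu$tau),
            3 * sqrt(ftu$tau_se^2 + fiu$tau_se^2))
})
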