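# synthetic_data: state paths, trace rendering, cohorts

test_that("absorbing and degenerate rate cases behave exactly", {
  p <- simulate_state_path(0, 0.5, 100, 0.05, seed = 1,
                           initial_state = "unbound")
  expect_true(all(p$labels == "unbound"))
  expect_equal(nrow(transitions(p)), 0L)

  pb <- simulate_state_path(0, 0, 10, 0.05, seed = 1,
                            initial_state = "bound")
  expect_true(all(pb$labels == "bound"))

  expect_error(simulate_state_path(-1, 0.1, 10, 0.05), "non-negative")
  expect_error(simulate_state_path(Inf, 0.1, 10, 0.05), "finite")
})

test_that("complete bound dwells at k_off = 1/290 average 290 s (3 SE)", {
  k_off <- 1 / 290
  durations <- c()
  seed <- 100
  while (length(durations) < 1000) {
    seed <- seed + 1
    p <- simulate_state_path(0.05, k_off, 50000, 0.5, seed = seed)
    durations <- c(durations, oracle_complete_dwells(p, "bound"))
  }
  se <- sd(durations) / sqrt(length(durations))
  expect_lt(abs(mean(durations) - 290), 3 * se)
})

test_that("symmetric rates give half occupancy and the oracle's event count", {
  k <- 0.2
  p <- simulate_state_path(k, k, 20000, 0.05, seed = 42)
  expect_lt(abs(mean(p$labels == "bound") - 0.5), 0.02)

  # transition count against the brute-force event-by-event simulator
  n_pkg <- vapply(1:30, function(s)
    nrow(transitions(simulate_state_path(k, k, 2000, 0.05, seed = s))), 1)
  n_oracle <- vapply(31:60, function(s)
    length(brute_force_ctmc(k, k, 2000, seed = s)$times), 1)
  expected <- 2000 / (1 / k + 1 / k)  # duration / mean cycle * 2 states
  expect_lt(abs(mean(n_pkg) - 2 * expected) / (2 * expected), 0.1)
  expect_lt(abs(mean(n_pkg) - mean(n_oracle)) /
              (sd(n_oracle) / sqrt(30) + sd(n_pkg) / sqrt(30)), 3)
})

test_that("majority-vote frame binning matches a brute-force binner", {
  for (s in 1:5) {
    ev <- brute_force_ctmc(0.8, 1.2, 50, seed = s, start_bound = FALSE)
    oracle_labels <- brute_force_bin(ev, 50, 0.05)
    lab <- smkinetics:::bin_events_majority(ev$times, 1L, 50, 0.05)
    expect_identical(lab, oracle_labels)
  }
  # fast kinetics relative to frames still disagrees on < 1% of frames
  # whenever dt <= 0.05 * min dwell time
  p <- simulate_state_path(0.5, 0.5, 5000, 0.05, seed = 9)
  ev <- p$event_times
  state_at <- function(t) ev$state[findInterval(t, ev$time)]
  mid <- (seq_along(p$labels) - 0.5) * 0.05
  expect_lt(mean(p$labels != state_at(mid)), 0.01)
})

test_that("identical seeds reproduce identical paths and cohorts", {
  p1 <- simulate_state_path(0.3, 0.2, 500, 0.05, seed = 7)
  p2 <- simulate_state_path(0.3, 0.2, 500, 0.05, seed = 7)
  expect_identical(p1, p2)

  cfg <- sim_config(duration = 20, k_on = 0.5, k_off = 0.5,
                    tf_concentration = 1)
  c1 <- simulate_cohort(cfg, c(0.5, 1), 3, seed = 5)
  c2 <- simulate_cohort(cfg, c(0.5, 1), 3, seed = 5)
  expect_identical(c1, c2)
})

test_that("noiseless PIFE rendering is a two-level step function", {
  cfg <- sim_config(noise_sd = 0, bleach_rate = 0, duration = 100,
                    k_on = 0.05, k_off = 0.05, tf_concentration = 1)
  p <- simulate_state_path(0.05, 0.05, 100, 0.05, seed = 3)
  tr <- render_trace(p, cfg, seed = 4)
  lv <- sort(unique(tr$channels$cy3))
  expect_equal(lv, c(1000, 1500))
  expect_identical(tr$channels$cy3 == 1500, p$labels == "bound")
})

test_that("noiseless FRET proximity ratio is exactly E per state", {
  cfg <- sim_config(modality = "FRET", noise_sd = 0, bleach_rate = 0,
                    duration = 50, k_on = 0.1, k_off = 0.2,
                    tf_concentration = 1)
  p <- simulate_state_path(0.1, 0.2, 50, 0.05, seed = 5)
  tr <- render_trace(p, cfg, seed = 6)
  ratio <- trace_observable(tr)
  expect_equal(ratio[p$labels == "unbound"],
               rep(0.8, sum(p$labels == "unbound")))
  expect_equal(ratio[p$labels == "bound"],
               rep(0.2, sum(p$labels == "bound")))
})

test_that("bleaching truncates the trace to a dark tail", {
  cfg <- sim_config(noise_sd = 0, duration = 100)
  p <- simulate_state_path(0.05, 0.05, 100, 0.05, seed = 3)
  tr0 <- render_trace(p, cfg, seed = 1, bleach_time = 0)
  expect_true(all(tr0$channels$cy3 == 0))
  expect_true(all(tr0$ground_truth$labels == "dark"))

  tr <- render_trace(p, cfg, seed = 1, bleach_time = 50)
  dark <- tr$ground_truth$labels == "dark"
  expect_true(all(which(dark) > max(which(!dark)) - 1))
  expect_true(all(tr$channels$cy3[dark] == 0))

  cfg2 <- sim_config(dt = 0.1)
  expect_error(render_trace(p, cfg2), "dt")
})

test_that("cohort bookkeeping: counts, inactivity, manifest", {
  cfg <- sim_config(duration = 5, k_on = 1, k_off = 1, inactive_fraction = 1)
  co <- simulate_cohort(cfg, c(1, 10), 5, seed = 2)
  expect_true(all(vapply(co, function(tr)
    nrow(transitions(tr$ground_truth)) == 0, TRUE)))

  cfg3 <- sim_config(duration = 2, k_on = 1, k_off = 1)
  co3 <- simulate_cohort(cfg3, c(0.1, 0.2, 0.5, 1), 300, seed = 3)
  expect_length(co3, 1200)
  expect_equal(nrow(attr(co3, "manifest")), 1200)

  # inactive_fraction = 0.3 at near-certain fluctuation => ~70% fluctuate
  cfg2 <- sim_config(duration = 100, k_on = 1, k_off = 1,
                     inactive_fraction = 0.3, bleach_rate = 0)
  co2 <- simulate_cohort(cfg2, 10, 400, seed = 4)
  fluct <- mean(vapply(co2, function(tr)
    nrow(transitions(tr$ground_truth)) > 0, TRUE))
  expect_lt(abs(fluct - 0.7), 3 * sqrt(0.7 * 0.3 / 400))

  expect_error(simulate_cohort(cfg, numeric(0), 5), "non-empty")
})

test_that("long-run occupancy equals k_eff/(k_eff + k_off)", {
  for (r in list(c(0.4, 0.1), c(0.05, 0.2))) {
    p <- simulate_state_path(r[1], r[2], 50000, 0.05, seed = sum(r * 100))
    occ <- r[1] / (r[1] + r[2])
    expect_lt(abs(mean(p$labels == "bound") - occ), 0.03)
  }
})

test_that("sim_config rejects invalid parameter combinations", {
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(E_bound = 0.9, E_unbound = 0.8), "E_bound")
  expect_error(sim_config(pife_enhancement = 1), "pife_enhancement")
  expect_error(sim_config(inactive_fraction = 1.2), "inactive_fraction")
  expect_error(sim_config(k_off = -1), "k_off")
})
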