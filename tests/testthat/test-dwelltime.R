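# dwelltime: extraction, censoring, exponential fits

test_that("dwell extraction marks runs and censoring correctly", {
  p <- state_path(c("unbound", "unbound", "bound", "bound", "bound",
                    "unbound"), dt = 1, source = "inferred")
  dw <- extract_dwells(p, "m1", 0.5)
  expect_equal(nrow(dw), 3L)
  expect_equal(dw$duration, c(2, 3, 1))
  expect_equal(complete_dwells(dw, "bound"), 3)
  expect_length(complete_dwells(dw, "unbound"), 0)  # both runs censored
  expect_true(dw$left_censored[1] && dw$right_censored[3])

  single <- state_path(rep("bound", 10), dt = 0.5, source = "inferred")
  ds <- extract_dwells(single)
  expect_length(complete_dwells(ds, "bound"), 0)

  # dark tail right-censors the preceding dwell and forms no dwell itself
  pb <- state_path(c("unbound", "bound", "bound", "dark", "dark"), dt = 1,
                   source = "inferred")
  db <- extract_dwells(pb)
  expect_equal(nrow(db), 2L)
  expect_true(db$right_censored[2])
})

test_that("run-length bookkeeping matches a brute-force encoder", {
  set.seed(5)
  labels <- sample(c("unbound", "bound"), 200, replace = TRUE,
                   prob = c(0.6, 0.4))
  # brute-force run-length encoder: explicit scan
  runs <- list(); cur <- labels[1]; len <- 1
  for (i in 2:length(labels)) {
    if (labels[i] == cur) len <- len + 1
    else { runs[[length(runs) + 1]] <- list(cur, len); cur <- labels[i]; len <- 1 }
  }
  runs[[length(runs) + 1]] <- list(cur, len)
  dw <- extract_dwells(state_path(labels, dt = 0.1, source = "inferred"))
  expect_equal(nrow(dw), length(runs))
  expect_equal(dw$duration,
               vapply(runs, function(r) r[[2]] * 0.1, 1))
  expect_equal(dw$state, vapply(runs, `[[`, "", 1))
})

test_that("exponential MLE closed forms", {
  expect_equal(fit_exponential_mle(c(1, 2, 3))$tau, 2)
  expect_equal(fit_exponential_mle(5)$tau, 5)
  expect_true(fit_exponential_mle(5)$low_confidence)
  expect_error(fit_exponential_mle(numeric(0)), "no dwell")
  f <- fit_exponential_mle(c(1, 2, 3))
  expect_equal(f$tau_se, 2 / sqrt(3))
  # left truncation: mean - truncation
  expect_equal(fit_exponential_mle(c(1, 2, 3), truncation = 0.5)$tau, 1.5)
})

test_that("1000 simulated dwells at tau 0.31 recover within 3 SE", {
  set.seed(17)
  d <- rexp(1000, 1 / 0.31)
  f <- fit_exponential_mle(d)
  expect_lt(abs(f$tau - 0.31), 3 * f$tau_se)
})

test_that("histogram fit agrees with the MLE and is bin-width stable", {
  set.seed(23)
  d <- rexp(5000, 1 / 2.1)
  fm <- fit_exponential_mle(d)
  fh <- fit_exponential_histogram(d, dt = 0.05)
  expect_lt(abs(fh$tau - fm$tau) / fm$tau, 0.05)
  bw <- max(0.05, mean(d) / 10)
  fh2 <- fit_exponential_histogram(d, bin_width = 2 * bw, dt = 0.05)
  expect_lt(abs(fh2$tau - fh$tau) / fh$tau, 0.05)
  expect_error(fit_exponential_histogram(rep(1, 50), dt = 1), "non-empty bins")
})

test_that("two-bin histogram closed form: tau = 1/log(100/37)", {
  fit <- fit_exp_to_histogram(centers = c(0.5, 1.5), counts = c(100, 37))
  expect_equal(fit$tau, 1 / log(100 / 37), tolerance = 1e-6)
  expect_equal(fit$amplitude * exp(-0.5 / fit$tau), 100, tolerance = 1e-4)
})

test_that("censored MLE removes window bias that the naive mean has", {
  # dwells comparable to the window: complete-only mean is biased down
  set.seed(41)
  tau <- 300; window <- 2000
  tabs <- list()
  for (s in 1:60) {
    p <- simulate_state_path(1 / 100, 1 / tau, window, 0.5, seed = 4100 + s)
    tabs[[s]] <- extract_dwells(p)
  }
  dw <- bind_dwells(tabs)
  fc <- fit_exponential_censored(dw, "bound")
  fn <- fit_exponential_mle(complete_dwells(dw, "bound"))
  expect_lt(abs(fc$tau - tau), 3 * fc$tau_se)
  expect_lt(fn$tau, fc$tau)  # naive estimator biased downward

  # counting right-censored dwells as complete biases tau downward too
  f_bad <- fit_exponential_mle(
    dw$duration[dw$state == "bound" & !dw$left_censored])
  expect_lt(f_bad$tau, tau)
})

test_that("tau estimates are invariant to molecule concatenation order", {
  set.seed(53)
  tabs <- lapply(1:10, function(s) {
    p <- simulate_state_path(0.2, 0.2, 500, 0.05, seed = 530 + s)
    extract_dwells(p, molecule_id = paste0("m", s))
  })
  f1 <- fit_exponential_censored(bind_dwells(tabs), "bound")
  f2 <- fit_exponential_censored(bind_dwells(rev(tabs)), "bound")
  expect_equal(f1$tau, f2$tau)
  d1 <- complete_dwells(bind_dwells(tabs), "unbound")
  d2 <- complete_dwells(bind_dwells(rev(tabs)), "unbound")
  expect_equal(fit_exponential_mle(d1)$tau, fit_exponential_mle(d2)$tau)
})

test_that("missed-event correction exactly inverts its forward model", {
  # forward model: tau_obs = (tau + p * g) / (1 - p) with p and g from the
  # *true* opposite-state tau; the inversion must return the true pair
  forward <- function(tau_b, tau_u, td) {
    p <- function(tau) 1 - exp(-td / tau)
    g <- function(tau) tau - td * exp(-td / tau) / p(tau)
    c((tau_b + p(tau_u) * g(tau_u)) / (1 - p(tau_u)),
      (tau_u + p(tau_b) * g(tau_b)) / (1 - p(tau_b)))
  }
  for (pars in list(c(0.31, 0.22), c(0.31, 7.4), c(290, 20), c(1, 1))) {
    obs <- forward(pars[1], pars[2], td = 0.075)
    corr <- correct_missed_events(obs[1], obs[2], deadtime = 0.075)
    expect_equal(corr$tau_bound, pars[1], tolerance = 1e-8)
    expect_equal(corr$tau_unbound, pars[2], tolerance = 1e-8)
    # apparent times are inflated, corrected ones smaller
    expect_gte(obs[1], corr$tau_bound)
    expect_gte(obs[2], corr$tau_unbound)
  }
  # no deadtime, no change
  id <- correct_missed_events(1.5, 2.5, 0)
  expect_equal(id$tau_bound, 1.5)
  expect_equal(id$tau_unbound, 2.5)
})

test_that("estimators recover a tau grid spanning 0.3 to 300 s", {
  # window >= 20 tau, censored dwells excluded: both estimators unbiased
  for (tau in c(0.3, 30, 300)) {
    dt <- tau / 20
    tabs <- lapply(1:20, function(s) {
      p <- simulate_state_path(1 / tau, 1 / tau, 40 * tau, dt,
                               seed = round(1e4 * log(tau) + s))
      extract_dwells(p)
    })
    dw <- bind_dwells(tabs)
    for (st in c("bound", "unbound")) {
      fm <- fit_exponential_mle(complete_dwells(dw, st))
      expect_lt(abs(fm$tau - tau), 3.5 * fm$tau_se)
    }
  }
})
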