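# ensemble: occupancy curves, isotherm fits, histogram unmixing

test_that("fraction of time bound hits the closed-form occupancy", {
  all_bound <- replicate(3, state_path(rep("bound", 50), 0.05, "inferred"),
                         simplify = FALSE)
  tc <- fraction_time_bound(setNames(list(all_bound), "1"), n_boot = 0)
  expect_equal(tc$response, 1)

  none <- replicate(3, state_path(rep("unbound", 50), 0.05, "inferred"),
                    simplify = FALSE)
  tc0 <- fraction_time_bound(setNames(list(none), "1"), n_boot = 0)
  expect_equal(tc0$response, 0)

  # equilibrium occupancy k_on C / (k_on C + k_off)
  k_on <- 0.1; k_off <- 0.2; C <- 3
  paths <- lapply(1:20, function(s)
    simulate_state_path(k_on * C, k_off, 2000, 0.05, seed = 700 + s))
  tc2 <- fraction_time_bound(setNames(list(paths), as.character(C)),
                             n_boot = 50, seed = 1)
  occ <- k_on * C / (k_on * C + k_off)
  expect_lt(abs(tc2$response - occ), 4 * tc2$response_se)

  dark <- list(state_path(rep("dark", 10), 0.05, "inferred"))
  expect_error(fraction_time_bound(setNames(list(dark), "1")),
               "zero analyzable")
})

test_that("relative FRET change maps efficiencies to [0, 1]", {
  tc <- relative_fret_change(c(0.01, 100), c(0.8, 0.2),
                             E_max = 0.8, E_min = 0.2)
  expect_equal(tc$response, c(0, 1))
  expect_error(relative_fret_change(1, 0.5, E_max = 0.2, E_min = 0.8),
               "E_max")

  # midpoint of a synthetic titration occurs at the generating S_0.5
  s05 <- 2
  conc <- 10^seq(-2, 2, length.out = 15)
  eff <- 0.8 - 0.6 * conc / (s05 + conc)
  rc <- relative_fret_change(conc, eff, 0.8, 0.2)
  fit <- fit_binding_curve(rc, "noncooperative")
  expect_equal(fit$s05, s05, tolerance = 1e-6)
})

test_that("noiseless isotherm fits recover published parameters exactly", {
  conc <- 10^seq(-2.5, 1.5, length.out = 10)
  nc <- simulate_titration("noncooperative", 0.13, conc, noise_sd = 0)
  f1 <- fit_binding_curve(nc, "noncooperative")
  expect_equal(f1$s05, 0.13, tolerance = 1e-6)

  hill <- simulate_titration("hill", 0.042, 10^seq(-4, 0, length.out = 12),
                             hill_n = 1.5, noise_sd = 0)
  f2 <- fit_binding_curve(hill, "hill")
  expect_equal(f2$s05, 0.042, tolerance = 1e-4)
  expect_equal(f2$hill_n, 1.5, tolerance = 1e-3)
})

test_that("depletion fit recovers K_D where a naive fit reads the DNA conc", {
  target <- 0.2; K <- 0.005
  conc <- 10^seq(-3, 0.5, length.out = 20)
  curve <- simulate_titration("depletion", K, conc, target_conc = target,
                              noise_sd = 0)
  fd <- fit_binding_curve(curve, "depletion", target_conc = target)
  expect_equal(fd$s05, K, tolerance = 1e-4)
  fn <- suppressWarnings(fit_binding_curve(curve, "noncooperative"))
  expect_gt(fn$s05, 10 * K)            # naive S_0.5 tracks the DNA conc
  expect_lt(abs(fn$s05 - (target / 2 + K)) / (target / 2 + K), 0.25)

  # depletion reduces to the noncooperative model as target/K_D -> 0
  K2 <- 1
  curve2 <- simulate_titration("depletion", K2, 10^seq(-2, 2, length.out = 15),
                               target_conc = K2 * 1e-2, noise_sd = 0)
  fnc <- fit_binding_curve(curve2, "noncooperative")
  expect_equal(fnc$s05, K2, tolerance = 0.01)
})

test_that("responses are monotone in concentration for noiseless input", {
  conc <- 10^seq(-3, 3, length.out = 30)
  for (m in c("noncooperative", "hill"))
    expect_true(!is.unsorted(
      simulate_titration(m, 1, conc, hill_n = 2, noise_sd = 0)$response))
  expect_true(!is.unsorted(
    simulate_titration("depletion", 0.01, conc, target_conc = 0.5,
                       noise_sd = 0)$response))
})

test_that("histogram unmixing recovers mixture weights", {
  ref_lo <- c(1000, 120); ref_hi <- c(1500, 150)
  set.seed(83)
  lo_only <- rnorm(400, ref_lo[1], ref_lo[2])
  expect_lt(intensity_histogram_unmix(lo_only, ref_lo, ref_hi)$fraction_high,
            0.02)

  half <- c(rnorm(500, ref_lo[1], ref_lo[2]),
            rnorm(500, ref_hi[1], ref_hi[2]))
  u <- intensity_histogram_unmix(half, ref_lo, ref_hi)
  expect_lt(abs(u$fraction_high - 0.5), 3 * sqrt(0.25 / 1000) + 0.02)

  expect_error(intensity_histogram_unmix(half, c(1000, 400), c(1100, 400)),
               "indistinguishable")
})

test_that("unmixed titration recovers a 5 pM Hill-2 midpoint", {
  ref_lo <- c(1000, 120); ref_hi <- c(1500, 150)
  s05 <- 0.005  # 5 pM in nM
  conc <- c(0.0005, 0.001, 0.002, 0.005, 0.01, 0.02, 0.05, 0.1)
  set.seed(97)
  fr <- vapply(conc, function(C) {
    w <- C^2 / (s05^2 + C^2)
    n <- 600
    x <- c(rnorm(round(n * (1 - w)), ref_lo[1], ref_lo[2]),
           rnorm(round(n * w), ref_hi[1], ref_hi[2]))
    intensity_histogram_unmix(x, ref_lo, ref_hi)$fraction_high
  }, 1)
  fit <- fit_binding_curve(titration_curve(conc, fr,
                                           response_kind = "high_peak_area_fraction"),
                           "hill")
  expect_lt(abs(fit$s05 - s05) / s05, 0.2)
  expect_lt(abs(fit$hill_n - 2), 0.4)
})
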