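#' Titration curves
#'
#' @param tf_concentration Concentrations, nM (>= 0).
#' @param response Response values (fraction bound, relative FRET change,
#'   high-peak area fraction, or fraction of time bound).
#' @param response_se Optional standard errors.
#' @param response_kind One of `"fraction_bound"`, `"relative_fret_change"`,
#'   `"high_peak_area_fraction"`, `"fraction_time_bound"`.
#' @return An object of class `titration_curve` (a data frame).
#' @export
titration_curve <- function(tf_concentration, response,
                            response_se = NA_real_,
                            response_kind = c("fraction_bound",
                                              "relative_fret_change",
                                              "high_peak_area_fraction",
                                              "fraction_time_bound")) {
  response_kind <- match.arg(response_kind)
  if (any(tf_concentration < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (any(!is.finite(response))) stop("responses must be finite", call. = FALSE)
  structure(data.frame(tf_concentration = tf_concentration,
                       response = response,
                       response_se = rep_len(response_se,
                                             length(tf_concentration))),
            response_kind = response_kind,
            class = c("titration_curve", "data.frame"))
}

# Noiseless mean response of the supported binding models.
# For "depletion", `conc` is the *total* TF concentration and the exact 1:1
# binding quadratic is solved for the bound fraction of target at total
# target concentration `target_conc`.
binding_response <- function(conc, model, s05, hill_n = 1,
                             target_conc = NULL) {
  switch(model,
    noncooperative = conc / (s05 + conc),
    hill = conc^hill_n / (s05^hill_n + conc^hill_n),
    depletion = {
      if (is.null(target_conc) || target_conc <= 0)
        stop("depletion model needs a positive `target_conc`", call. = FALSE)
      K <- s05
      b <- conc + target_conc + K
      bound <- (b - sqrt(b^2 - 4 * conc * target_conc)) / 2
      bound / target_conc
    },
    stop("unknown binding model: ", model, call. = FALSE))
}

#' Simulate an ensemble titration curve
#'
#' Draws the noiseless mean response from the chosen binding model and adds
#' Gaussian replicate noise; the reported response is the replicate mean
#' and its standard error.  The depletion model solves the exact 1:1
#' binding quadratic in free TF at the stated target (DNA/nucleosome)
#' concentration, reproducing the regime where an ensemble S_0.5 tracks the
#' target concentration rather than the K_D.
#'
#' @param model `"noncooperative"`, `"hill"`, or `"depletion"`.
#' @param s05 Midpoint (S_0.5, nM); for the depletion model this is the
#'   true K_D.
#' @param concentrations Positive TF concentrations, nM.
#' @param hill_n Hill coefficient (> 0; `hill` model only).
#' @param target_conc Total target concentration, nM (`depletion` only).
#' @param noise_sd Gaussian replicate noise sd (response units).
#' @param replicates Replicates per concentration (default 3).
#' @param seed Optional integer seed.
#' @return A [titration_curve] with attribute `truth` recording the
#'   generating parameters.
#' @export
simulate_titration <- function(model = c("noncooperative", "hill", "depletion"),
                               s05, concentrations, hill_n = 1,
                               target_conc = NULL, noise_sd = 0,
                               replicates = 3L, seed = NULL) {
  model <- match.arg(model)
  if (any(concentrations <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (s05 <= 0) stop("`s05` must be > 0", call. = FALSE)
  if (hill_n <= 0) stop("`hill_n` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mu <- binding_response(concentrations, model, s05, hill_n, target_conc)
  if (noise_sd > 0) {
    reps <- vapply(mu, function(m)
      mean(rnorm(replicates, mean = m, sd = noise_sd)), 1)
    se <- rep(noise_sd / sqrt(replicates), length(mu))
  } else {
    reps <- mu
    se <- rep(0, length(mu))
  }
  out <- titration_curve(concentrations, reps, se, "fraction_bound")
  attr(out, "truth") <- list(model = model, s05 = s05, hill_n = hill_n,
                             target_conc = target_conc)
  out
}

#' Fraction of time bound, per concentration
#'
#' Computes total bound frames over total analyzable (non-dark) frames for
#' each concentration group of idealized paths; at equilibrium this
#' estimates the bound occupancy `k_on C / (k_on C + k_off)`.  Standard
#' errors come from a bootstrap over molecules.
#'
#' @param path_groups Named list: one entry per concentration (names are
#'   concentrations in nM), each a list of [state_path] objects.
#' @param n_boot Bootstrap replicates over molecules (default 200).
#' @param seed Optional seed for the bootstrap.
#' @return A [titration_curve] with `response_kind = "fraction_time_bound"`.
#' @export
fraction_time_bound <- function(path_groups, n_boot = 200L, seed = NULL) {
  if (length(path_groups) == 0L) stop("no path groups supplied", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  conc <- as.numeric(names(path_groups))
  if (any(is.na(conc)))
    stop("`path_groups` must be named by concentration (nM)", call. = FALSE)
  est <- se <- numeric(length(path_groups))
  for (i in seq_along(path_groups)) {
    paths <- path_groups[[i]]
    bound <- vapply(paths, function(p) sum(p$labels == "bound"), 1)
    live <- vapply(paths, function(p) sum(p$labels != "dark"), 1)
    if (sum(live) == 0) stop("zero analyzable frames at concentration ",
                             conc[i], call. = FALSE)
    est[i] <- sum(bound) / sum(live)
    if (length(paths) > 1L && n_boot > 0L) {
      bb <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(paths), replace = TRUE)
        s <- sum(live[idx])
        if (s == 0) return(NA_real_)
        sum(bound[idx]) / s
      }, 1)
      se[i] <- sd(bb, na.rm = TRUE)
    } else se[i] <- NA_real_
  }
  titration_curve(conc, est, se, "fraction_time_bound")
}

#' Relative FRET change titration
#'
#' Maps ensemble FRET efficiencies to the relative change
#' `(E_max - E(C)) / (E_max - E_min)`: 0 with no TF bound, 1 at
#' saturation.  Because the map is affine in `E`, the curve is invariant to
#' the (ratio)_A correction constants, which default to identity.  The
#' single-molecule counterpart of this quantity is the fraction of time in
#' the low-FRET state, available via [fraction_time_bound()].
#'
#' @param tf_concentration Concentrations, nM.
#' @param efficiency Ensemble FRET efficiency at each concentration.
#' @param E_max Efficiency with no TF bound (fully wrapped).
#' @param E_min Efficiency at saturating TF.
#' @param efficiency_se Optional standard errors on the efficiencies.
#' @return A [titration_curve] with `response_kind = "relative_fret_change"`.
#' @export
relative_fret_change <- function(tf_concentration, efficiency, E_max, E_min,
                                 efficiency_se = NA_real_) {
  if (E_max <= E_min) stop("`E_max` must exceed `E_min`", call. = FALSE)
  span <- E_max - E_min
  titration_curve(tf_concentration, (E_max - efficiency) / span,
                  rep_len(efficiency_se, length(efficiency)) / span,
                  "relative_fret_change")
}

#' Fit a binding isotherm to a titration curve
#'
#' Weighted least squares of `response = C^n / (S_0.5^n + C^n)` (Hill; `n`
#' fixed at 1 for the non-cooperative model), or of the exact 1:1
#' ligand-depletion quadratic at a stated target concentration.  Weights
#' are `1 / response_se^2` when standard errors are available, otherwise
#' uniform.  A warning is emitted when the data do not span the 0.2-0.8
#' response range (wide standard errors expected).
#'
#' @param curve A [titration_curve] (or data frame with columns
#'   `tf_concentration`, `response`, optionally `response_se`) with at
#'   least 3 concentrations.
#' @param model `"noncooperative"`, `"hill"`, or `"depletion"`.
#' @param target_conc Total target concentration, nM (`depletion` only).
#' @return An object of class `binding_fit`: `s05` (for the depletion model
#'   this is the fitted K_D), `hill_n`, standard errors, the model, and the
#'   fitted curve function.
#' @export
fit_binding_curve <- function(curve, model = c("noncooperative", "hill",
                                               "depletion"),
                              target_conc = NULL) {
  model <- match.arg(model)
  df <- as.data.frame(curve)
  stopifnot(all(c("tf_concentration", "response") %in% names(df)))
  df <- df[df$tf_concentration > 0, , drop = FALSE]
  if (nrow(df) < 3L) stop("need >= 3 positive concentrations", call. = FALSE)
  if (min(df$response) > 0.2 || max(df$response) < 0.8)
    warning("titration does not span the 0.2-0.8 response range; expect wide standard errors",
            call. = FALSE)
  w <- if ("response_se" %in% names(df) &&
           all(is.finite(df$response_se)) && all(df$response_se > 0))
    1 / df$response_se^2 else rep(1, nrow(df))

  # midpoint start value by interpolation
  s0 <- tryCatch({
    o <- order(df$tf_concentration)
    stats::approx(df$response[o], df$tf_concentration[o], xout = 0.5,
                  ties = "ordered")$y
  }, error = function(e) NA_real_)
  if (!is.finite(s0) || s0 <= 0) s0 <- exp(mean(log(df$tf_concentration)))

  env <- list2env(list(C = df$tf_concentration, y = df$response, w = w,
                       target_conc = target_conc))
  fit <- switch(model,
    noncooperative = nls(y ~ C / (s05 + C), data = env,
                         start = list(s05 = s0), weights = w,
                         algorithm = "port", lower = c(s05 = 1e-12),
                         control = list(warnOnly = TRUE)),
    hill = nls(y ~ C^n / (s05^n + C^n), data = env,
               start = list(s05 = s0, n = 1), weights = w,
               algorithm = "port", lower = c(s05 = 1e-12, n = 0.05),
               control = list(warnOnly = TRUE)),
    depletion = {
      if (is.null(target_conc) || target_conc <= 0)
        stop("depletion model needs a positive `target_conc`", call. = FALSE)
      nls(y ~ ((C + target_conc + K) -
                 sqrt((C + target_conc + K)^2 - 4 * C * target_conc)) /
            (2 * target_conc),
          data = env, start = list(K = max(s0 - target_conc / 2, s0 * 1e-3)),
          weights = w, algorithm = "port", lower = c(K = 1e-12),
          control = list(warnOnly = TRUE))
    })
  est <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e)
    matrix(NA_real_, length(est), length(est)))
  if (model == "hill") {
    s05 <- est[["s05"]]; n <- est[["n"]]
    s05_se <- sqrt(vc[1L, 1L]); n_se <- sqrt(vc[2L, 2L])
  } else if (model == "noncooperative") {
    s05 <- est[["s05"]]; n <- 1; s05_se <- sqrt(vc[1L, 1L]); n_se <- 0
  } else {
    s05 <- est[["K"]]; n <- 1; s05_se <- sqrt(vc[1L, 1L]); n_se <- 0
  }
  structure(list(s05 = s05, s05_se = s05_se, hill_n = n, hill_n_se = n_se,
                 model = model, target_conc = target_conc,
                 fitted = function(C) binding_response(C, model, s05, n,
                                                       target_conc)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  lbl <- if (x$model == "depletion") "K_D" else "S_0.5"
  cat(sprintf("<binding_fit %s> %s = %.4g +/- %.3g nM",
              x$model, lbl, x$s05, x$s05_se))
  if (x$model == "hill")
    cat(sprintf(", Hill n = %.3g +/- %.3g", x$hill_n, x$hill_n_se))
  cat("\n")
  invisible(x)
}

#' Unmix a per-molecule intensity histogram into two reference components
#'
#' Models per-molecule mean intensities at one TF concentration as a
#' mixture of two *fixed* reference Gaussians -- the 0-TF distribution and
#' the saturating-TF distribution -- and estimates only the mixture weight
#' by maximum likelihood.  Fixing the reference shapes (rather than fitting
#' a free four-parameter double Gaussian) is what makes the high-peak area
#' fraction a direct occupancy readout.
#'
#' @param samples Per-molecule mean intensities at the concentration of
#'   interest.
#' @param ref_low,ref_high Numeric `c(mean, sd)` of the unbound and bound
#'   reference distributions (fitted from the 0-TF and saturating cohorts).
#' @param min_separation_sd Error if the reference means are closer than
#'   this many pooled sds (default 1).
#' @return List with `fraction_high`, `fraction_high_se` (observed-information),
#'   and `n`.
#' @export
intensity_histogram_unmix <- function(samples, ref_low, ref_high,
                                      min_separation_sd = 1) {
  stopifnot(length(ref_low) == 2L, length(ref_high) == 2L)
  if (abs(ref_high[1L] - ref_low[1L]) <
      min_separation_sd * mean(c(ref_low[2L], ref_high[2L])))
    stop("reference distributions are indistinguishable (mean separation below the sd-overlap criterion)",
         call. = FALSE)
  d_lo <- dnorm(samples, ref_low[1L], ref_low[2L])
  d_hi <- dnorm(samples, ref_high[1L], ref_high[2L])
  nll <- function(wgt) -sum(log(pmax(wgt * d_hi + (1 - wgt) * d_lo, 1e-300)))
  opt <- optimize(nll, interval = c(0, 1))
  w <- opt$minimum
  # observed information for the SE (finite difference)
  h <- 1e-4
  wc <- min(max(w, h), 1 - h)
  info <- (nll(wc + h) - 2 * nll(wc) + nll(wc - h)) / h^2
  se <- if (is.finite(info) && info > 0) sqrt(1 / info) else NA_real_
  list(fraction_high = w, fraction_high_se = se, n = length(samples))
}
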