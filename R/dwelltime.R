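#' Extract censoring-annotated dwell times from a state path
#'
#' Maximal constant-state runs of the path become dwells.  The first dwell
#' of a trace is left-censored (its start was not observed) and the last
#' dwell -- or the dwell truncated by photobleaching -- is right-censored:
#' both under-estimate the true dwell duration, so the default fitting
#' policy excludes them.  Dark (post-bleach) frames never form dwells.
#'
#' @param path A [state_path].
#' @param molecule_id Identifier recorded in the table.
#' @param tf_concentration TF concentration recorded in the table, nM.
#' @return A `dwell_table`: a data frame with columns `molecule_id`,
#'   `state`, `duration` (s), `left_censored`, `right_censored`, and
#'   attributes `dt` and `tf_concentration`.
#' @examples
#' p <- state_path(c("unbound", "unbound", "bound", "bound", "bound",
#'                   "unbound"), dt = 1, source = "inferred")
#' extract_dwells(p)
#' @export
extract_dwells <- function(path, molecule_id = "mol",
                           tf_concentration = NA_real_) {
  stopifnot(inherits(path, "state_path"))
  lab <- path$labels
  bleached <- any(lab == "dark")
  lab <- lab[lab != "dark"]
  if (length(lab) == 0L) {
    tab <- data.frame(molecule_id = character(), state = character(),
                      duration = numeric(), left_censored = logical(),
                      right_censored = logical(), stringsAsFactors = FALSE)
  } else {
    r <- rle(lab)
    k <- length(r$lengths)
    tab <- data.frame(
      molecule_id = rep(molecule_id, k),
      state = r$values,
      duration = r$lengths * path$dt,
      left_censored = seq_len(k) == 1L,
      # the final run is truncated by acquisition end or by bleaching
      right_censored = seq_len(k) == k,
      stringsAsFactors = FALSE)
  }
  structure(tab, dt = path$dt, tf_concentration = tf_concentration,
            class = c("dwell_table", "data.frame"))
}

#' Combine dwell tables from several molecules
#'
#' @param ... `dwell_table` objects (or a single list of them).
#' @return A `dwell_table` with a common `dt`.
#' @export
bind_dwells <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && !inherits(tabs[[1L]], "dwell_table"))
    tabs <- tabs[[1L]]
  dts <- unique(vapply(tabs, function(t) attr(t, "dt"), 1))
  if (length(dts) != 1L) stop("dwell tables disagree on `dt`", call. = FALSE)
  conc <- unique(vapply(tabs, function(t) attr(t, "tf_concentration"), 1))
  out <- do.call(rbind, lapply(tabs, as.data.frame))
  structure(out, dt = dts,
            tf_concentration = if (length(conc) == 1L) conc else NA_real_,
            class = c("dwell_table", "data.frame"))
}

#' Complete (uncensored) dwell durations for one state
#'
#' @param dwells A `dwell_table`.
#' @param state `"bound"` or `"unbound"`.
#' @param include_censored Include left/right-censored dwells (used only to
#'   demonstrate the downward bias this causes; default `FALSE`).
#' @return Numeric vector of durations, s.
#' @export
complete_dwells <- function(dwells, state, include_censored = FALSE) {
  sel <- dwells$state == state
  if (!include_censored)
    sel <- sel & !dwells$left_censored & !dwells$right_censored
  dwells$duration[sel]
}

exp_fit <- function(tau, tau_se, amplitude = NA_real_, method, n_dwells,
                    min_dwells = 20L) {
  structure(list(tau = tau, tau_se = tau_se, amplitude = amplitude,
                 method = method, n_dwells = n_dwells,
                 low_confidence = n_dwells < min_dwells),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit %s> tau = %.4g +/- %.3g s (n = %d%s)\n",
              x$method, x$tau, x$tau_se, x$n_dwells,
              if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  invisible(x)
}

#' Maximum-likelihood exponential fit of dwell durations
#'
#' For exponentially distributed durations the MLE of the characteristic
#' time is the sample mean, with standard error `tau / sqrt(n)`.  Used as
#' the cross-check for the histogram fit.
#'
#' @param durations Positive dwell durations, s.
#' @param min_dwells Below this count the fit is flagged low-confidence
#'   (default 20).
#' @param truncation Left-truncation point, s: when only dwells longer than
#'   a detection deadtime are observable, the exponential's memorylessness
#'   gives `E[duration] = truncation + tau`, so the MLE is
#'   `mean(durations) - truncation`.  Default 0 (no truncation).
#' @return An `exp_fit` with `method = "mle"`.
#' @export
fit_exponential_mle <- function(durations, min_dwells = 20L, truncation = 0) {
  if (length(durations) == 0L)
    stop("no dwell durations supplied", call. = FALSE)
  if (any(!is.finite(durations) | durations <= 0))
    stop("durations must be positive and finite", call. = FALSE)
  tau <- max(mean(durations) - truncation, min(durations) * 1e-3)
  exp_fit(tau, tau / sqrt(length(durations)), method = "mle",
          n_dwells = length(durations), min_dwells = min_dwells)
}

#' Weighted-histogram exponential fit of dwell durations
#'
#' Bins the durations and fits counts to `A * exp(-t / tau)` at the bin
#' centers by weighted least squares, mirroring the weighted dwell-time
#' histogram fits used experimentally.  Each non-empty bin gets Poisson
#' weight (sigma_i = sqrt(count)); empty bins are excluded.  The default
#' bin width is `max(dt, tau_init / 10)` with `tau_init` from the MLE,
#' which keeps the fit stable and makes the two estimators
#' cross-validating.
#'
#' @param durations Positive dwell durations, s.
#' @param bin_width Histogram bin width, s (>= `dt` when supplied).
#' @param dt Frame time, s (used for the default bin width; default is the
#'   smallest duration).
#' @param min_bins Minimum number of non-empty bins (default 3); fewer is
#'   an error (under-determined fit).
#' @param min_dwells Low-confidence threshold, as in
#'   [fit_exponential_mle()].
#' @return An `exp_fit` with `method = "weighted_histogram"` and the fitted
#'   amplitude.
#' @export
fit_exponential_histogram <- function(durations, bin_width = NULL, dt = NULL,
                                      min_bins = 3L, min_dwells = 20L) {
  if (length(durations) == 0L)
    stop("no dwell durations supplied", call. = FALSE)
  if (is.null(dt)) dt <- min(durations)
  tau_init <- mean(durations)
  if (is.null(bin_width)) bin_width <- max(dt, tau_init / 10)
  if (bin_width < dt) stop("`bin_width` must be >= dt", call. = FALSE)

  breaks <- seq(0, max(durations) + bin_width, by = bin_width)
  counts <- tabulate(findInterval(durations, breaks, left.open = TRUE),
                     nbins = length(breaks) - 1L)
  centers <- breaks[-length(breaks)] + bin_width / 2
  keep <- counts > 0
  centers <- centers[keep]; counts <- counts[keep]
  if (length(counts) < min_bins)
    stop(sprintf("only %d non-empty bins (< %d): exponential fit is under-determined",
                 length(counts), min_bins), call. = FALSE)
  fit <- fit_exp_to_histogram(centers, counts)
  exp_fit(fit$tau, fit$tau_se, amplitude = fit$amplitude,
          method = "weighted_histogram", n_dwells = length(durations),
          min_dwells = min_dwells)
}

#' Censoring-aware exponential MLE from a dwell table
#'
#' The maximum-likelihood estimate of an exponential characteristic time
#' under right censoring is the total observed time in the state divided by
#' the number of observed exits from it: censored dwells contribute
#' exposure to the numerator but no event to the denominator.
#' Left-censored (trace-initial) dwells of an exponential state are
#' themselves exponential by memorylessness, so they enter like complete
#' dwells.  This removes the downward window bias that affects
#' complete-dwell-only estimators whenever dwell times are not tiny
#' relative to the acquisition window.  An optional left-truncation offset
#' (detection deadtime) is subtracted, as in [fit_exponential_mle()].
#'
#' @param dwells A `dwell_table` (see [extract_dwells()]).
#' @param state `"bound"` or `"unbound"`.
#' @param truncation Detection deadtime, s (default 0).
#' @param min_dwells Low-confidence threshold on the exit count.
#' @return An `exp_fit` with `method = "censored_mle"`; `n_dwells` is the
#'   number of observed exits.
#' @export
fit_exponential_censored <- function(dwells, state, truncation = 0,
                                     min_dwells = 20L) {
  sel <- dwells$state == state
  if (!any(sel)) stop("no dwells in state ", state, call. = FALSE)
  total <- sum(dwells$duration[sel])
  exits <- sum(sel & !dwells$right_censored)
  if (exits == 0)
    stop("no observed exits from state ", state,
         ": tau is unidentified (see koff_upper_bound_from_survival)",
         call. = FALSE)
  tau <- max(total / exits - truncation, min(dwells$duration[sel]) * 1e-3)
  exp_fit(tau, tau / sqrt(exits), method = "censored_mle",
          n_dwells = exits, min_dwells = min_dwells)
}

#' Correct dwell-time estimates for missed short events
#'
#' Frame binning and the minimum-event floor impose a detection deadtime:
#' sojourns in one state shorter than the deadtime are not detected, so the
#' flanking dwells of the *other* state are concatenated and its apparent
#' characteristic time inflates by roughly `1 / (1 - p_miss)`.  For
#' alternating exponential dwells the observed times satisfy
#'
#' \deqn{\tau_b^{obs} = (\tau_b + p_u g_u) / (1 - p_u),}
#'
#' (and symmetrically for the unbound state), where
#' `p_u = 1 - exp(-t_d / tau_u)` is the probability an unbound sojourn is
#' shorter than the deadtime `t_d` and `g_u = E[u | u < t_d]` is the mean
#' missed gap.  This function inverts that pair of relations by fixed-point
#' iteration, the standard analytic missed-event correction for an imposed
#' deadtime.  With the default idealization (majority-vote frame binning
#' plus a 2-frame minimum event) the effective imposed deadtime is about
#' 1.5 frame times.
#'
#' @param tau_bound_obs,tau_unbound_obs Observed (apparent) characteristic
#'   times, s.
#' @param deadtime Imposed detection deadtime, s (0 disables the
#'   correction).
#' @param max_iter,tol Fixed-point controls.
#' @return List with `tau_bound`, `tau_unbound` (corrected),
#'   `p_miss_bound`, `p_miss_unbound`, and `reliable` (`FALSE` when more
#'   than 90\% of either state's events are estimated missed, where the
#'   inversion degenerates).
#' @export
correct_missed_events <- function(tau_bound_obs, tau_unbound_obs, deadtime,
                                  max_iter = 100L, tol = 1e-12) {
  stopifnot(tau_bound_obs > 0, tau_unbound_obs > 0, deadtime >= 0)
  if (deadtime == 0)
    return(list(tau_bound = tau_bound_obs, tau_unbound = tau_unbound_obs,
                p_miss_bound = 0, p_miss_unbound = 0, reliable = TRUE))
  pmiss <- function(tau) 1 - exp(-deadtime / tau)
  gap <- function(tau) {         # E[dwell | dwell < deadtime]
    p <- pmiss(tau)
    tau - deadtime * exp(-deadtime / tau) / p
  }
  tb <- tau_bound_obs; tu <- tau_unbound_obs
  for (i in seq_len(max_iter)) {
    pu <- pmiss(tu); pb <- pmiss(tb)
    tb_new <- max(tau_bound_obs * (1 - pu) - pu * gap(tu), deadtime * 1e-3)
    tu_new <- max(tau_unbound_obs * (1 - pb) - pb * gap(tb), deadtime * 1e-3)
    if (abs(tb_new - tb) < tol * tb && abs(tu_new - tu) < tol * tu) {
      tb <- tb_new; tu <- tu_new; break
    }
    tb <- tb_new; tu <- tu_new
  }
  pu <- pmiss(tu); pb <- pmiss(tb)
  list(tau_bound = tb, tau_unbound = tu,
       p_miss_bound = pb, p_miss_unbound = pu,
       reliable = pu < 0.9 && pb < 0.9)
}

#' Fit `A * exp(-t / tau)` to histogram counts by weighted least squares
#'
#' Lower-level worker for [fit_exponential_histogram()]; also usable on
#' hand-built histograms.  Weights are Poisson (`sigma_i = sqrt(count)`).
#'
#' @param centers Bin centers, s.
#' @param counts Positive counts per bin.
#' @return List with `tau`, `tau_se`, `amplitude`, `amplitude_se`.
#' @export
fit_exp_to_histogram <- function(centers, counts) {
  stopifnot(length(centers) == length(counts), all(counts > 0))
  # weighted log-linear regression gives exact starting values (and the
  # exact solution when the model can interpolate the points)
  w <- counts  # var(log y) ~ 1/y for Poisson counts
  lf <- stats::lm(log(counts) ~ centers, weights = w)
  tau0 <- -1 / coef(lf)[[2L]]
  A0 <- exp(coef(lf)[[1L]])
  if (!is.finite(tau0) || tau0 <= 0) { tau0 <- mean(centers); A0 <- max(counts) }
  df <- data.frame(t = centers, y = counts)
  fit <- tryCatch(
    nls(y ~ A * exp(-t / tau), data = df, start = list(A = A0, tau = tau0),
        weights = 1 / counts, control = list(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    se <- summary(lf)$coefficients[2L, 2L] * tau0^2
    return(list(tau = tau0, tau_se = se, amplitude = A0,
                amplitude_se = NA_real_))
  }
  est <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2L, 2L))
  list(tau = est[["tau"]], tau_se = sqrt(vc[2L, 2L]),
       amplitude = est[["A"]], amplitude_se = sqrt(vc[1L, 1L]))
}
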