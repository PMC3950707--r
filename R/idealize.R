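#' Detect photobleaching in a trace
#'
#' Finds the earliest frame after which the total intensity stays below a
#' dark threshold for the remainder of the trace.  Detection runs on a
#' centered running median of the total intensity (window `smooth_window`
#' frames) so single noisy frames cannot mask or fake a bleach; the running
#' median crosses the threshold within about one frame of the true dark
#' transition.  The threshold is `dark_fraction` times the bright level
#' (median of the upper half of the smoothed intensity), and at least
#' `min_dark_frames` consecutive terminal dark frames are required.
#'
#' @param trace An [sm_trace].
#' @param dark_fraction Threshold as a fraction of the bright level
#'   (default 0.2).
#' @param min_dark_frames Minimum length of the terminal dark block
#'   (default 50 frames).
#' @param smooth_window Running-median window, frames (odd; default 25).
#' @return 1-based index of the first dark frame, or `NULL` if no bleach is
#'   detected.  An all-dark trace returns 1.
#' @export
detect_bleach <- function(trace, dark_fraction = 0.2, min_dark_frames = 50L,
                          smooth_window = 25L) {
  stopifnot(inherits(trace, "sm_trace"))
  total <- if (trace$modality == "PIFE") trace$channels$cy3
           else trace$channels$donor + trace$channels$acceptor
  n <- length(total)
  k <- min(as.integer(smooth_window), if (n %% 2L == 0L) n - 1L else n)
  if (k < 1L) k <- 1L
  if (k %% 2L == 0L) k <- k - 1L
  sm <- if (k >= 3L) stats::runmed(total, k, endrule = "median") else total
  # bright level from a high quantile so that traces that bleach early
  # (majority dark) still yield the pre-bleach level; frame-to-frame
  # differences give a noise scale to recognize all-dark traces
  bright <- quantile(sm, 0.99, names = FALSE, type = 7)
  noise <- stats::mad(diff(total)) / sqrt(2)
  if (!is.finite(bright) || bright <= max(2 * noise, .Machine$double.eps))
    return(1L)  # all-dark trace
  thr <- dark_fraction * bright
  above <- sm >= thr
  if (all(!above)) return(1L)
  last_bright <- max(which(above))
  if (last_bright >= n) return(NULL)
  n_dark <- n - last_bright
  if (n_dark < min_dark_frames) return(NULL)
  last_bright + 1L
}

#' Emission model of a two-state idealization
#'
#' @param means,sds Per-state observable mean and sd, ordered
#'   (unbound, bound).
#' @param trans 2x2 transition probability matrix (rows: from
#'   unbound/bound).
#' @param init Initial state probabilities.
#' @param log_likelihood Final EM log-likelihood.
#' @param bleach_frame Optional first dark frame (1-based) or `NULL`.
#' @param converged Did EM converge within the iteration cap?
#' @param degenerate `TRUE` when the two fitted levels were
#'   indistinguishable (sd-overlap criterion) and a zero-transition path
#'   was returned.
#' @return An object of class `emission_model`.
#' @export
emission_model <- function(means, sds, trans, init, log_likelihood,
                           bleach_frame = NULL, converged = TRUE,
                           degenerate = FALSE) {
  stopifnot(all(sds > 0))
  structure(list(means = means, sds = sds, trans = trans, init = init,
                 log_likelihood = log_likelihood, bleach_frame = bleach_frame,
                 converged = converged, degenerate = degenerate),
            class = "emission_model")
}

#' @export
print.emission_model <- function(x, ...) {
  cat("<emission_model>\n")
  cat(sprintf("  unbound: mean %.4g (sd %.3g); bound: mean %.4g (sd %.3g)\n",
              x$means[1L], x$sds[1L], x$means[2L], x$sds[2L]))
  cat(sprintf("  logLik %.2f, converged: %s, degenerate: %s\n",
              x$log_likelihood, x$converged, x$degenerate))
  invisible(x)
}

#' Idealize a trace to a two-state step function
#'
#' Fits a two-state Gaussian-emission hidden Markov model to the trace
#' observable (Cy3 intensity for PIFE, proximity ratio for FRET) by
#' expectation-maximization, then decodes the most probable state sequence
#' with the Viterbi algorithm.  A maximum-likelihood HMM with a hard
#' two-state constraint stands in for variational-Bayes step fitting: the
#' deliverable is the two-state step function, and ML is deterministic and
#' directly verifiable.  Initialization is a median split of the
#' observable; EM stops when the log-likelihood changes by less than `tol`
#' or after `max_iter` iterations.  Frames after a detected photobleach are
#' excluded from fitting and labeled `"dark"`.  States are labeled by the
#' modality's ordering rule: the bound state has the higher Cy3 mean
#' (PIFE) or the lower proximity ratio (FRET).  Inferred dwells shorter
#' than `min_event_frames` frames are merged into the flanking state to
#' guard against noise-induced spurious transitions.  If the two fitted
#' levels overlap (separation below `min_separation_sd` times the mean sd),
#' a zero-transition path in the majority state is returned with the
#' `degenerate` flag set -- not an error, since non-fluctuating molecules
#' are expected.
#'
#' @param trace An [sm_trace] with at least 10 frames.
#' @param max_iter EM iteration cap (default 500).
#' @param tol EM log-likelihood tolerance (default 1e-6).
#' @param min_event_frames Minimum event length in frames (default 2).
#' @param min_separation_sd Level-separation floor in pooled-sd units
#'   (default 1).
#' @param shared_sd Share a single emission sd across the two states
#'   (default `TRUE`).  The per-frame noise is detector noise and does not
#'   depend on the binding state; tying the sds also prevents EM from
#'   collapsing onto a wide outlier component when one state is rare.
#' @param bleach_args List of arguments for [detect_bleach()].
#' @return A list with components `path` (a [state_path] with
#'   `source = "inferred"`) and `model` (an [emission_model]).
#' @examples
#' cfg <- sim_config(duration = 50, tf_concentration = 10, k_off = 0.2,
#'                   bleach_rate = 0, seed = 1)
#' p <- simulate_state_path(cfg$k_on * 10, cfg$k_off, 50, cfg$dt, seed = 2)
#' tr <- render_trace(p, cfg, seed = 3)
#' ideal <- idealize_two_state(tr)
#' mean(ideal$path$labels == p$labels)
#' @export
idealize_two_state <- function(trace, max_iter = 500L, tol = 1e-6,
                               min_event_frames = 2L, min_separation_sd = 1,
                               shared_sd = TRUE, bleach_args = list()) {
  stopifnot(inherits(trace, "sm_trace"))
  obs_full <- trace_observable(trace)
  n <- length(obs_full)
  if (n < 10L) stop("trace too short to idealize (< 10 frames)", call. = FALSE)

  bleach <- do.call(detect_bleach, c(list(trace), bleach_args))
  live <- if (is.null(bleach)) seq_len(n) else seq_len(bleach - 1L)
  if (length(live) < 10L) {
    # effectively all dark: nothing to analyze
    lab <- rep("dark", n)
    if (length(live)) lab[live] <- "unbound"
    mdl <- emission_model(c(0, 0) + c(0, 1e-6), c(1e-6, 1e-6),
                          diag(2), c(1, 0), -Inf,
                          bleach_frame = bleach, degenerate = TRUE)
    return(list(path = state_path(lab, trace$dt, "inferred"), model = mdl))
  }
  obs <- obs_full[live]

  # initialization: two-cluster split at the midpoint of the robust range.
  # A plain median split fails when one state is rare (e.g. 4% occupancy);
  # the 1%/99% quantile midpoint finds a rare level as long as it occupies
  # >~1% of frames.
  thr <- mean(quantile(obs, c(0.01, 0.99), names = FALSE, type = 7))
  lo <- obs[obs <= thr]; hi <- obs[obs > thr]
  if (!length(hi)) hi <- lo
  if (!length(lo)) lo <- hi
  mu0 <- c(mean(lo), mean(hi))
  sd_all <- sd(obs)
  sd_floor <- max(sd_all * 1e-3, .Machine$double.eps * 100)
  sd0 <- pmax(c(sd(lo), sd(hi)), sd_floor)
  sd0[!is.finite(sd0)] <- sd_floor
  if (diff(mu0) < sd_floor) mu0[2L] <- mu0[1L] + sd_floor
  trans0 <- matrix(c(0.95, 0.05, 0.05, 0.95), 2L, 2L)
  init0 <- c(0.5, 0.5)

  fit <- hmm_em_cpp(obs, mu0, sd0, trans0, init0,
                    as.integer(max_iter), tol, sd_floor, isTRUE(shared_sd))
  mu <- fit$mu; sds <- pmax(fit$sd, sd_floor)

  # Distinguishable levels?  Three guards, all of which a genuine two-state
  # trace passes by a wide margin:
  #  (i)  sd-overlap: level separation in pooled-sd units;
  #  (ii) BIC against a single Gaussian -- a noise-only trace gains almost
  #       no likelihood from a second HMM state, a real one gains hundreds;
  #  (iii) FRET only: both state means must be plausible proximity ratios
  #       (the heavy tails of the ratio sit outside [0, 1], and EM
  #       occasionally latches onto them).
  sep <- abs(diff(mu)) / mean(sds)
  ll1 <- sum(dnorm(obs, mean(obs), sd(obs), log = TRUE))
  two_state_supported <- is.finite(sep) && sep >= min_separation_sd &&
    (fit$loglik - ll1) >= 2 * log(length(obs)) &&
    (trace$modality == "PIFE" || all(mu > -0.05 & mu < 1.05))
  if (!two_state_supported) {
    maj <- "unbound"  # a single-level trace shows no binding events
    lab <- rep(maj, n)
    if (!is.null(bleach)) lab[seq.int(bleach, n)] <- "dark"
    mdl <- emission_model(sort(mu), sds, fit$trans, fit$init, fit$loglik,
                          bleach_frame = bleach, converged = fit$converged,
                          degenerate = TRUE)
    return(list(path = state_path(lab, trace$dt, "inferred"), model = mdl))
  }

  vit <- hmm_viterbi_cpp(obs, mu, sds, fit$trans, fit$init)  # 0-based comp idx
  # modality ordering rule: bound = higher Cy3 (PIFE), lower ratio (FRET)
  bound_comp <- if (trace$modality == "PIFE") which.max(mu) else which.min(mu)
  lab_live <- ifelse(vit + 1L == bound_comp, "bound", "unbound")
  lab_live <- merge_short_events(lab_live, min_event_frames)

  lab <- rep("dark", n)
  lab[live] <- lab_live
  means <- mu[c(3L - bound_comp, bound_comp)]  # (unbound, bound)
  sdv <- sds[c(3L - bound_comp, bound_comp)]
  mdl <- emission_model(means, sdv, fit$trans, fit$init, fit$loglik,
                        bleach_frame = bleach, converged = fit$converged,
                        degenerate = FALSE)
  if (!fit$converged)
    attr(mdl, "flagged") <- "EM did not converge within the iteration cap"
  list(path = state_path(lab, trace$dt, "inferred"), model = mdl)
}

# Merge runs shorter than `min_len` frames into the flanking state (both
# neighbors share a state in a two-state path).  Single left-to-right
# absorb pass per iteration, O(n) each; converges in a handful of passes
# even on noise-dominated paths with thousands of 1-frame runs.
merge_short_events <- function(labels, min_len) {
  if (min_len <= 1L) return(labels)
  repeat {
    r <- rle(labels)
    k <- length(r$lengths)
    if (k <= 1L || all(r$lengths >= min_len)) return(labels)
    vals <- r$values; lens <- r$lengths
    if (lens[1L] < min_len) {      # leading short run: absorb rightward
      vals[1L] <- vals[2L]
      labels <- rep.int(vals, lens)
      next
    }
    new_vals <- character(k); new_lens <- integer(k)
    m <- 1L
    new_vals[1L] <- vals[1L]; new_lens[1L] <- lens[1L]
    for (i in 2:k) {
      if (lens[i] < min_len || vals[i] == new_vals[m]) {
        new_lens[m] <- new_lens[m] + lens[i]   # absorb into left neighbor
      } else {
        m <- m + 1L
        new_vals[m] <- vals[i]; new_lens[m] <- lens[i]
      }
    }
    labels <- rep.int(new_vals[seq_len(m)], new_lens[seq_len(m)])
  }
}

#' Select analyzable molecules from an idealized cohort
#'
#' Keeps traces that (i) passed the Cy5 colocalization check
#' (`colocalized_acceptor`) and (ii) fluctuate, i.e. show at least one
#' transition in the inferred path.  Mirrors the experimental bookkeeping
#' in which only colocalized, fluctuating molecules enter the dwell-time
#' histograms, and the fluctuating fraction itself is reported.
#'
#' @param traces List of [sm_trace] objects.
#' @param ideals List of idealization results (as returned by
#'   [idealize_two_state()]), parallel to `traces`.
#' @return A list with `traces`, `paths` (selected subsets),
#'   `fluctuating_fraction` (fluctuating / colocalized), `n_colocalized`,
#'   and `excluded` (data frame of molecule_id + reason).
#' @export
select_molecules <- function(traces, ideals) {
  if (length(traces) == 0L) stop("empty cohort", call. = FALSE)
  if (length(traces) != length(ideals))
    stop("`traces` and `ideals` must be parallel lists", call. = FALSE)
  coloc <- vapply(traces, function(tr) tr$colocalized_acceptor, TRUE)
  n_trans <- vapply(ideals, function(id) nrow(transitions(id$path)), 1L)
  fluct <- n_trans >= 1L
  keep <- coloc & fluct
  reason <- ifelse(!coloc, "no_colocalized_acceptor",
                   ifelse(!fluct, "no_fluctuations", NA_character_))
  excluded <- data.frame(
    molecule_id = vapply(traces[!keep], function(tr) tr$molecule_id, ""),
    reason = reason[!keep], stringsAsFactors = FALSE)
  list(traces = traces[keep],
       paths = lapply(ideals[keep], function(id) id$path),
       fluctuating_fraction = if (any(coloc)) mean(fluct[coloc]) else NA_real_,
       n_colocalized = sum(coloc),
       excluded = excluded)
}
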