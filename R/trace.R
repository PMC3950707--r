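#' Single-molecule fluorescence traces
#'
#' An `sm_trace` holds one molecule's per-frame intensity series: a single
#' Cy3 channel for PIFE, or a donor/acceptor pair for FRET, together with
#' the frame time, the TF concentration at acquisition, an identifier, and
#' a flag recording whether a colocalized Cy5 acceptor was found under
#' direct 638-nm excitation (molecules failing that check are discarded by
#' [select_molecules()]).  Synthetic traces also carry their generator
#' ground-truth [state_path].
#'
#' @param channels Named list of equal-length numeric vectors: `cy3` for
#'   PIFE, `donor` and `acceptor` for FRET.
#' @param dt Frame time, s.
#' @param modality `"PIFE"` or `"FRET"`.
#' @param tf_concentration TF concentration, nM.
#' @param molecule_id Identifier string.
#' @param colocalized_acceptor Logical; passed the Cy5 colocalization check.
#' @param ground_truth Optional ground-truth [state_path].
#' @return An object of class `sm_trace`.
#' @export
sm_trace <- function(channels, dt, modality = c("PIFE", "FRET"),
                     tf_concentration = NA_real_, molecule_id = "mol",
                     colocalized_acceptor = TRUE, ground_truth = NULL) {
  modality <- match.arg(modality)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  want <- if (modality == "PIFE") "cy3" else c("donor", "acceptor")
  if (!all(want %in% names(channels)))
    stop("channels for ", modality, " must include: ",
         paste(want, collapse = ", "), call. = FALSE)
  channels <- channels[want]
  len <- vapply(channels, length, 1L)
  if (length(unique(len)) != 1L)
    stop("all channel series must have equal length", call. = FALSE)
  if (!all(vapply(channels, function(ch) all(is.finite(ch)), TRUE)))
    stop("intensities must be finite", call. = FALSE)
  structure(list(channels = channels, dt = dt, modality = modality,
                 tf_concentration = tf_concentration,
                 molecule_id = molecule_id,
                 colocalized_acceptor = isTRUE(colocalized_acceptor),
                 ground_truth = ground_truth),
            class = "sm_trace")
}

#' @export
print.sm_trace <- function(x, ...) {
  cat(sprintf("<sm_trace %s> %s, %d frames (dt = %g s), [TF] = %g nM\n",
              x$molecule_id, x$modality, length(x$channels[[1L]]), x$dt,
              x$tf_concentration))
  invisible(x)
}

#' Per-frame observable used for idealization
#'
#' PIFE: the Cy3 intensity. FRET: the uncorrected proximity ratio
#' `acceptor / (donor + acceptor)` (no gamma correction; the correction
#' factors are identity hooks).  The denominator is floored at half the
#' median total intensity: frames whose total dips far below the typical
#' photon budget carry no usable FRET information, and an unregularized
#' ratio there has heavy tails that destabilize emission-model fitting.
#'
#' @param trace An [sm_trace].
#' @return Numeric vector, one value per frame.
#' @export
trace_observable <- function(trace) {
  stopifnot(inherits(trace, "sm_trace"))
  if (trace$modality == "PIFE") {
    trace$channels$cy3
  } else {
    tot <- trace$channels$donor + trace$channels$acceptor
    floor_tot <- max(0.5 * median(tot), .Machine$double.eps)
    trace$channels$acceptor / pmax(tot, floor_tot)
  }
}

#' Render a state path as a noisy fluorescence trace
#'
#' Converts a [state_path] to per-frame channel intensities under the
#' configured modality.  PIFE: Cy3 mean is `total_intensity` when unbound
#' and `total_intensity * pife_enhancement` when bound.  FRET: acceptor
#' mean is `E_state * total_intensity` and donor mean is
#' `(1 - E_state) * total_intensity`.  Independent Gaussian noise of sd
#' `noise_sd` is added per frame and channel.  A single exponential
#' photobleach time (rate `bleach_rate`) truncates the signal: frames whose
#' midpoint falls after the bleach time have mean zero in every channel
#' (noise remains), and the attached ground truth marks them `"dark"`.
#'
#' @param path A [state_path] (ground truth).
#' @param config A [sim_config]; must share `dt` with `path`.
#' @param seed Optional integer seed.
#' @param bleach_time Override the random bleach time with a fixed value in
#'   seconds (`Inf` disables bleaching regardless of `bleach_rate`).
#' @return An [sm_trace] with `ground_truth` attached.
#' @export
render_trace <- function(path, config, seed = NULL, bleach_time = NULL) {
  stopifnot(inherits(path, "state_path"))
  config <- validate_sim_config(config)
  if (abs(path$dt - config$dt) > 1e-12)
    stop("`path` and `config` disagree on the frame time `dt`", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n <- length(path$labels)
  if (is.null(bleach_time)) {
    bleach_time <- if (config$bleach_rate > 0)
      rexp(1, rate = config$bleach_rate) else Inf
  }
  mid <- (seq_len(n) - 0.5) * config$dt
  dark <- mid > bleach_time
  bound <- path$labels == "bound" & !dark

  labels <- path$labels
  labels[dark] <- "dark"
  gt <- state_path(labels, dt = path$dt, source = "ground_truth",
                   event_times = path$event_times)

  noise <- function() rnorm(n, sd = config$noise_sd)
  if (config$modality == "PIFE") {
    mu <- ifelse(bound, config$total_intensity * config$pife_enhancement,
                 config$total_intensity)
    mu[dark] <- 0
    channels <- list(cy3 = mu + noise())
  } else {
    E <- ifelse(bound, config$E_bound, config$E_unbound)
    acc <- E * config$total_intensity
    don <- (1 - E) * config$total_intensity
    acc[dark] <- 0
    don[dark] <- 0
    channels <- list(donor = don + noise(), acceptor = acc + noise())
  }
  sm_trace(channels, dt = config$dt, modality = config$modality,
           tf_concentration = config$tf_concentration,
           ground_truth = gt)
}

#' Simulate a cohort of traces over a concentration grid
#'
#' Generates `n_molecules` independent traces at each TF concentration.
#' Each molecule is flagged inactive with probability
#' `config$inactive_fraction`; inactive molecules never bind (effective
#' on-rate 0), emulating the non-fluctuating molecules seen in real
#' acquisitions.  Per-molecule seeds are derived deterministically from
#' `seed`, so identical seeds reproduce identical cohorts bit for bit.
#'
#' @param config A [sim_config] (its `tf_concentration` is overridden by
#'   the grid).
#' @param concentrations Numeric vector of TF concentrations, nM.
#' @param n_molecules Molecules per concentration (>= 1).
#' @param seed Integer master seed.
#' @param initial_state Passed to [simulate_state_path()]; `NULL` draws the
#'   initial state from equilibrium.
#' @return A list of [sm_trace] objects with attributes `manifest` (data
#'   frame: molecule_id, concentration, seed, inactive) and `config`.
#' @export
simulate_cohort <- function(config, concentrations, n_molecules,
                            seed = 1L, initial_state = NULL) {
  config <- validate_sim_config(config)
  if (length(concentrations) < 1L)
    stop("`concentrations` must be non-empty", call. = FALSE)
  if (any(concentrations < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (n_molecules < 1L) stop("`n_molecules` must be >= 1", call. = FALSE)

  grid <- expand.grid(mol = seq_len(n_molecules), conc = concentrations,
                      KEEP.OUT.ATTRS = FALSE)
  n_tot <- nrow(grid)
  set.seed(seed)
  mol_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  inactive <- runif(n_tot) < config$inactive_fraction

  traces <- vector("list", n_tot)
  ids <- sprintf("mol_%03d_c%g", grid$mol, grid$conc)
  for (i in seq_len(n_tot)) {
    traces[[i]] <- simulate_one_molecule(config, grid$conc[i], mol_seeds[i],
                                         inactive[i], initial_state, ids[i])
  }
  manifest <- data.frame(molecule_id = ids, concentration = grid$conc,
                         seed = mol_seeds, inactive = inactive,
                         stringsAsFactors = FALSE)
  structure(traces, manifest = manifest, config = config,
            class = c("sm_cohort", "list"))
}

# One molecule of a cohort: seeded path simulation + rendering.  Inactive
# molecules never bind (effective on-rate 0, start unbound).
simulate_one_molecule <- function(config, conc, mol_seed, inactive,
                                  initial_state, molecule_id) {
  cfg <- config
  cfg$tf_concentration <- conc
  k_eff <- if (inactive) 0 else cfg$k_on * conc
  init <- if (inactive) "unbound" else initial_state
  set.seed(mol_seed)
  path <- simulate_state_path(k_eff, cfg$k_off, cfg$duration, cfg$dt,
                              initial_state = init)
  tr <- render_trace(path, cfg)
  tr$molecule_id <- molecule_id
  tr
}

#' @export
print.sm_cohort <- function(x, ...) {
  m <- attr(x, "manifest")
  cat(sprintf("<sm_cohort> %d traces, %d concentrations (%s nM)\n",
              length(x), length(unique(m$concentration)),
              paste(sort(unique(m$concentration)), collapse = ", ")))
  invisible(x)
}
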