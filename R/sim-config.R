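#' Simulation configuration for synthetic smTIRF traces
#'
#' Bundles every knob of the synthetic trace generator.  Defaults describe a
#' typical smTIRF acquisition: 50-ms frames, FRET efficiency ~0.8 for the
#' fully wrapped (TF-unbound) nucleosome dropping to ~0.2 when the TF traps
#' the partially unwrapped state, and intensities scaled so the PIFE level
#' separation over noise (SNR) is 3 -- strong enough to idealize reliably,
#' weak enough that idealization is actually exercised.
#'
#' @param dt Frame time in seconds.
#' @param k_on Intrinsic binding rate constant, s^-1 nM^-1.
#' @param k_off Dissociation rate constant, s^-1.
#' @param tf_concentration TF concentration in nM; the effective on-rate is
#'   `k_on * tf_concentration`.
#' @param duration Trace duration in seconds.
#' @param modality `"PIFE"` (single Cy3 channel whose mean steps up on
#'   binding) or `"FRET"` (donor/acceptor channel pair).
#' @param E_unbound,E_bound FRET efficiencies of the unbound and TF-bound
#'   states (dimensionless, `0 <= E_bound < E_unbound <= 1`).
#' @param pife_enhancement Fold change of the Cy3 mean upon binding (> 1).
#' @param total_intensity Total emission level in arbitrary units; for FRET
#'   this is donor + acceptor.
#' @param noise_sd Per-frame, per-channel Gaussian noise standard deviation,
#'   same units as `total_intensity`.
#' @param bleach_rate Exponential photobleaching rate, s^-1; a single bleach
#'   time truncates the whole trace to a dark level.
#' @param inactive_fraction Probability that a molecule never binds (damaged
#'   molecule or missing target site), in \[0, 1\].
#' @param labeling_efficiency Probability that each of the two acceptor
#'   sites carries a functional dye, in \[0, 1\].
#' @param seed Optional integer seed recorded in the config.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(k_on = 0.05, k_off = 3.4e-3, tf_concentration = 0.3)
#' cfg$dt
#' @export
sim_config <- function(dt = 0.05,
                       k_on = 0.05,
                       k_off = 3.4e-3,
                       tf_concentration = 1,
                       duration = 2000,
                       modality = c("PIFE", "FRET"),
                       E_unbound = 0.8,
                       E_bound = 0.2,
                       pife_enhancement = 1.5,
                       total_intensity = 1000,
                       noise_sd = 167,
                       bleach_rate = 1e-4,
                       inactive_fraction = 0,
                       labeling_efficiency = 0.88,
                       seed = NULL) {
  modality <- match.arg(modality)
  cfg <- structure(list(
    dt = dt, k_on = k_on, k_off = k_off,
    tf_concentration = tf_concentration, duration = duration,
    modality = modality, E_unbound = E_unbound, E_bound = E_bound,
    pife_enhancement = pife_enhancement, total_intensity = total_intensity,
    noise_sd = noise_sd, bleach_rate = bleach_rate,
    inactive_fraction = inactive_fraction,
    labeling_efficiency = labeling_efficiency, seed = seed
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$dt) || cfg$dt <= 0)
    stop("`dt` must be a positive finite number (frame time in s)", call. = FALSE)
  for (nm in c("k_on", "k_off", "bleach_rate"))
    if (!num1(cfg[[nm]]) || cfg[[nm]] < 0)
      stop(sprintf("`%s` must be a finite non-negative rate", nm), call. = FALSE)
  if (!num1(cfg$tf_concentration) || cfg$tf_concentration < 0)
    stop("`tf_concentration` must be non-negative (nM)", call. = FALSE)
  if (!num1(cfg$duration) || cfg$duration < cfg$dt)
    stop("`duration` must be at least one frame time", call. = FALSE)
  if (!num1(cfg$E_bound) || !num1(cfg$E_unbound) ||
      cfg$E_bound < 0 || cfg$E_bound >= cfg$E_unbound || cfg$E_unbound > 1)
    stop("require 0 <= E_bound < E_unbound <= 1", call. = FALSE)
  if (!num1(cfg$pife_enhancement) || cfg$pife_enhancement <= 1)
    stop("`pife_enhancement` must be > 1", call. = FALSE)
  if (!num1(cfg$total_intensity) || cfg$total_intensity <= 0)
    stop("`total_intensity` must be positive", call. = FALSE)
  if (!num1(cfg$noise_sd) || cfg$noise_sd < 0)
    stop("`noise_sd` must be non-negative", call. = FALSE)
  if (!num1(cfg$inactive_fraction) ||
      cfg$inactive_fraction < 0 || cfg$inactive_fraction > 1)
    stop("`inactive_fraction` must lie in [0, 1]", call. = FALSE)
  if (!num1(cfg$labeling_efficiency) ||
      cfg$labeling_efficiency < 0 || cfg$labeling_efficiency > 1)
    stop("`labeling_efficiency` must lie in [0, 1]", call. = FALSE)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  modality: %s, dt = %g s, duration = %g s\n",
              x$modality, x$dt, x$duration))
  cat(sprintf("  k_on = %g /s/nM, k_off = %g /s, [TF] = %g nM\n",
              x$k_on, x$k_off, x$tf_concentration))
  cat(sprintf("  intensity = %g, noise sd = %g, bleach rate = %g /s\n",
              x$total_intensity, x$noise_sd, x$bleach_rate))
  invisible(x)
}
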