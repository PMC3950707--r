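#' Run the full single-molecule kinetics pipeline
#'
#' Orchestrates, per binding context: trace acquisition (synthetic
#' simulation or a manifest of trace files) -> photobleach detection and
#' two-state HMM idealization -> molecule selection (colocalized,
#' fluctuating) -> censoring-aware dwell extraction -> per-concentration
#' single-exponential dwell fits -> concentration-series fit -> rate
#' constants; then, when two contexts are named in `config$compare`, the
#' DNA-vs-nucleosome fold-change comparison.  Synthetic cohorts are
#' processed one molecule at a time, so memory stays flat in cohort size.
#'
#' @param config Nested configuration list (see Details).
#' @param seed Master integer seed; every random stage derives from it, so
#'   a fixed seed reproduces the result bundle exactly.
#' @param out_dir Optional directory for intermediate tables (per-context
#'   dwell tables as TSV) and the result bundle JSON.
#' @param verbose Emit per-stage progress messages (default `FALSE`).
#'
#' @details `config$contexts` is a named list; each context holds either a
#' `simulate` block (fields of [sim_config()] plus `concentrations`,
#' `n_molecules` and optional `initial_state`) or a `manifest` path for
#' [read_traces()].  Optional sections: `idealize` (arguments of
#' [idealize_two_state()]), `dwell` (`method` = `"censored_mle"` (default:
#' the censoring-aware, deadtime-corrected exponential MLE), `"mle"`
#' (complete dwells only) or `"weighted_histogram"` (the classic histogram
#' fit); `min_dwells`;
#' `missed_event_correction` / `deadtime` to disable or override the
#' missed-event inversion;
#' `min_complete` -- concentrations with fewer complete dwells in either
#' state are dropped from the series fit), `ensemble`
#' (`fraction_time_bound = TRUE` adds an occupancy titration curve per
#' context), and `compare = c(dna_context, nuc_context)`.
#'
#' @return An object of class `result_bundle`: per-context
#'   [kinetic_params], fit diagnostics (fluctuating fraction, excluded and
#'   dropped counts, per-concentration dwell fits), optional occupancy
#'   curves, the comparison, and the seed.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir = NULL, verbose = FALSE) {
  if (is.null(config$contexts) || !length(config$contexts))
    stop("config must name at least one context", call. = FALSE)
  if (is.null(names(config$contexts)))
    stop("config$contexts must be a named list", call. = FALSE)
  set.seed(seed)
  ctx_seeds <- sample.int(.Machine$integer.max - 1L,
                          length(config$contexts))
  say <- function(...) if (verbose) message(sprintf(...))

  results <- list()
  for (ci in seq_along(config$contexts)) {
    ctx_name <- names(config$contexts)[ci]
    ctx <- config$contexts[[ci]]
    say("[%s] processing context", ctx_name)
    results[[ctx_name]] <- tryCatch(
      process_context(ctx_name, ctx, config, ctx_seeds[ci], say),
      error = function(e)
        stop(sprintf("stage failure in context '%s': %s", ctx_name,
                     conditionMessage(e)), call. = FALSE))
  }

  comparison <- NULL
  if (!is.null(config$compare)) {
    cmp <- config$compare
    if (length(cmp) != 2L || !all(cmp %in% names(results)))
      stop("config$compare must name two fitted contexts", call. = FALSE)
    comparison <- compare_contexts(results[[cmp[1L]]]$params,
                                   results[[cmp[2L]]]$params)
  }

  bundle <- structure(list(
    params = lapply(results, `[[`, "params"),
    diagnostics = lapply(results, `[[`, "diagnostics"),
    occupancy = lapply(results, `[[`, "occupancy"),
    comparison = comparison,
    seed = seed), class = "result_bundle")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(results)) {
      dw <- results[[nm]]$dwells
      utils::write.table(dw, file.path(out_dir, paste0("dwells_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    write_result_bundle(bundle, file.path(out_dir, "result_bundle.json"))
  }
  bundle
}

# Process one context end to end; streaming when simulating.
process_context <- function(ctx_name, ctx, config, ctx_seed, say) {
  ideal_args <- config$idealize %||% list()
  dwell_cfg <- config$dwell %||% list()
  method <- dwell_cfg$method %||% "censored_mle"
  min_dwells <- dwell_cfg$min_dwells %||% 20L
  min_complete <- dwell_cfg$min_complete %||% 5L
  want_occ <- isTRUE((config$ensemble %||% list())$fraction_time_bound)
  min_event <- ideal_args$min_event_frames %||%
    eval(formals(idealize_two_state)$min_event_frames)

  acc <- new.env(parent = emptyenv())
  acc$dwells <- list(); acc$n_total <- 0L; acc$n_coloc <- 0L
  acc$n_fluct <- 0L; acc$n_em_flagged <- 0L
  acc$bound_frames <- list(); acc$live_frames <- list()

  consume <- function(trace) {
    acc$n_total <- acc$n_total + 1L
    if (!trace$colocalized_acceptor) return(invisible())
    acc$n_coloc <- acc$n_coloc + 1L
    ideal <- do.call(idealize_two_state, c(list(trace), ideal_args))
    if (!is.null(attr(ideal$model, "flagged")))
      acc$n_em_flagged <- acc$n_em_flagged + 1L
    if (nrow(transitions(ideal$path)) < 1L) return(invisible())
    acc$n_fluct <- acc$n_fluct + 1L
    key <- as.character(trace$tf_concentration)
    acc$dwells[[length(acc$dwells) + 1L]] <-
      extract_dwells(ideal$path, trace$molecule_id, trace$tf_concentration)
    if (want_occ) {
      lab <- ideal$path$labels
      acc$bound_frames[[key]] <- c(acc$bound_frames[[key]],
                                   sum(lab == "bound"))
      acc$live_frames[[key]] <- c(acc$live_frames[[key]],
                                  sum(lab != "dark"))
    }
    invisible()
  }

  if (!is.null(ctx$simulate)) {
    sim <- ctx$simulate
    concs <- sim$concentrations
    if (is.null(concs) || !length(concs))
      stop("simulate block needs `concentrations`", call. = FALSE)
    n_mol <- sim$n_molecules %||% 100L
    cfg_fields <- intersect(names(sim), names(formals(sim_config)))
    cfg <- do.call(sim_config, sim[cfg_fields])
    init <- sim$initial_state
    set.seed(ctx_seed)
    n_tot <- n_mol * length(concs)
    mol_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
    inactive <- runif(n_tot) < cfg$inactive_fraction
    i <- 0L
    for (conc in concs) for (m in seq_len(n_mol)) {
      i <- i + 1L
      tr <- simulate_one_molecule(cfg, conc, mol_seeds[i], inactive[i], init,
                                  sprintf("mol_%03d_c%g", m, conc))
      consume(tr)
    }
    say("[%s] simulated and idealized %d traces", ctx_name, n_tot)
  } else if (!is.null(ctx$manifest)) {
    cohort <- read_traces(ctx$manifest)
    for (tr in cohort) consume(tr)
    say("[%s] idealized %d traces from %s", ctx_name, length(cohort),
        ctx$manifest)
  } else {
    stop("context needs a `simulate` block or a `manifest` path",
         call. = FALSE)
  }

  if (!length(acc$dwells))
    stop("no fluctuating molecules: nothing to fit", call. = FALSE)
  dwells <- bind_dwells(acc$dwells)
  dt <- attr(dwells, "dt")
  # imposed detection deadtime: majority-vote binning plus the minimum-event
  # floor cannot see sojourns shorter than ~(min_event - 1/2) frames
  deadtime <- if (isFALSE(dwell_cfg$missed_event_correction)) 0 else
    dwell_cfg$deadtime %||% (max(min_event - 0.5, 0.5) * dt)

  conc_of <- vapply(acc$dwells, function(d) attr(d, "tf_concentration"), 1)
  concs_seen <- sort(unique(conc_of))
  per_conc <- list()
  dropped <- character()
  for (conc in concs_seen) {
    sub <- bind_dwells(acc$dwells[conc_of == conc])
    exits_b <- sum(sub$state == "bound" & !sub$right_censored)
    exits_u <- sum(sub$state == "unbound" & !sub$right_censored)
    if (exits_b < min_complete || exits_u < min_complete) {
      dropped <- c(dropped, as.character(conc))
      next
    }
    fb <- fit_dwell_set(sub, "bound", dt, method, min_dwells, deadtime)
    fu <- fit_dwell_set(sub, "unbound", dt, method, min_dwells, deadtime)
    if (deadtime > 0) {
      corr <- correct_missed_events(fb$tau, fu$tau, deadtime)
      # first-order SE propagation through the inversion (finite difference)
      eps_b <- fb$tau * 1e-4; eps_u <- fu$tau * 1e-4
      jb <- (correct_missed_events(fb$tau + eps_b, fu$tau, deadtime)$tau_bound -
               corr$tau_bound) / eps_b
      ju <- (correct_missed_events(fb$tau, fu$tau + eps_u, deadtime)$tau_unbound -
               corr$tau_unbound) / eps_u
      fb$tau <- corr$tau_bound
      fb$tau_se <- abs(jb) * fb$tau_se
      fu$tau <- corr$tau_unbound
      fu$tau_se <- abs(ju) * fu$tau_se
    }
    per_conc[[as.character(conc)]] <- list(
      conc = conc, bound = fb, unbound = fu,
      n_bound = exits_b, n_unbound = exits_u)
  }
  if (!length(per_conc))
    stop("no concentration retained enough complete dwells", call. = FALSE)

  series <- concentration_series(
    tf_concentration = vapply(per_conc, `[[`, 1, "conc"),
    tau_unbound = lapply(per_conc, `[[`, "unbound"),
    tau_bound = lapply(per_conc, `[[`, "bound"))
  params <- fit_concentration_series(series, context = ctx_name)

  occupancy <- NULL
  if (want_occ && length(acc$live_frames)) {
    oc <- as.numeric(names(acc$live_frames))
    est <- mapply(function(b, l) sum(b) / sum(l),
                  acc$bound_frames, acc$live_frames)
    occupancy <- titration_curve(oc, est,
                                 response_kind = "fraction_time_bound")
  }

  list(params = params,
       dwells = dwells,
       occupancy = occupancy,
       diagnostics = list(
         n_total = acc$n_total, n_colocalized = acc$n_coloc,
         n_fluctuating = acc$n_fluct,
         fluctuating_fraction = if (acc$n_coloc) acc$n_fluct / acc$n_coloc
                                else NA_real_,
         n_em_flagged = acc$n_em_flagged,
         dropped_concentrations = dropped,
         per_concentration = lapply(per_conc, function(p)
           list(conc = p$conc, tau_bound = p$bound$tau,
                tau_bound_se = p$bound$tau_se, tau_unbound = p$unbound$tau,
                tau_unbound_se = p$unbound$tau_se,
                n_bound = p$n_bound, n_unbound = p$n_unbound))))
}

# Per-concentration dwell estimator.
# "censored_mle" (default): censoring-aware exponential MLE (total time in
#   state / observed exits, minus the detection deadtime) -- unbiased for
#   any window length and sample size, honest SE.
# "mle": truncation-corrected mean of complete dwells (window-biased when
#   tau is comparable to the trace length).
# "weighted_histogram": the classic weighted histogram fit (slope-based, so
#   truncation-immune, but sparse tail bins mislead it at small n); falls
#   back to the censored MLE when under-determined.
fit_dwell_set <- function(dwells, state, dt, method, min_dwells,
                          truncation = 0) {
  switch(method,
    censored_mle = fit_exponential_censored(dwells, state, truncation,
                                            min_dwells),
    mle = fit_exponential_mle(complete_dwells(dwells, state), min_dwells,
                              truncation = truncation),
    weighted_histogram = tryCatch(
      fit_exponential_histogram(complete_dwells(dwells, state), dt = dt,
                                min_dwells = min_dwells),
      error = function(e)
        fit_exponential_censored(dwells, state, truncation, min_dwells)),
    stop("unknown dwell fit method: ", method, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle>\n")
  for (nm in names(x$params)) {
    p <- x$params[[nm]]
    d <- x$diagnostics[[nm]]
    cat(sprintf("  %s: tau_bound = %.4g s, k_on = %.4g /s/nM, k_off = %.4g /s, K_D = %.4g nM (fluctuating %.0f%%)\n",
                nm, p$tau_bound, p$k_on, p$k_off, p$K_D,
                100 * d$fluctuating_fraction))
  }
  if (!is.null(x$comparison))
    cat(sprintf("  comparison: k_on reduced %.3g-fold, k_off increased %.3g-fold\n",
                x$comparison$binding_fold_reduction,
                x$comparison$dissociation_fold_increase))
  invisible(x)
}

#' Serialize a result bundle to JSON
#'
#' @param bundle A `result_bundle` from [run_pipeline()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_result_bundle <- function(bundle, path) {
  strip <- function(x) {
    if (inherits(x, "titration_curve")) return(as.data.frame(x))
    if (is.function(x)) return(NULL)
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  jsonlite::write_json(strip(unclass(bundle)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
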