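#' Concentration series of dwell-time fits
#'
#' @param tf_concentration Distinct positive TF concentrations, nM.
#' @param tau_unbound,tau_bound Lists of `exp_fit` objects (one per
#'   concentration).
#' @param n_molecules Optional molecule counts per concentration.
#' @return An object of class `concentration_series`.
#' @export
concentration_series <- function(tf_concentration, tau_unbound, tau_bound,
                                 n_molecules = NA_integer_) {
  k <- length(tf_concentration)
  if (k < 1L) stop("need at least one concentration", call. = FALSE)
  if (any(tf_concentration <= 0) ||
      anyDuplicated(tf_concentration))
    stop("concentrations must be distinct and > 0", call. = FALSE)
  if (length(tau_unbound) != k || length(tau_bound) != k)
    stop("one tau fit per concentration required", call. = FALSE)
  structure(list(tf_concentration = tf_concentration,
                 tau_unbound = tau_unbound, tau_bound = tau_bound,
                 n_molecules = rep_len(n_molecules, k)),
            class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  cat("<concentration_series>\n")
  for (i in seq_along(x$tf_concentration))
    cat(sprintf("  %g nM: tau_unbound = %.4g +/- %.3g s, tau_bound = %.4g +/- %.3g s\n",
                x$tf_concentration[i],
                x$tau_unbound[[i]]$tau, x$tau_unbound[[i]]$tau_se,
                x$tau_bound[[i]]$tau, x$tau_bound[[i]]$tau_se))
  invisible(x)
}

#' Kinetic parameters of one binding context
#'
#' Holds the unbound-dwell coefficient `A` (tau_unbound = A / C), the
#' concentration-independent bound dwell time, and the derived rate
#' constants `k_on = 1/A`, `k_off = 1/tau_bound`, `K_D = k_off/k_on`,
#' each with a first-order (delta-method) standard error.
#'
#' @param A Unbound-dwell coefficient, s nM.
#' @param A_se,tau_bound_se Standard errors.
#' @param tau_bound Bound dwell time, s.
#' @param context Context label, e.g. `"LexA-DNA"`.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(A, A_se, tau_bound, tau_bound_se,
                           context = "context") {
  if (!is.finite(A) || A <= 0 || !is.finite(tau_bound) || tau_bound <= 0)
    stop("`A` and `tau_bound` must be positive and finite", call. = FALSE)
  k_on <- 1 / A
  k_off <- 1 / tau_bound
  K_D <- A / tau_bound  # = k_off / k_on
  rel_A <- A_se / A
  rel_t <- tau_bound_se / tau_bound
  structure(list(
    A = A, A_se = A_se,
    tau_bound = tau_bound, tau_bound_se = tau_bound_se,
    k_on = k_on, k_on_se = k_on * rel_A,
    k_off = k_off, k_off_se = k_off * rel_t,
    K_D = K_D, K_D_se = K_D * sqrt(rel_A^2 + rel_t^2),
    context = context), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params: %s>\n", x$context))
  cat(sprintf("  tau_bound = %.4g +/- %.3g s, A = %.4g +/- %.3g s nM\n",
              x$tau_bound, x$tau_bound_se, x$A, x$A_se))
  cat(sprintf("  k_on = %.4g +/- %.3g /s/nM, k_off = %.4g +/- %.3g /s\n",
              x$k_on, x$k_on_se, x$k_off, x$k_off_se))
  cat(sprintf("  K_D = %.4g +/- %.3g nM\n", x$K_D, x$K_D_se))
  invisible(x)
}

#' Fit kinetic parameters to a concentration series
#'
#' The unbound dwell times follow `tau_unbound = A / C` for a
#' pseudo-first-order binding step; `A` is fitted by weighted least squares
#' (weights `1 / SE^2`), which has the closed form
#' `A = sum(w_i tau_i / C_i) / sum(w_i / C_i^2)` with
#' `var(A) = 1 / sum(w_i / C_i^2)`.  The bound dwell time is
#' concentration-independent and estimated as the inverse-variance weighted
#' mean.  If any pair of per-concentration bound dwell times disagrees at
#' `z > 3`, a warning is recorded (and emitted) but the fit is still
#' returned.
#'
#' @param series A [concentration_series].
#' @param context Context label carried into the result.
#' @return A [kinetic_params].
#' @export
fit_concentration_series <- function(series, context = "context") {
  stopifnot(inherits(series, "concentration_series"))
  C <- series$tf_concentration
  if (length(C) < 2L)
    warning("only one concentration: A = C * tau_unbound is unregularized",
            call. = FALSE)
  tu <- vapply(series$tau_unbound, function(f) f$tau, 1)
  tu_se <- vapply(series$tau_unbound, function(f) f$tau_se, 1)
  tb <- vapply(series$tau_bound, function(f) f$tau, 1)
  tb_se <- vapply(series$tau_bound, function(f) f$tau_se, 1)

  w <- 1 / tu_se^2
  if (any(!is.finite(w))) w[!is.finite(w)] <- max(w[is.finite(w)], 1)
  A <- sum(w * tu / C) / sum(w / C^2)
  A_se <- sqrt(1 / sum(w / C^2))

  wb <- 1 / tb_se^2
  if (any(!is.finite(wb))) wb[!is.finite(wb)] <- max(wb[is.finite(wb)], 1)
  tau_b <- sum(wb * tb) / sum(wb)
  tau_b_se <- sqrt(1 / sum(wb))

  # consistency check on the concentration independence of tau_bound
  if (length(tb) > 1L) {
    pairs <- utils::combn(length(tb), 2L)
    z <- abs(tb[pairs[1L, ]] - tb[pairs[2L, ]]) /
      sqrt(tb_se[pairs[1L, ]]^2 + tb_se[pairs[2L, ]]^2)
    if (any(is.finite(z) & z > 3))
      warning("bound dwell times are inconsistent across concentrations (pairwise z > 3)",
              call. = FALSE)
  }
  kinetic_params(A, A_se, tau_b, tau_b_se, context = context)
}

#' Derive rate constants from A and the bound dwell time
#'
#' `k_on = 1/A`, `k_off = 1/tau_bound`, `K_D = k_off/k_on = A/tau_bound`;
#' standard errors by first-order propagation (relative errors add in
#' quadrature for `K_D`).
#'
#' @param A Unbound-dwell coefficient, s nM (> 0).
#' @param tau_bound Bound dwell time, s (> 0).
#' @param A_se,tau_bound_se Standard errors (default 0).
#' @param context Context label.
#' @return A [kinetic_params].
#' @examples
#' derive_rates(A = 20, tau_bound = 290, A_se = 6, tau_bound_se = 20)
#' @export
derive_rates <- function(A, tau_bound, A_se = 0, tau_bound_se = 0,
                         context = "context") {
  kinetic_params(A, A_se, tau_bound, tau_bound_se, context = context)
}

#' Compare kinetics between duplex DNA and nucleosome contexts
#'
#' Computes the fold reduction in binding rate (`k_on` DNA / nucleosome),
#' the fold increase in dissociation rate (`k_off` nucleosome / DNA), the
#' affinity fold change (`K_D` nucleosome / DNA), and the site-exposure
#' probability `p_exposed = k_on(nuc) / k_on(DNA)`.  The last follows from
#' assuming the TF binds an unwrapped nucleosomal site at the same rate as
#' naked DNA, so any on-rate suppression reflects how rarely the buried
#' site is transiently exposed.
#'
#' @param dna,nuc [kinetic_params] for the two contexts.
#' @return An object of class `context_comparison` with components
#'   `binding_fold_reduction`, `dissociation_fold_increase`,
#'   `s05_fold_increase`, `p_exposed`, and propagated standard errors.
#' @export
compare_contexts <- function(dna, nuc) {
  stopifnot(inherits(dna, "kinetic_params"), inherits(nuc, "kinetic_params"))
  rel <- function(x, sx) if (x > 0) sx / x else NA_real_
  bfr <- dna$k_on / nuc$k_on
  dfi <- nuc$k_off / dna$k_off
  s05 <- nuc$K_D / dna$K_D
  structure(list(
    binding_fold_reduction = bfr,
    binding_fold_reduction_se = bfr * sqrt(rel(dna$k_on, dna$k_on_se)^2 +
                                             rel(nuc$k_on, nuc$k_on_se)^2),
    dissociation_fold_increase = dfi,
    dissociation_fold_increase_se = dfi * sqrt(rel(nuc$k_off, nuc$k_off_se)^2 +
                                                 rel(dna$k_off, dna$k_off_se)^2),
    s05_fold_increase = s05,
    p_exposed = 1 / bfr,
    contexts = c(dna = dna$context, nuc = nuc$context)),
    class = "context_comparison")
}

#' @export
print.context_comparison <- function(x, ...) {
  cat(sprintf("<context_comparison> %s vs %s\n",
              x$contexts[["dna"]], x$contexts[["nuc"]]))
  cat(sprintf("  binding rate reduced %.3g-fold; dissociation rate increased %.3g-fold\n",
              x$binding_fold_reduction, x$dissociation_fold_increase))
  cat(sprintf("  K_D increased %.3g-fold; site-exposure probability %.3g\n",
              x$s05_fold_increase, x$p_exposed))
  invisible(x)
}

#' Upper bound on a dissociation rate from a survival count
#'
#' When almost no molecules dissociate within the acquisition window the
#' dwell-time fit is impossible, but the survival fraction still bounds
#' `k_off`.  The point estimate is `-log(n_surviving / n_bound_start) /
#' duration`; the one-sided upper confidence bound comes from the
#' Clopper-Pearson lower bound on the binomial survival probability mapped
#' through the exponential survival function `S(T) = exp(-k T)`.
#'
#' @param n_bound_start Molecules bound at the start.
#' @param n_surviving Of those, still bound after `duration` (> 0; if every
#'   molecule dissociated the exponential point estimate is undefined and
#'   only the bound from the first-frame analysis is returned).
#' @param duration Acquisition time, s.
#' @param confidence One-sided confidence level (default 0.95).
#' @return List with `k_point` (s^-1; `NA` when `n_surviving = 0`),
#'   `k_upper` (s^-1), `survival_fraction`, `confidence`.
#' @examples
#' koff_upper_bound_from_survival(100, 90, 2000)
#' @export
koff_upper_bound_from_survival <- function(n_bound_start, n_surviving,
                                           duration, confidence = 0.95) {
  if (n_bound_start < 1 || n_surviving > n_bound_start || n_surviving < 0)
    stop("require 0 <= n_surviving <= n_bound_start with n_bound_start >= 1",
         call. = FALSE)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  alpha <- 1 - confidence
  if (n_surviving == 0) {
    # all dissociated: exponential point estimate diverges; bound k from
    # below using the survival probability's upper confidence limit
    p_upper <- qbeta(confidence, 1, n_bound_start)
    return(list(k_point = NA_real_, k_upper = Inf,
                k_lower = -log(p_upper) / duration,
                survival_fraction = 0, confidence = confidence))
  }
  frac <- n_surviving / n_bound_start
  k_point <- -log(frac) / duration
  # Clopper-Pearson lower bound on survival probability
  p_lower <- qbeta(alpha, n_surviving, n_bound_start - n_surviving + 1)
  k_upper <- -log(p_lower) / duration
  list(k_point = k_point, k_upper = k_upper, k_lower = 0,
       survival_fraction = frac, confidence = confidence)
}
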