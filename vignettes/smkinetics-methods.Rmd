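---
title: "Models and methods behind smkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smkinetics)
```

# The problem

Transcription factors (TFs) find and occupy short recognition sequences in
genomic DNA. When such a site sits in the entry–exit region of a
nucleosome, the wrapped DNA sterically occludes it; the site is only
reachable during transient partial unwrapping ("site exposure"), and the
nucleosome can also eject a partially dissociated TF by re-wrapping.
Single-molecule TIRF experiments quantify both effects by watching
individual surface-tethered DNA or nucleosome molecules in the presence of
TF and timing the visits of the TF to its site.

Two readouts are used:

* **PIFE** (protein-induced fluorescence enhancement): a Cy3 dye adjacent
  to the site emits more strongly while the TF is bound; a single-channel
  intensity trace steps between two levels.
* **FRET**: a donor on the DNA end and acceptors on the histone octamer
  give high transfer efficiency (~0.8) while the nucleosome is wrapped and
  low efficiency (~0.2) while a bound TF traps the unwrapped state.

Under first-order kinetics the per-molecule state sequence is a two-state
continuous-time Markov chain with pseudo-first-order binding rate
$k_{\text{eff}} = k_{\text{on}} C$ and dissociation rate
$k_{\text{off}}$. Dwell times in each state are exponential; the unbound
characteristic time scales as $\tau_u = A/C$ with $k_{\text{on}} = 1/A$,
the bound time $\tau_b = 1/k_{\text{off}}$ is concentration-independent,
and the affinity is $K_D = k_{\text{off}}/k_{\text{on}} = A/\tau_b$.
Comparing the same TF on naked DNA and on nucleosomes yields two fold
changes: the on-rate suppression (equal, under the equal-intrinsic-rate
assumption, to the site-exposure probability) and the off-rate
enhancement. `smkinetics` implements the full chain from raw (or
synthetic) traces to those numbers.

# The synthetic-data generator: a stated world

Every stage is validated against simulation because no public raw traces
exist for this kind of experiment. The generator
([`simulate_state_path()`], [`render_trace()`], [`simulate_cohort()`])
emulates:

* exact exponential waiting times for the two-state chain, binned to
  camera frames of `dt = 0.05` s (the instrument's 50-ms resolution) by
  **majority occupancy** within each frame — mimicking camera integration
  rather than point sampling; the un-binned event times are retained as
  ground truth;
* the initial state drawn from the equilibrium occupancy
  $k_{\text{eff}}/(k_{\text{eff}}+k_{\text{off}})$ (steady-state
  acquisition), with an override to start bound for survival-style
  experiments;
* PIFE rendering (Cy3 mean `total_intensity`, times `pife_enhancement`
  = 1.5 when bound) and FRET rendering (acceptor mean $E \cdot$ total,
  donor $(1-E)\cdot$ total, with $E$ = 0.8 unbound / 0.2 bound);
* additive Gaussian noise per frame and channel (adequate for EMCCD gain
  regimes; Poisson statistics are not modeled), a single exponential
  photobleach time that truncates the trace to a dark level, a
  configurable fraction of inactive molecules that never bind, and
  binomial acceptor-labeling stoichiometry for the labeling module.

**Defaults and why.** The experiments report no absolute intensities or
SNR, so the defaults are chosen once to make idealization non-trivial but
reliable: `total_intensity = 1000`, `noise_sd = 167`, giving a PIFE
level-separation-to-noise ratio of 3 and a FRET proximity-ratio separation
of ~4.3 of its noise. `pife_enhancement = 1.5` is a config knob, not a
claim — the publications never quantify the enhancement factor, and any
value giving SNR ≥ 3 exercises the same code paths. `bleach_rate = 1e-4`
s⁻¹ represents residual bleaching under an oxygen-scavenging system (mean
bleach time 10⁴ s, so ~18% of 2000-s traces truncate). These are the
stated world of the test-suite and acceptance runs and are not tuned.

What the generator does **not** emulate: camera image formation, spot
detection and drift, acceptor blinking or acceptor-only bleaching,
triplet-state photophysics, baseline drift, and non-exponential kinetic
heterogeneity. A green test therefore establishes correctness of the
analysis under the assumed two-state exponential world, not robustness to
every artifact of real recordings.

# Idealization

Traces are reduced to two-state step functions by a maximum-likelihood
Gaussian-emission hidden Markov model
([`idealize_two_state()`]). A variational-Bayes step fitter is commonly
used for this in practice; the deliverable, however, is the two-state step
function itself, and a hard two-state ML fit is deterministic and directly
checkable (EM tolerance 1e-6 on the log-likelihood, 500-iteration cap,
Viterbi decoding; decoder optimality is tested by exhaustive enumeration
on short traces). Designs that proved out during validation:

* **Initialization** is a two-cluster split at the midpoint of the 1%/99%
  quantile range of the observable. A plain median split fails whenever
  one state occupies a small fraction of frames (at 4% bound occupancy
  both init clusters land on the majority level and EM converges to a
  degenerate solution; measured event recovery fell from ~80% to ~15%).
* **The emission sd is shared between states** (`shared_sd = TRUE`).
  Detector noise does not depend on the binding state, and freeing the
  sds lets EM collapse onto one wide "outlier" component that absorbs the
  heavy tails of the FRET proximity ratio.
* **The FRET observable** is the uncorrected proximity ratio
  $A/(D+A)$, with the denominator floored at half the median total
  intensity: frames whose total collapses carry no usable FRET
  information and an unregularized ratio there has destabilizing tails.
  Gamma-correction factors are identity hooks; relative-change titrations
  are invariant to them.
* **Degeneracy (single-level) detection** uses three guards, each passed
  by genuine two-state traces with a wide margin: level separation of at
  least 1 pooled sd; a BIC comparison against a single Gaussian (a real
  two-state trace gains hundreds of log-likelihood units, a noise split
  gains ~1); and, for FRET, both state means inside the physical
  efficiency range [−0.05, 1.05] (EM occasionally latches onto ratio
  tails at ≈1.1, which no FRET state can produce). Degenerate traces
  return a zero-transition path — they are not errors, because
  non-fluctuating molecules are an expected part of every cohort.
* **Minimum event length**: inferred dwells shorter than 2 frames are
  merged into the flanking state, an imposed detection deadtime handled
  explicitly downstream (next section).
* **Photobleaching** is detected on a 25-frame running median of the total
  intensity: the earliest frame after which it stays below 0.2 of the
  bright level (the 99th percentile of the smoothed trace — robust even
  when a trace bleaches early and is majority-dark) for at least 50
  frames. Post-bleach frames are excluded from fitting and labeled dark.

Molecule selection ([`select_molecules()`]) keeps traces with a
colocalized acceptor and at least one inferred transition, and reports the
fluctuating fraction — the same bookkeeping experiments use when they
report that e.g. 70% of nucleosomes or 25% of DNA molecules fluctuate.

# Dwell times, censoring and the deadtime

Runs of constant state become dwells ([`extract_dwells()`]). The first
dwell of a trace is left-censored, and the final dwell — or a dwell cut
off by photobleaching — is right-censored. Three estimators of the
exponential characteristic time are provided:

1. **Censored MLE** (pipeline default, [`fit_exponential_censored()`]):
   total observed time in the state divided by the number of observed
   exits. Censored dwells contribute exposure but no event; left-censored
   dwells of an exponential state are themselves exponential by
   memorylessness. This is the textbook Type-I-censoring estimator and is
   unbiased for any window length — which matters here, because the
   slow context has $\tau_b \approx 290$ s against 2000-s traces, where
   a complete-dwell-only mean is ~20% low.
2. **Complete-dwell MLE** ([`fit_exponential_mle()`]): the sample mean,
   with the optional left-truncation correction `mean − deadtime`.
3. **Weighted histogram fit** ([`fit_exponential_histogram()`]): counts
   binned at `max(dt, τ/10)` fitted to $A e^{-t/\tau}$ with Poisson
   weights — the procedure used experimentally, retained and
   cross-validated against the MLE (they agree within 5% on dense
   samples). Its known failure mode, documented by test: with only tens
   of dwells spread over many bins the unit-count tail bins flatten the
   slope and inflate τ severalfold, which is why it is not the default.

**Missed events.** Majority-vote binning plus the 2-frame event floor
impose a detection deadtime $t_d \approx 1.5\,dt$: sojourns shorter than
$t_d$ in one state vanish, concatenating flanking dwells of the other
state, whose apparent time inflates by $\approx 1/(1-p)$ with
$p = 1 - e^{-t_d/\tau}$. At the highest mononucleosome concentration
($\tau_u = 0.22$ s) this is a 45% upward bias on $\tau_b$ — far outside
the target accuracy. The pipeline applies the standard analytic
missed-event correction ([`correct_missed_events()`]): the pair of
forward relations $\tau_b^{obs} = (\tau_b + p_u g_u)/(1-p_u)$ (and
symmetrically for $\tau_u$), with $g$ the mean missed gap, is inverted
jointly by fixed-point iteration using the *known, imposed* deadtime.
The forward model reproduces the measured bias to ~2%, and corrected
recoveries sit within statistical error of generator truth at every
concentration.

# Rates, affinities, contexts

Per concentration, both dwell fits feed a weighted least-squares
concentration-series fit ([`fit_concentration_series()`]):
$A$ has the closed form
$\sum w_i \tau_i / C_i \,/\, \sum w_i / C_i^2$ with $w = 1/\text{SE}^2$,
and $\tau_b$ is the inverse-variance weighted mean, with a recorded
warning if per-concentration bound times disagree pairwise at $z > 3$.
[`derive_rates()`] then gives $k_{\text{on}} = 1/A$,
$k_{\text{off}} = 1/\tau_b$, $K_D = A/\tau_b$ with first-order (delta
method) standard errors; [`compare_contexts()`] forms the DNA-vs-nucleosome
fold changes and the site-exposure probability
$p_{\text{exposed}} = k_{\text{on}}^{nuc}/k_{\text{on}}^{DNA}$.

When essentially nothing dissociates within the acquisition window the
dwell fit is unidentified and [`koff_upper_bound_from_survival()`] is used
instead: the point estimate $-\ln(S)/T$ from the survival fraction plus a
one-sided Clopper–Pearson upper bound mapped through the exponential
survival function.

# Ensemble titrations and labeling

[`fit_binding_curve()`] fits fraction-bound responses with the Hill form
$C^n/(S_{0.5}^n + C^n)$ ($n \equiv 1$ for the non-cooperative model) or,
when the target concentration is comparable to the affinity, the exact
1:1 ligand-depletion quadratic. For 1:1 binding the depletion midpoint is
exactly $S_{0.5} = \text{target}/2 + K_D$ (at half-saturation the free TF
equals $K_D$), which is why ensemble titrations at 100–200 pM target can
only bound a picomolar affinity, while the per-molecule intensity
histogram — unmixed against *fixed* 0-TF and saturating-TF reference
Gaussians with only the weight free
([`intensity_histogram_unmix()`]) — resolves it.

The labeling module inverts the binomial acceptor-stoichiometry relation
$A_{two}/A_{one} = L_P^2 / (2 L_P (1-L_P))$, i.e.
$L_P = 2r/(1+2r)$, after a free two-Gaussian EM fit of the
direct-to-sensitized Cy5 intensity ratio ([`fit_two_gaussians()`]); a
cohort in which effectively all molecules carry two acceptors is detected
by BIC model selection and flagged degenerate rather than producing an
arbitrary ratio.

# Numerical choices and degenerate inputs

* EM: tolerance 1e-6 on log-likelihood, cap 500 iterations; a non-
  converged fit is flagged and counted in the pipeline diagnostics.
* Emission sds floored at 1e-3 of the observable sd; binding-curve and
  histogram fits use `nls(algorithm = "port")` with positivity bounds and
  closed-form or log-linear starting values.
* Frame ties in majority binning (a dwell occupying exactly half a frame)
  count as bound; the set of such events has probability zero in
  continuous time.
* Zero rates are legal everywhere (absorbing states); negative or
  non-finite rates are rejected with explanatory errors.
* All concentrations are nM and all times seconds internally; picomolar
  figures are converted at the boundary.
* Every random stage takes a seed; cohorts derive per-molecule seeds
  deterministically from it, so identical seeds give bit-identical
  cohorts and result bundles.

# Known limitations

* The two-state assumption is structural: intermediate FRET states,
  multi-step binding, or static heterogeneity between molecules are not
  modeled and would be silently averaged.
* The missed-event correction is first-order in the miss probability; it
  was validated for $\tau \gtrsim 4\,dt$ and degrades as dwell times
  approach the frame time (it refuses to extrapolate beyond a 90% miss
  fraction).
* Additive Gaussian noise and a single global bleach event are
  simplifications; acceptor-only bleaching in FRET would mimic a binding
  event and is out of scope.
* The selection rule (≥ 1 transition) slightly disfavors molecules whose
  single dwell outlasts the window; at the parameter sets studied here
  the effect is below statistical error, but it would matter if
  $\tau_b$ approached the full acquisition length.

# A worked example

```{r example, eval = FALSE}
library(smkinetics)
config <- list(
  contexts = list(
    "LexA-DNA" = list(simulate = list(
      modality = "PIFE", k_on = 0.05, k_off = 3.4e-3,
      concentrations = c(0.03, 0.1, 0.3, 1),
      n_molecules = 100, duration = 2000, dt = 0.05)),
    "LexA-monoNuc" = list(simulate = list(
      modality = "FRET", k_on = 9e-5, k_off = 3.3,
      concentrations = c(1500, 5000, 15000, 50000),
      n_molecules = 100, duration = 200, dt = 0.05))),
  compare = c("LexA-DNA", "LexA-monoNuc"))
bundle <- run_pipeline(config, seed = 1)
print(bundle)
```

The README shows the output this produces and how to regenerate the full
acceptance report with `scripts/acceptance.R`.
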