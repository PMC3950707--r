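# smkinetics

Single-molecule binding kinetics of transcription factors (TFs) at target
sites in duplex DNA and in nucleosomes, from smTIRF fluorescence time
series.

## Who this is for

Single-molecule biophysicists and chromatin researchers who record
per-molecule PIFE (one Cy3 channel that brightens on TF binding) or FRET
(donor/acceptor pair reporting nucleosome unwrapping) traces and want
binding/dissociation rate constants out — plus anyone who needs a fully
synthetic, ground-truth-attached testbed for such pipelines.

## The model

Each molecule switches between *unbound* and *bound* as a two-state
continuous-time Markov chain with pseudo-first-order binding rate
k_on·C and dissociation rate k_off. Dwell times are exponential:

    tau_unbound = A / C,   k_on  = 1/A
    tau_bound   = const,   k_off = 1/tau_bound
    K_D = k_off / k_on = A / tau_bound

Comparing a TF on naked DNA vs on a nucleosome gives the fold reduction
in k_on (equal to the site-exposure probability of the wrapped target
site, under equal intrinsic binding rates) and the fold increase in
k_off. The pipeline: noisy traces → two-state Gaussian-HMM idealization
(EM + Viterbi, photobleach detection) → censoring-annotated dwell tables
→ exponential dwell fits (censoring-aware MLE with analytic missed-event
correction; classic weighted-histogram fit available) → weighted
concentration-series fit → rates, affinities, fold changes. Side
modules: binding-isotherm fits (non-cooperative / Hill / exact 1:1
ligand depletion), per-molecule intensity-histogram unmixing, survival
bounds for ultra-slow dissociation, and acceptor-labeling-efficiency
estimation from two-Gaussian intensity-ratio mixtures
(L_P = 2r/(1+2r) from the two-to-one acceptor area ratio r).

## Worked example

Simulate both LexA contexts at their published rate constants (100
molecules per concentration; 2000-s PIFE traces on DNA at 0.03–1 nM,
200-s FRET traces on mononucleosomes at 1.5–50 µM), run the full
pipeline and compare:

```r
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
#> <result_bundle>
#>   LexA-DNA: tau_bound = 285.4 s, k_on = 0.04955 /s/nM, k_off = 0.003504 /s, K_D = 0.07071 nM (fluctuating 97%)
#>   LexA-monoNuc: tau_bound = 0.3052 s, k_on = 9.004e-05 /s/nM, k_off = 3.277 /s, K_D = 3.639e+04 nM (fluctuating 100%)
#>   comparison: k_on reduced 550-fold, k_off increased 935-fold
```

Reading this: on naked DNA the TF stays bound ~5 min (tau_bound ≈ 285 s,
generator truth 294 s) with sub-nanomolar affinity; inside the
nucleosome it stays ~0.3 s, binding is ~550-fold slower (so the buried
site is exposed ~0.2% of the time) and dissociation ~935-fold faster —
the recovered values match the generating parameters within their
standard errors (about ±7 s on tau_bound here).

## Command line

```sh
Rscript inst/cli/smkinetics simulate --config cfg.json --out cohort/ --seed 3
Rscript inst/cli/smkinetics dwells   --manifest cohort/manifest.json --out dwells.tsv
Rscript inst/cli/smkinetics run      --config inst/extdata/lexa_dna.json --out bundle.json
Rscript inst/cli/smkinetics report   --in bundle.json
```

Trace files are tab-delimited text (`time_s`, then `cy3` or
`donor`/`acceptor`) with a JSON manifest; configs are JSON (YAML works
when the `yaml` package is present).

## Documentation

`vignettes/smkinetics-methods.Rmd` describes the model, the synthetic
world and its defaults, every estimator choice (and the measured failure
modes that motivated them), numerical tolerances, and known limitations.
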