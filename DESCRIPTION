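Package: smkinetics
Title: Single-Molecule Transcription Factor Binding Kinetics from
    Fluorescence Traces
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying transcription-factor binding and
    dissociation kinetics at target sites in duplex DNA and in nucleosomes
    from single-molecule TIRF fluorescence time series.  Provides a
    synthetic trace generator (two-state continuous-time Markov binding
    process rendered as PIFE or FRET intensity traces with shot-like noise
    and photobleaching), two-state hidden-Markov idealization with Viterbi
    decoding, censoring-aware dwell-time extraction and single-exponential
    fitting, derivation of on/off rate constants and dissociation constants
    from concentration series, binding-isotherm fits (non-cooperative,
    Hill, ligand depletion), per-molecule intensity-histogram unmixing, and
    acceptor-labeling-efficiency estimation from two-component intensity
    ratio mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
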