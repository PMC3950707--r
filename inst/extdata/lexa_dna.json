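{
  "contexts": {
    "LexA-DNA": {
      "simulate": {
        "modality": "PIFE",
        "k_on": 0.05,
        "k_off": 0.02,
        "concentrations": [0.3, 1],
        "n_molecules": 8,
        "duration": 400,
        "dt": 0.05,
        "bleach_rate": 0.0001
      }
    }
  },
  "dwell": { "min_dwells": 10, "min_complete": 3 }
}
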