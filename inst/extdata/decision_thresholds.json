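{
  "published_tree": {
    "plexus60_hi": 1.77,
    "plexus60_lo": 1.05,
    "module_hi": 1.11,
    "module_cap": 3.19,
    "performance": {
      "sensitivity": 0.96,
      "specificity": 0.61,
      "ppv": 0.92,
      "npv": 0.80
    }
  },
  "brain_tbr": 1.6,
  "dual_plexus": {
    "early": 1.0,
    "late": 1.2
  },
  "thalamus_absolute": {
    "early": 1.0,
    "late": 1.1
  },
  "thalamus_relative": {
    "early": 1.7,
    "late": 1.6
  },
  "complete_cases": 262,
  "n_samples": 284,
  "n_tumor": 230,
  "n_astrogliosis": 54
}
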