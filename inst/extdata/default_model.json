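{
  "normalization": {
    "bounds": {
      "PSD": [0.95, 16.9],
      "MD": [-24.1, 6.39],
      "RNFL_S": [6, 172],
      "RNFL_I": [0, 195],
      "RNFL_T": [20, 110],
      "IOP": [5, 29]
    },
    "reversed": ["MD", "RNFL_S", "RNFL_I", "RNFL_T"]
  },
  "model": {
    "weights": {
      "PSD": 0.27,
      "MD": 0.14,
      "RNFL_S": 0.11,
      "RNFL_I": 0.31,
      "RNFL_T": 0.1,
      "IOP": 0.07
    },
    "base_ratio": 0.8,
    "nni_ratio": 0.2,
    "threshold": 0.36,
    "k": 5,
    "staging_bins": {
      "intermediate": -5,
      "advanced": -12
    },
    "border_margin": 0.05
  }
}
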