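{
  "name": "tempo34_egfr (published estimates/SEs; synthetic reconstructed vcov)",
  "equation": "egfr",
  "coefficients": {
    "lambda": 4.48474,
    "beta": -0.06227
  },
  "se": {
    "lambda": 0.08244,
    "beta": 0.01124
  },
  "vcov": [
    [0.0067963536, -0.000924429034323832],
    [-0.000924429034323832, 0.0001263376]
  ]
}
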