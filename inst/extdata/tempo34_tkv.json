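{
  "name": "tempo34_tkv (published estimates/SEs; synthetic reconstructed vcov)",
  "equation": "tkv",
  "coefficients": {
    "lambda": 0.7889,
    "alpha": 0.1107,
    "beta": 0.8027,
    "gamma": -0.0486,
    "delta": -0.016
  },
  "se": {
    "lambda": 1.1313,
    "alpha": 0.0287,
    "beta": 0.1556,
    "gamma": 0.0266,
    "delta": 0.0039
  },
  "vcov": [
    [1.27983969, -0.0319726229042089, -0.175603192832397, -0.000359519683610705, 0.00433441470534657],
    [-0.031972622904209, 0.00082369, 0.0043874784425679, 4.36818441850249e-07, -0.000111665936973355],
    [-0.175603192832395, 0.00438747844256784, 0.02421136, 8.31026114341349e-07, -0.000597612020660565],
    [-0.000359519683611559, 4.36818441871725e-07, 8.31026114459225e-07, 0.00070756, -2.8654449511243e-08],
    [0.00433441470534654, -0.000111665936973354, -0.000597612020660567, -2.86544495083125e-08, 1.521e-05]
  ]
}
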