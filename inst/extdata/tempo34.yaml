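# Base-case run: TEMPO 3:4-matched cohort, lifetime horizon, coefficient
# and baseline sampling on, synthetic UK-like background mortality.
seed: 1
horizon_years: 80
sample_coefficients: true
mortality_enabled: true
record_trajectories: false
cohort:
  preset: tempo34
  n: 10000
coefficients:
  tkv: default
  egfr: default
life_table: synthetic
output_dir: adpkdsim-output
reports: [summary, outcomes]
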