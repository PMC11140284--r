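# Single-class null cohort: one latent trajectory, no class structure.
n_subjects: 800
n_waves: 4
time_scores: [0, 1, 2, 3]
class_proportions: [1.0]
class_means:
  - [3.745, -0.088]
factor_cov:
  psi00: 0.06
  psi11: 0.004
  psi01: 0.0
residual_var: 0.02
censor_to_scale: false
missing_rate: 0.0
predictor_specs: default
outcome_specs: default
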