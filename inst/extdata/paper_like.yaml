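# Two-class cohort emulating the published visual-trajectory solution:
# 81.9% high-baseline declining class, 18.1% low-baseline improving class,
# four waves at times 0..3 on the 1-4 vision scale.
n_subjects: 2235
n_waves: 4
time_scores: [0, 1, 2, 3]
class_proportions: [0.819, 0.181]
class_means:
  - [3.992, -0.174]
  - [2.641, 0.296]
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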