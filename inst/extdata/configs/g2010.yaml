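# Generator configuration calibrated to the 2010-guideline cohort
# (arrest years 2012-2014): pattern weights match component prevalences
# A 24.9%, B 21.9%, C 6.5%; witnessed rate ~37.5%, PAD ~0.9% of cohort.
n_records: 10000
seed: 1
years: [2012, 2013, 2014]
score_distribution: [0.567106, 0.345421, 0.075042, 0.012431]
p_cpc12: [0.001458, 0.007073, 0.035921, 0.133477]
p_cpc34: [0.007, 0.013, 0.050, 0.130]
component_style:
  one_weights: [0.4895, 0.3907, 0.1198]
  two_weights: [0.85, 0.05, 0.10]
  witnessed_rate_b0: 0.200
  pad_share: 0.146
contamination:
  under_18: 0.0
  external_cause: 0.0
  missing_fields: 0.0
  prehospital_rosc: 0.0
  kanto: 0.0
  transition_year: 0.0
predicted_probabilities: [0.0015, 0.0071, 0.0359, 0.1335]
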