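# Generator configuration calibrated to the 2015-guideline cohort
# (arrest years 2017-2019): pattern weights match component prevalences
# A 23.7%, B 22.4%, C 6.0%; witnessed rate ~37.5%, PAD ~1.1% of cohort.
n_records: 10000
seed: 1
years: [2017, 2018, 2019]
score_distribution: [0.574704, 0.341552, 0.071354, 0.012390]
p_cpc12: [0.001705, 0.008977, 0.046496, 0.167513]
p_cpc34: [0.006, 0.012, 0.050, 0.140]
component_style:
  one_weights: [0.4703, 0.4216, 0.1081]
  two_weights: [0.85, 0.05, 0.10]
  witnessed_rate_b0: 0.195
  pad_share: 0.182
contamination:
  under_18: 0.0
  external_cause: 0.0
  missing_fields: 0.0
  prehospital_rosc: 0.0
  kanto: 0.0
  transition_year: 0.0
predicted_probabilities: [0.0017, 0.0090, 0.0465, 0.1675]
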