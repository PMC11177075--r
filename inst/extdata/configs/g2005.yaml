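# Generator configuration calibrated to the 2005-guideline cohort
# (arrest years 2007-2009): per-score shares and favourable-outcome
# rates from the reconstructed strata; pattern weights solved to match
# the published component prevalences (A 28.7%, B 21.9%, C 7.6%).
# p_cpc34 above score 0 is not published; values chosen to reproduce
# the published score-0 rate (0.8%) and overall CPC 3-4 total (~1.6%).
n_records: 10000
seed: 1
years: [2007, 2008, 2009]
score_distribution: [0.537607, 0.360168, 0.085600, 0.016625]
p_cpc12: [0.001795, 0.005768, 0.029294, 0.095379]
p_cpc34: [0.008, 0.015, 0.050, 0.120]
component_style:
  one_weights: [0.5355, 0.3354, 0.1290]
  two_weights: [0.85, 0.05, 0.10]
  witnessed_rate_b0: 0.214
  pad_share: 0.069
contamination:
  under_18: 0.0
  external_cause: 0.0
  missing_fields: 0.0
  prehospital_rosc: 0.0
  kanto: 0.0
  transition_year: 0.0
# example predicted probabilities for calibration plots (per score 0..3)
predicted_probabilities: [0.0018, 0.0058, 0.0293, 0.0954]
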