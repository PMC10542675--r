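# Study-like synthetic cohort conditions (matches the package defaults).
n_participants: 3038
baseline_window: [0, 31]
min_lead_months: 5
retention:
  intermediate: 0.70
  final: 0.985
pdmooc_rate: 0.588
age_mean: 63.7
age_sd: 7.7
age_min: 50
gender_probs:
  female: 0.716
  male: 0.282
  other: 0.002
education_probs:
  university: 0.553
  post_secondary: 0.279
  school_only: 0.130
  unknown: 0.038
intercept: 2.17
sd_ref: 1.24
re_sd: 0.90
resid_sd: 0.75
beta_exposure_s: -0.03
beta_pdmooc_s: -0.11
beta_interaction_s: -0.03
beta_time: -0.07
a: 0.41
b_s: -0.05
rho_m: 0.5
g_exp: 0.11
unknown_rates:
  alcohol: 0.068
  bmi: 0.044
  hypertension: 0.005
  cholesterol: 0.006
  diabetes: 0.008
  smoking: 0.002
  cognitive_activity: 0.011
  physical_activity: 0.030
  diet: 0.005
followup_unknown_scale: 0.4
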