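# Default model configuration: every published input (mean, standard
# error, distribution family), economic settings, and structural flags.
# Values are carried verbatim from the source input table. Where the
# narrative text and the input table disagree, the table value is used:
# outpatient cost (moderate) is 133 USD (text prints 113), and the annual
# mild-to-moderate transition probability is 0.0620 (text prints 6.4%).
# Inputs published only with a +/-20% variation are marked cv20: the
# probabilistic dispersion used for them is default_cv * mean.
parameters:
  diagnostic:
    p_test_positive:
      mean: 0.899
      se: 0.0339
      family: beta
    p_true_positive:
      mean: 0.8286
      se: 0.0368
      family: beta
    p_false_positive:
      mean: 0.1961
      se: 0.0556
      family: beta
    p_delayed_tdas:
      mean: 0.0071
      se: 0.0071
      family: beta
    p_mild_tdas:
      mean: 0.1111
      se: 0.0786
      family: dirichlet
    p_moderate_tdas:
      mean: 0.5069
      se: 0.0585
      family: dirichlet
    p_severe_tdas:
      mean: 0.3819
      se: 0.0655
      family: dirichlet
    p_diagnosed_clin:
      mean: 0.6731
      se: 0.0376
      family: beta
    p_delayed_clin:
      mean: 0.2
      se: 0.0332
      family: beta
    p_mild_clin:
      mean: 0.0608
      se: 0.0797
      family: dirichlet
    p_moderate_clin:
      mean: 0.3311
      se: 0.0672
      family: dirichlet
    p_severe_clin:
      mean: 0.6081
      se: 0.0515
      family: dirichlet
  transitions:
    tp_mild_moderate:
      mean: 0.062
      se: 0.0538
      family: beta
    tp_mild_severe:
      mean: 0.0
      se: 0.0
      family: fixed
    tp_moderate_mild:
      mean: 0.2643
      se: 0.0226
      family: beta
    tp_moderate_severe:
      mean: 0.0218
      se: 0.0087
      family: beta
    tp_severe_mild:
      mean: 0.0025
      se: 0.0044
      family: beta
    tp_severe_moderate:
      mean: 0.2078
      se: 0.173
      family: beta
    rr_death_asd:
      mean: 2.37
      se: 0.0942
      family: lognormal
  utilities:
    u_mild:
      mean: 0.8659
      se: 0.0085
      family: beta
    u_moderate:
      mean: 0.841
      se: 0.0098
      family: beta
    u_severe:
      mean: 0.793
      se: 0.0177
      family: beta
  direct_medical:
    c_inpatient_mild:
      mean: 387.0
      se: 88.0
      family: gamma
    c_inpatient_moderate:
      mean: 416.0
      se: 38.0
      family: gamma
    c_inpatient_severe:
      mean: 664.0
      se: 53.0
      family: gamma
    p_admission:
      mean: 0.346
      se: 0.028
      family: beta
    p_admitted_mild:
      mean: 0.0585
      family: fixed
    p_admitted_moderate:
      mean: 0.3032
      family: fixed
    p_admitted_severe:
      mean: 0.6383
      family: fixed
    c_outpatient_mild:
      mean: 66.0
      se: 11.0
      family: gamma
    c_outpatient_moderate:
      mean: 133.0
      se: 7.0
      family: gamma
    c_outpatient_severe:
      mean: 124.0
      se: 12.0
      family: gamma
    c_instruments_mild:
      mean: 11.0
      se: 26.0
      family: gamma
    c_instruments_moderate:
      mean: 197.0
      se: 24.0
      family: gamma
    c_instruments_severe:
      mean: 199.0
      se: 25.0
      family: gamma
    p_instruments_mild:
      mean: 0.5565
      family: fixed
    p_instruments_moderate:
      mean: 0.6852
      family: fixed
    p_instruments_severe:
      mean: 0.8966
      family: fixed
    c_activities_mild:
      mean: 1314.0
      se: 246.0
      family: gamma
    c_activities_moderate:
      mean: 1148.0
      se: 188.0
      family: gamma
    c_activities_severe:
      mean: 1152.0
      se: 216.0
      family: gamma
    p_activities_mild:
      mean: 0.2114
      family: fixed
    p_activities_moderate:
      mean: 0.2243
      family: fixed
    p_activities_severe:
      mean: 0.4561
      family: fixed
  direct_nonmedical:
    c_travel_outpatient:
      mean: 13.0
      se: 0.9
      family: gamma
    c_food_outpatient:
      mean: 8.0
      se: 0.5
      family: gamma
    c_accommodation_outpatient:
      mean: 24.0
      se: 3.6
      family: gamma
    p_accommodation_outpatient:
      mean: 0.6
      se: 0.03
      family: beta
    n_visits_mild:
      mean: 5.13
      se: 0.49
      family: gamma
    n_visits_moderate:
      mean: 4.89
      se: 0.48
      family: gamma
    n_visits_severe:
      mean: 6.65
      se: 0.91
      family: gamma
    c_caregiver_outpatient:
      mean: 38.0
      se: 3.0
      family: gamma
    c_travel_admission_patient:
      mean: 48.0
      se: 6.0
      family: gamma
    c_food_admission_patient:
      mean: 9.0
      se: 0.7
      family: gamma
    c_accommodation_admission_patient:
      mean: 15.0
      se: 1.0
      family: gamma
    p_accommodation_admission:
      mean: 0.385
      se: 0.078
      family: beta
    c_travel_admission_caregiver:
      mean: 63.0
      se: 10.0
      family: gamma
    c_food_admission_caregiver:
      mean: 80.0
      se: 8.0
      family: gamma
    c_accommodation_admission_caregiver:
      mean: 183.0
      se: 48.0
      family: gamma
    c_caregiver_admission:
      mean: 225.0
      se: 105.0
      family: gamma
    n_admissions_per_year:
      mean: 1.0
      family: fixed
  caregiver_home:
    c_hired_caregiver:
      mean: 196.0
      se: 32.0
      family: gamma
    p_hired_caregiver:
      mean: 0.058
      family: fixed
    c_lost_income:
      mean: 518.0
      se: 53.0
      family: gamma
    p_quit_mild:
      mean: 0.1778
      family: fixed
    p_quit_moderate:
      mean: 0.1348
      family: fixed
    p_quit_severe:
      mean: 0.2364
      family: fixed
  strategy_costs:
    c_tdas_training:
      mean: 151.0
      family: gamma
      cv20: yes
    c_tdas_instruments:
      mean: 323.0
      family: gamma
      cv20: yes
    c_tdas_maintenance:
      mean: 0.27
      family: gamma
      cv20: yes
    c_cloud_service:
      mean: 1.43
      family: gamma
      cv20: yes
    c_labor_tdas:
      mean: 134.0
      family: gamma
      cv20: yes
    c_labor_clin:
      mean: 61.0
      family: gamma
      cv20: yes
    n_diagnoses_per_week:
      mean: 2.0
      family: fixed
  scenario:
    p_mild_clin_scenario:
      mean: 0.1139
      family: fixed
    p_moderate_clin_scenario:
      mean: 0.4557
      family: fixed
    p_severe_clin_scenario:
      mean: 0.4304
      family: fixed
economics:
  discount_rate: 0.03
  wtp_thb: 160000.0
  exchange_rate: 34.994999999999997
  start_age: 3.52
  max_age: 100.0
  psa_iterations: 10000.0
  default_cv: 0.2
flags:
  tree_interpretation: renormalize
  asd_prevalence: .na.real
  u_non_asd: 0.0
  fp_workup_cost: 0.0
  half_cycle_correction: no
  instrument_mode: entry
  dirichlet_neff: min
  dirichlet_counts:
    tdas: 147.0
    clin: 148.0
  rr_se_scale: natural
  amortization_diagnoses_per_provider_year: 104.0
life_table: bundled
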