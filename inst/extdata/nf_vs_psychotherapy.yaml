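strategies:
- name: nf_ot
  per_session_cost: 140.0
  sessions_per_course: 13.5
  per_course_cost: 1890.0
  annual_drug_cost: 0.0
  dropout_course_prob: 0.132
  relapse_prob: 0.14
  retreatment_prob: 0.5
  effect_mean: 7.01
  effect_dispersion: 11.300000000000001
  effect_dispersion_kind: ci95
  course_cycles: 1.0
  relapse_cycles: 1.0
- name: psychotherapy
  per_session_cost: 147.0
  sessions_per_course: 13.5
  per_course_cost: 1985.0
  annual_drug_cost: 0.0
  dropout_course_prob: 0.206
  relapse_prob: 0.14
  retreatment_prob: 0.5
  effect_mean: 6.25
  effect_dispersion: 4.94
  effect_dispersion_kind: sd
  course_cycles: 1.0
  relapse_cycles: 1.0
state_costs:
  severe: 5880.0
  moderate: 4900.0
  mild: 3450.0
  asymptomatic: 0.0
mortality:
  severe: 0.001
  moderate: 0.0008
  mild: 0.00065
  asymptomatic: 0.0005
bands:
- label: severe
  caps5_low: 60
  caps5_high: 80
- label: moderate
  caps5_low: 40
  caps5_high: 59
- label: mild
  caps5_low: 20
  caps5_high: 39
- label: asymptomatic
  caps5_low: 0
  caps5_high: 19
horizon_cycles: 12
cycle_length_years: 0.25
annual_discount_rate: 0.03
wtp_per_qaly: 0.0
initial_distribution:
  severe: 0.333333333333333
  moderate: 0.333333333333333
  mild: 0.333333333333333
  asymptomatic: 0.0
regression:
  intercept: 92.0
  slope: -0.68
psa_distributions:
  strategies.nf_ot.dropout_course_prob:
    family: beta
    param_a: 21.567999999999998
    param_b: 141.825939393939365
    derived_from:
      mean: 0.132
      sd: 0.0264
  strategies.nf_ot.relapse_prob:
    family: beta
    param_a: 21.359999999999999
    param_b: 131.211428571428542
    derived_from:
      mean: 0.14
      sd: 0.028
  strategies.nf_ot.retreatment_prob:
    family: beta
    param_a: 4.835555555555553
    param_b: 4.835555555555553
    derived_from:
      mean: 0.5
      sd: 0.153061224489796
  strategies.nf_ot.effect_mean:
    family: normal
    param_a: 7.01
    param_b: 2.88265306122449
    derived_from:
      mean: 7.01
      sd: 2.88265306122449
  strategies.nf_ot.per_course_cost:
    family: gamma
    param_a: 25.0
    param_b: 75.599999999999994
    derived_from:
      mean: 1890.0
      sd: 378.0
  strategies.psychotherapy.dropout_course_prob:
    family: beta
    param_a: 111.765952642214515
    param_b: 430.787215523875432
    derived_from:
      mean: 0.206
      sd: 0.01734693877551
  strategies.psychotherapy.relapse_prob:
    family: beta
    param_a: 21.359999999999999
    param_b: 131.211428571428542
    derived_from:
      mean: 0.14
      sd: 0.028
  strategies.psychotherapy.retreatment_prob:
    family: beta
    param_a: 4.835555555555553
    param_b: 4.835555555555553
    derived_from:
      mean: 0.5
      sd: 0.153061224489796
  strategies.psychotherapy.effect_mean:
    family: normal
    param_a: 6.25
    param_b: 4.94
    derived_from:
      mean: 6.25
      sd: 4.94
  strategies.psychotherapy.per_course_cost:
    family: gamma
    param_a: 25.0
    param_b: 79.400000000000006
    derived_from:
      mean: 1985.0
      sd: 397.0
  state_costs.severe:
    family: gamma
    param_a: 25.0
    param_b: 235.199999999999989
    derived_from:
      mean: 5880.0
      sd: 1176.0
  state_costs.moderate:
    family: gamma
    param_a: 25.0
    param_b: 196.0
    derived_from:
      mean: 4900.0
      sd: 980.0
  state_costs.mild:
    family: gamma
    param_a: 25.0
    param_b: 138.0
    derived_from:
      mean: 3450.0
      sd: 690.0
seed: 20251
half_cycle_correction: no
bill_therapy_every_cycle: no
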