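# Scenario bundle: two health-promoting interventions vs no intervention,
# 4-year horizon, 3% annual discounting, cohort starting all-mild.
discount_rate: 0.03
horizon: 4
cohort_size: 100
files:
  transition_matrix: transition_probabilities.csv
  payoffs: state_payoffs.csv
  trial_arms: trial_arms.csv
  cost_items: intervention_cost_items.csv
  interventions: interventions.csv
scenarios:
  - label: control
  - label: senior_meetings
    arm: SM
    convention: overall_rr_nondeath
    schedule: year1_only
  - label: preventive_home_visit
    arm: PV
    convention: overall_rr_nondeath
    schedule: year1_only
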