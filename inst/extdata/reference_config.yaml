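study:
  country: FRA
  sex: female
  start_age: 60
  start_stage: III
  max_cycles: 60
  discount_rate_costs: 0.03
  discount_rate_effects: 0.03
  wtp_threshold: 23500.0
  half_cycle_correction: no
  recurrence_source: alt_table_row
  initial_cost_at_start: yes
  advanced_cost_on_general_death: no
  lb_followup_in_stage_iv: yes
  occupancy_epsilon: 1.0e-09
  composition: sequential
parameters:
  country: FRA
  sex: female
  lb_test_cost: 441.449999999999989
  inflation_rate: 0.04
  stages:
  - stage: I
    utility: 0.74
    stay_prob: 0.983
    alt_recurrence_prob: 0.01
    crc_death_prob: 0.015
    cost_initial: 13584.479999999999563
    cost_followup: 601.909999999999968
    cost_advanced: 17488.520000000000437
  - stage: II
    utility: 0.74
    stay_prob: 0.944
    alt_recurrence_prob: 0.025
    crc_death_prob: 0.039
    cost_initial: 17488.520000000000437
    cost_followup: 601.909999999999968
    cost_advanced: 24553.720000000001164
  - stage: III
    utility: 0.67
    stay_prob: 0.887
    alt_recurrence_prob: 0.077
    crc_death_prob: 0.078
    cost_initial: 24553.720000000001164
    cost_followup: 845.07000000000005
    cost_advanced: 29300.68999999999869
  - stage: IV
    utility: 0.25
    stay_prob: .na.real
    alt_recurrence_prob: .na.real
    crc_death_prob: 0.33
    cost_initial: 29300.68999999999869
    cost_followup: 1008.460000000000036
    cost_advanced: 29300.68999999999869
comparators:
  standard_care:
    name: standard care
    mort_multiplier: 1.0
    prog_multiplier: 1.0
    lb_enabled: no
    lb_test_cost: 441.449999999999989
  mort0_tx1:
    name: MortSuccess 0% - TxSuccess 1%
    mort_multiplier: 1.0
    prog_multiplier: 0.99
    lb_enabled: yes
    lb_test_cost: 441.449999999999989
  mort0_tx3:
    name: MortSuccess 0% - TxSuccess 3%
    mort_multiplier: 1.0
    prog_multiplier: 0.97
    lb_enabled: yes
    lb_test_cost: 441.449999999999989
  mort1_tx0:
    name: MortSuccess 1% - TxSuccess 0%
    mort_multiplier: 0.99
    prog_multiplier: 1.0
    lb_enabled: yes
    lb_test_cost: 441.449999999999989
  mort3_tx0:
    name: MortSuccess 3% - TxSuccess 0%
    mort_multiplier: 0.97
    prog_multiplier: 1.0
    lb_enabled: yes
    lb_test_cost: 441.449999999999989
  mort1_tx1:
    name: MortSuccess 1% - TxSuccess 1%
    mort_multiplier: 0.99
    prog_multiplier: 0.99
    lb_enabled: yes
    lb_test_cost: 441.449999999999989
  mort3_tx3:
    name: MortSuccess 3% - TxSuccess 3%
    mort_multiplier: 0.97
    prog_multiplier: 0.97
    lb_enabled: yes
    lb_test_cost: 441.449999999999989
  validation:
    name: validation (zero-effect LB)
    mort_multiplier: 1.0
    prog_multiplier: 1.0
    lb_enabled: yes
    lb_test_cost: 441.449999999999989
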