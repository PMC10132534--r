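model: aggregate
pathways:
- name: All
  proportion: 1.0
  shelter_policy: until_housing
  priority: 1
  housing_time:
    kind: fixed
    value: 10.0
arrivals:
  base_rate: 1.0
  start_date: '2023-01-01'
  year_factors: []
  compounding: yes
  fixed:
    times:
    - 0.0
    - 1.0
    - 2.0
    pathways:
    - 1
    - 1
    - 1
returns:
  probability: 0.0
  delay:
    kind: fixed
    value: 1.0
  reassign_pathway: yes
policy:
  name: micro
  provenance: ~
  schedules:
  - resource: shelter
    dates: '2023-01-01'
    units: 1
    interpolation: step
  - resource: All
    dates: '2023-01-01'
    units: 1
    interpolation: step
initial:
  capacity:
    shelter: 1
    All: 1
  occupied:
    shelter: 0
    All: 0
  queue:
    All: 0
  shelter_mix:
    All: 0
  residual_time_rule: stationary_residual
horizon:
- '2023-01-01'
- '2023-01-31'
sample_interval_days: 1.0
replications: 1
master_seed: 1
unit_costs: ~
options:
  admission_rule: fifo_overall
  include_sr_in_unmet: yes
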