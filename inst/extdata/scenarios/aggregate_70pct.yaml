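model: aggregate
pathways:
- name: All
  proportion: 1.0
  shelter_policy: until_housing
  priority: 1
  housing_time:
    kind: triangular
    min: 0.0
    mode: 2191.5
    max: 2922.0
arrivals:
  base_rate: 10.0
  start_date: '2022-01-01'
  year_factors:
    '2022': 1.2
    '2023': 1.1
    '2024': 1.0
    '2025': 0.9
    '2026': 0.9
  compounding: yes
  fixed: ~
returns:
  probability: 0.17
  delay:
    kind: uniform
    min: 0.0
    max: 730.0
  reassign_pathway: yes
policy:
  name: aggregate_70pct
  provenance: 70% of the plan's housing anchors; shelter held at its running maximum
  schedules:
  - resource: shelter
    dates:
    - '2022-01-01'
    - '2023-01-01'
    - '2024-01-01'
    - '2025-01-01'
    - '2026-01-01'
    - '2027-01-01'
    units:
    - 1500
    - 2500
    - 3200
    - 3200
    - 3200
    - 3200
    interpolation: linear
  - resource: All
    dates:
    - '2022-01-01'
    - '2023-01-01'
    - '2024-01-01'
    - '2025-01-01'
    - '2026-01-01'
    - '2027-01-01'
    units:
    - 2800
    - 4200
    - 6720
    - 9520
    - 13510
    - 16800
    interpolation: linear
initial:
  capacity:
    shelter: 1500
    All: 4000
  occupied:
    shelter: 1500
    All: 4000
  queue:
    All: 3456
  shelter_mix:
    All: 1500
  residual_time_rule: stationary_residual
horizon:
- '2022-01-01'
- '2027-12-31'
sample_interval_days: 7.0
replications: 100
master_seed: 20230426
unit_costs: ~
options:
  admission_rule: fifo_overall
  include_sr_in_unmet: yes
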