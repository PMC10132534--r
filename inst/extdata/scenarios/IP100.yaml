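model: detailed
pathways:
- name: Youth
  proportion: 0.02
  shelter_policy: none
  priority: 5
  housing_time:
    kind: uniform
    min: 365.25
    max: 730.5
- name: RR-Long
  proportion: 0.1
  shelter_policy: none
  priority: 5
  housing_time:
    kind: triangular
    min: 730.5
    mode: 2191.5
    max: 2922.0
- name: RR-Short
  proportion: 0.1
  shelter_policy: none
  priority: 5
  housing_time:
    kind: fixed
    value: 91.0
- name: RRH
  proportion: 0.15
  shelter_policy: until_housing
  priority: 3
  housing_time:
    kind: uniform
    min: 365.25
    max: 730.5
- name: SR
  proportion: 0.1
  shelter_policy: fixed_stay
  priority: 4
  shelter_stay:
    kind: fixed
    value: 152.0
- name: DA
  proportion: 0.28
  shelter_policy: until_housing
  priority: 2
  housing_time:
    kind: triangular
    min: 730.5
    mode: 2191.5
    max: 2922.0
- name: PSH
  proportion: 0.15
  shelter_policy: until_housing
  priority: 1
  housing_time:
    kind: triangular
    min: 730.5
    mode: 2191.5
    max: 2922.0
- name: PSH-Seniors
  proportion: 0.1
  shelter_policy: until_housing
  priority: 1
  housing_time:
    kind: triangular
    min: 730.5
    mode: 2191.5
    max: 2922.0
arrivals:
  base_rate: 10.0
  start_date: '2023-01-01'
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
  name: IP100
  provenance: baseline proportional-need plan; units by end of year; 2024 shelter
    anchor read as 3,221 (source prints '3.221')
  schedules:
  - resource: shelter
    dates:
    - '2023-12-31'
    - '2024-12-31'
    - '2025-12-31'
    - '2026-12-31'
    - '2027-12-31'
    units:
    - 2652
    - 3221
    - 2984
    - 1652
    - 1253
    interpolation: linear
  - resource: Youth
    dates:
    - '2023-12-31'
    - '2024-12-31'
    - '2025-12-31'
    - '2026-12-31'
    - '2027-12-31'
    units:
    - 104
    - 121
    - 138
    - 195
    - 173
    interpolation: linear
  - resource: RR-Long
    dates:
    - '2023-12-31'
    - '2024-12-31'
    - '2025-12-31'
    - '2026-12-31'
    - '2027-12-31'
    units:
    - 677
    - 1459
    - 2260
    - 3416
    - 4368
    interpolation: linear
  - resource: RR-Short
    dates:
    - '2023-12-31'
    - '2024-12-31'
    - '2025-12-31'
    - '2026-12-31'
    - '2027-12-31'
    units:
    - 130
    - 152
    - 173
    - 244
    - 216
    interpolation: linear
  - resource: RRH
    dates:
    - '2023-12-31'
    - '2024-12-31'
    - '2025-12-31'
    - '2026-12-31'
    - '2027-12-31'
    units:
    - 1120
    - 1305
    - 1488
    - 2100
    - 1857
    interpolation: linear
  - resource: DA
    dates:
    - '2023-12-31'
    - '2024-12-31'
    - '2025-12-31'
    - '2026-12-31'
    - '2027-12-31'
    units:
    - 1459
    - 3085
    - 4869
    - 7359
    - 9411
    interpolation: linear
  - resource: PSH
    dates:
    - '2023-12-31'
    - '2024-12-31'
    - '2025-12-31'
    - '2026-12-31'
    - '2027-12-31'
    units:
    - 3351
    - 4054
    - 4837
    - 6013
    - 6914
    interpolation: linear
  - resource: PSH-Seniors
    dates:
    - '2023-12-31'
    - '2024-12-31'
    - '2025-12-31'
    - '2026-12-31'
    - '2027-12-31'
    units:
    - 521
    - 1086
    - 1691
    - 2532
    - 3194
    interpolation: linear
initial:
  capacity:
    shelter: 2500
    Youth: 85
    RR-Long: 552
    RR-Short: 106
    RRH: 913
    DA: 1189
    PSH: 2731
    PSH-Seniors: 424
  occupied:
    shelter: 2500
    Youth: 85
    RR-Long: 552
    RR-Short: 106
    RRH: 913
    DA: 1189
    PSH: 2731
    PSH-Seniors: 424
  queue:
    Youth: 69
    RR-Long: 346
    RR-Short: 346
    RRH: 518
    SR: 346
    DA: 968
    PSH: 518
    PSH-Seniors: 345
  shelter_mix:
    Youth: 0
    RR-Long: 0
    RR-Short: 0
    RRH: 481
    SR: 321
    DA: 897
    PSH: 481
    PSH-Seniors: 320
  residual_time_rule: stationary_residual
horizon:
- '2023-01-01'
- '2028-12-31'
sample_interval_days: 7.0
replications: 100
master_seed: 20230426
unit_costs: ~
options:
  admission_rule: fifo_overall
  include_sr_in_unmet: yes
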