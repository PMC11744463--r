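# Example pipeline configuration.
# Every stochastic command requires an explicit seed.

generator:
  n_per_arm: 217
  n_centres: 20
  seed: 1

missingness:
  mechanism: MAR
  rate: 0.2
  seed: 2

within_trial:
  seed: 3
  m: 20
  B: 1000
  discount_rate: 0.035
  thresholds: [13000, 20000, 30000]
  unit_costs: unit_costs_synthetic

model:
  seed: 4
  horizon: 120
  start_age: 50.5
  prop_female: 0.71
  tunnel_months: 1
  p_resolved: 0.6
  surgery_episode_cost: 2900
  discount_rate: 0.035
  life_table: life_table_synthetic
  thresholds: [13000, 20000, 30000]
  LC:
    uptake: 0.705
  CM:
    uptake: 0.295
  psa:
    n_draws: 1000
    params:
      - name: p_resolved
        dist: beta
        mean: 0.6
        se: 0.1
      - name: surgery_episode_cost
        dist: gamma
        mean: 2900
        se: 290
      - name: "utility:RecoveryTunnel"
        dist: beta_utility
        mean: 0.60
        se: 0.05
      - name: "utility:SymptomsResolved"
        dist: beta_utility
        mean: 0.73
        se: 0.03
      - name: "utility:SymptomsPersist"
        dist: beta_utility
        mean: 0.73
        se: 0.03
      - name: hazard_scale
        dist: gamma
        mean: 1.0
        se: 0.1
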