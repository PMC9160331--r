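# Two-bottle preference test: two internal dimensions (water, sodium),
# three actions (do nothing, water intake, saltwater intake).  Saltwater
# delivers a positive water component as well as sodium, so it partially
# relieves water deficit.  Four depletion groups differ only in the
# initial internal state; depleted dimensions start at 0, fulfilled at H*.
name: sim3_two_bottle
n_agents: 100
base_seed: 857009
groups:
- label: control
  dim_names: [water, sodium]
  setpoint: [50.0, 50.0]
  exponent_n: 4.0
  exponent_m: 3.0
  tau: [500.0, 500.0]
  alpha_q: 0.035
  alpha_khat: 0.035
  beta: 1.6
  reward_mode: predicted_taste
  initial_state: [50.0, 50.0]
  n_trials: 200
  actions:
  - {label: do_nothing, intake: [0.0, 0.0], q0: 0.0}
  - {label: water_intake, intake: [1.0, 0.0], q0: 0.0}
  - {label: saltwater_intake, intake: [0.5, 1.0], q0: 0.0}
  metadata: {seconds_per_trial: 6}
- label: sodium_depleted
  dim_names: [water, sodium]
  setpoint: [50.0, 50.0]
  exponent_n: 4.0
  exponent_m: 3.0
  tau: [500.0, 500.0]
  alpha_q: 0.035
  alpha_khat: 0.035
  beta: 1.6
  reward_mode: predicted_taste
  initial_state: [50.0, 0.0]
  n_trials: 200
  actions:
  - {label: do_nothing, intake: [0.0, 0.0], q0: 0.0}
  - {label: water_intake, intake: [1.0, 0.0], q0: 0.0}
  - {label: saltwater_intake, intake: [0.5, 1.0], q0: 0.0}
  metadata: {seconds_per_trial: 6}
- label: water_depleted
  dim_names: [water, sodium]
  setpoint: [50.0, 50.0]
  exponent_n: 4.0
  exponent_m: 3.0
  tau: [500.0, 500.0]
  alpha_q: 0.035
  alpha_khat: 0.035
  beta: 1.6
  reward_mode: predicted_taste
  initial_state: [0.0, 50.0]
  n_trials: 200
  actions:
  - {label: do_nothing, intake: [0.0, 0.0], q0: 0.0}
  - {label: water_intake, intake: [1.0, 0.0], q0: 0.0}
  - {label: saltwater_intake, intake: [0.5, 1.0], q0: 0.0}
  metadata: {seconds_per_trial: 6}
- label: water_salt_depleted
  dim_names: [water, sodium]
  setpoint: [50.0, 50.0]
  exponent_n: 4.0
  exponent_m: 3.0
  tau: [500.0, 500.0]
  alpha_q: 0.035
  alpha_khat: 0.035
  beta: 1.6
  reward_mode: predicted_taste
  initial_state: [0.0, 0.0]
  n_trials: 200
  actions:
  - {label: do_nothing, intake: [0.0, 0.0], q0: 0.0}
  - {label: water_intake, intake: [1.0, 0.0], q0: 0.0}
  - {label: saltwater_intake, intake: [0.5, 1.0], q0: 0.0}
  metadata: {seconds_per_trial: 6}
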