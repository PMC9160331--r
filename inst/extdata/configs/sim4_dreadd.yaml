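# Chemogenetic (DREADD) manipulation in the two-bottle setting.  A tonic
# negative bias `lpbn` acts on the saltwater action at selection time
# only; DREADD adds the cancelling `drd = lpbn`.  The saltwater action's
# initial Q is set to lpbn so the control group's effective values start
# level (selection probability 0.5 between saltwater and do nothing).
name: sim4_dreadd
n_agents: 100
base_seed: 857009
groups:
- label: water_depleted_control
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
  bias: {lpbn: 1.0, drd: 1.0, dreadd_on: false, biased_action: saltwater_intake}
  actions:
  - {label: do_nothing, intake: [0.0, 0.0], q0: 0.0}
  - {label: water_intake, intake: [1.0, 0.0], q0: 0.0}
  - {label: saltwater_intake, intake: [0.5, 1.0], q0: 1.0}
  metadata: {seconds_per_trial: 6}
- label: water_depleted_dreadd
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
  bias: {lpbn: 1.0, drd: 1.0, dreadd_on: true, biased_action: saltwater_intake}
  actions:
  - {label: do_nothing, intake: [0.0, 0.0], q0: 0.0}
  - {label: water_intake, intake: [1.0, 0.0], q0: 0.0}
  - {label: saltwater_intake, intake: [0.5, 1.0], q0: 1.0}
  metadata: {seconds_per_trial: 6}
- label: sodium_depleted_control
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
  bias: {lpbn: 1.0, drd: 1.0, dreadd_on: false, biased_action: saltwater_intake}
  actions:
  - {label: do_nothing, intake: [0.0, 0.0], q0: 0.0}
  - {label: water_intake, intake: [1.0, 0.0], q0: 0.0}
  - {label: saltwater_intake, intake: [0.5, 1.0], q0: 1.0}
  metadata: {seconds_per_trial: 6}
- label: sodium_depleted_dreadd
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
  bias: {lpbn: 1.0, drd: 1.0, dreadd_on: true, biased_action: saltwater_intake}
  actions:
  - {label: do_nothing, intake: [0.0, 0.0], q0: 0.0}
  - {label: water_intake, intake: [1.0, 0.0], q0: 0.0}
  - {label: saltwater_intake, intake: [0.5, 1.0], q0: 1.0}
  metadata: {seconds_per_trial: 6}
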