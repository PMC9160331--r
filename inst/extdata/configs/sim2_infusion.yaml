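# Intragastric infusion test: taste acts as the reward's predictor of
# internal-state change (reward_mode: predicted_taste) while the state
# itself moves only by actual intake.  Control starts sodium-depleted
# (H0 = 0); the IG-infusion group starts half-satisfied (H0 = H*/2);
# the oral-stimulation group is depleted but receives a constant strong
# salty stimulus entering the predicted-intake term on every trial.
# 100 trials correspond to the 600 s test (6 s per trial, metadata only).
name: sim2_infusion
n_agents: 100
base_seed: 857009
groups:
- label: control
  dim_names: [sodium]
  setpoint: [50.0]
  exponent_n: 4.0
  exponent_m: 3.0
  tau: [50.0]
  alpha_q: 0.035
  alpha_khat: 0.035
  beta: 1.6
  reward_mode: predicted_taste
  initial_state: [0.0]
  n_trials: 100
  actions:
  - {label: do_nothing, intake: [0.0], q0: 0.0}
  - {label: intake, intake: [1.0], taste: [1.0], q0: 0.0}
  metadata: {seconds_per_trial: 6}
- label: ig_infusion
  dim_names: [sodium]
  setpoint: [50.0]
  exponent_n: 4.0
  exponent_m: 3.0
  tau: [50.0]
  alpha_q: 0.035
  alpha_khat: 0.035
  beta: 1.6
  reward_mode: predicted_taste
  initial_state: [25.0]
  n_trials: 100
  actions:
  - {label: do_nothing, intake: [0.0], q0: 0.0}
  - {label: intake, intake: [1.0], taste: [1.0], q0: 0.0}
  metadata: {seconds_per_trial: 6}
- label: oral_stimulation
  dim_names: [sodium]
  setpoint: [50.0]
  exponent_n: 4.0
  exponent_m: 3.0
  tau: [50.0]
  alpha_q: 0.035
  alpha_khat: 0.035
  beta: 1.6
  reward_mode: predicted_taste
  initial_state: [0.0]
  n_trials: 100
  ambient_stimulus: [50.0]
  actions:
  - {label: do_nothing, intake: [0.0], q0: 0.0}
  - {label: intake, intake: [1.0], taste: [1.0], q0: 0.0}
  metadata: {seconds_per_trial: 6}
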