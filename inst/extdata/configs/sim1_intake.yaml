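# Sodium intake test: one sodium dimension, do-nothing vs intake, reward
# from actual intake.  Parameter values calibrated so that the 100-agent
# cohort landmark medians fall near trials ~20 (P(intake) > 0.95), ~80
# (first overshoot of the setpoint) and ~140 (first return below it).
name: sim1_intake
n_agents: 100
base_seed: 857009
groups:
- label: standard
  dim_names: [sodium]
  setpoint: [50.0]
  exponent_n: 4.0
  exponent_m: 3.0
  tau: [100.0]
  alpha_q: 0.035
  alpha_khat: 0.035
  beta: 1.6
  reward_mode: actual_intake
  initial_state: [0.0]
  n_trials: 200
  actions:
  - {label: do_nothing, intake: [0.0], q0: 0.0}
  - {label: intake, intake: [1.0], q0: 0.0}
  metadata: {seconds_per_trial: 6}
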