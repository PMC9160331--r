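# Saltwater density preference: two groups of sodium-replete agents
# (H0 = H*) differing only in the sodium delivered per intake.  The
# smaller per-intake delivery of the low-density fluid incurs less
# overshoot punishment, so the low-density cohort accumulates more licks.
name: sim1_density
n_agents: 100
base_seed: 857009
groups:
- label: low_density
  dim_names: [sodium]
  setpoint: [50.0]
  exponent_n: 4.0
  exponent_m: 3.0
  tau: [100.0]
  alpha_q: 0.035
  alpha_khat: 0.035
  beta: 1.6
  reward_mode: actual_intake
  initial_state: [50.0]
  n_trials: 200
  actions:
  - {label: do_nothing, intake: [0.0], q0: 0.0}
  - {label: intake, intake: [0.4], q0: 0.0}
  metadata: {seconds_per_trial: 6}
- label: high_density
  dim_names: [sodium]
  setpoint: [50.0]
  exponent_n: 4.0
  exponent_m: 3.0
  tau: [100.0]
  alpha_q: 0.035
  alpha_khat: 0.035
  beta: 1.6
  reward_mode: actual_intake
  initial_state: [50.0]
  n_trials: 200
  actions:
  - {label: do_nothing, intake: [0.0], q0: 0.0}
  - {label: intake, intake: [2.0], q0: 0.0}
  metadata: {seconds_per_trial: 6}
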