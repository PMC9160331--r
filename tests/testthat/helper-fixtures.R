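# Shared fixtures and independent closed-form oracles.

# minimal one-dimensional sodium configuration (defaults match the sodium
# intake test geometry; individual tests override as needed)
sodium_config <- function(K = 1, tau = 100, alpha_q = 0.1, beta = 1,
                          n_trials = 50, H0 = 0, setpoint = 50,
                          q0_nothing = 0, q0_intake = 0, ...) {
  hrl_config(
    actions = list(hrl_action("do_nothing", 0, q0 = q0_nothing),
                   hrl_action("intake", K, q0 = q0_intake)),
    setpoint = setpoint, tau = tau, initial_state = H0,
    n_trials = n_trials, alpha_q = alpha_q, beta = beta, ...)
}

# geometric decay closed form: H_t = H_0 (1 - 1/tau)^t
decay_closed_form <- function(H0, tau, t) H0 * (1 - 1 / tau)^t

# repeated delta-rule update from 0 toward a constant target:
# x_t = target (1 - (1 - alpha)^t)
delta_rule_closed_form <- function(target, alpha, t) target * (1 - (1 - alpha)^t)

# hand-built trajectory carrying arbitrary records, for landmark tests
fake_trajectory <- function(records, config, agent_id = 0L) {
  structure(list(agent_id = as.integer(agent_id), seed = 0L,
                 config_digest = "fixture", records = records,
                 config = config),
            class = "hrl_trajectory")
}
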