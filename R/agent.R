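# The trial loop binding core dynamics and learning into an agent, plus
# episode (run_agent) and cohort (run_cohort) execution with full seed
# control.

#' Define an action available to the agent
#'
#' Each action carries its true intake vector `K` (the internal-state
#' change its execution actually delivers), an initial taste predictor
#' `K-hat_0` (defaulting to the true intake, i.e. a pre-learned taste),
#' and an initial action value.  Exactly one action of a configuration
#' must be the do-nothing action with an all-zero intake.
#'
#' @param label Action identifier (letters, digits, `_`, `.` or `-`).
#' @param intake Numeric intake vector `K`, componentwise `>= 0`.
#' @param taste Initial taste predictor; defaults to `intake`.
#' @param q0 Initial action value.
#' @return An object of class `hrl_action`.
#' @export
hrl_action <- function(label, intake, taste = intake, q0 = 0) {
  .check(is.character(label) && length(label) == 1 &&
           grepl("^[A-Za-z0-9_.-]+$", label),
         "`label` must be a single identifier made of [A-Za-z0-9_.-]")
  intake <- as.numeric(intake); taste <- as.numeric(taste)
  .check(all(is.finite(intake)) && all(intake >= 0),
         "action '%s': intake vector must be finite and >= 0", label)
  .check(length(taste) == length(intake) && all(is.finite(taste)),
         "action '%s': taste predictor must be finite and match the intake dimension",
         label)
  .check(is.numeric(q0) && length(q0) == 1 && is.finite(q0),
         "action '%s': `q0` must be a single finite number", label)
  structure(list(label = label, intake = intake, taste = taste,
                 q0 = as.numeric(q0)),
            class = "hrl_action")
}

#' Agent configuration
#'
#' Bundles the homeostatic space, the action set, the learning and policy
#' parameters, and the episode layout into a validated configuration.
#'
#' Two reward modes are supported.  With `reward_mode = "actual_intake"`
#' the reward on each trial is computed from the taken action's true
#' intake `K`.  With `reward_mode = "predicted_taste"` it is computed from
#' the taken action's current taste predictor `K-hat` (plus the ambient
#' oral stimulus, if one is configured) — the taste acts as a predictor of
#' the internal-state change, while the state itself always moves by the
#' true intake only.
#'
#' @param actions List of [hrl_action()] objects; exactly one must have an
#'   all-zero intake (the do-nothing action).
#' @param setpoint Ideal internal state `H*`, one entry per dimension.
#' @param tau Decay constants, one per dimension (trials, `>= 1`).
#' @param initial_state Internal state at trial 0.
#' @param n_trials Number of trials in an episode.
#' @param alpha_q Action-value learning rate in `(0, 1]`.
#' @param alpha_khat Taste-predictor learning rate in `(0, 1]`.
#' @param beta Nonnegative inverse temperature of the softmax policy.
#' @param exponent_n,exponent_m Drive-function exponents, see
#'   [drive_params()].
#' @param reward_mode `"actual_intake"` or `"predicted_taste"`.
#' @param bias Optional [bias_params()] selection-time bias.
#' @param ambient_stimulus Optional ambient oral stimulus vector, added to
#'   the predicted-intake term of the reward on every trial regardless of
#'   the selected action; never applied to the state transition.  Requires
#'   `reward_mode = "predicted_taste"`.
#' @param dim_names Optional names of the internal-state dimensions;
#'   defaults to `"sodium"` for one dimension and `c("water", "sodium")`
#'   for two.
#' @param metadata Optional free-form list (e.g. seconds per trial)
#'   carried along but never interpreted.
#' @return An object of class `hrl_config`.
#' @examples
#' cfg <- hrl_config(
#'   actions = list(hrl_action("do_nothing", 0), hrl_action("intake", 1)),
#'   setpoint = 50, tau = 100, initial_state = 0, n_trials = 200,
#'   alpha_q = 0.1)
#' cfg
#' @export
hrl_config <- function(actions, setpoint, tau, initial_state, n_trials,
                       alpha_q, alpha_khat = alpha_q, beta = 1,
                       exponent_n = 4, exponent_m = 3,
                       reward_mode = c("actual_intake", "predicted_taste"),
                       bias = NULL, ambient_stimulus = NULL,
                       dim_names = NULL, metadata = list()) {
  reward_mode <- match.arg(reward_mode)
  .check(is.list(actions) && length(actions) >= 2 &&
           all(vapply(actions, inherits, logical(1), "hrl_action")),
         "`actions` must be a list of at least two hrl_action objects")
  labels <- vapply(actions, `[[`, character(1), "label")
  .check(!anyDuplicated(labels), "action labels must be unique")

  drive_p <- drive_params(setpoint, exponent_n, exponent_m)
  decay <- decay_params(tau)
  nd <- length(drive_p$setpoint)
  .check(length(decay$tau) == nd,
         "`tau` has %d dimensions but the setpoint has %d",
         length(decay$tau), nd)
  initial_state <- as.numeric(initial_state)
  .check(length(initial_state) == nd && all(is.finite(initial_state)),
         "`initial_state` must be a finite vector of %d dimensions", nd)
  for (a in actions)
    .check(length(a$intake) == nd,
           "action '%s' has a %d-dimensional intake but the state has %d dimensions",
           a$label, length(a$intake), nd)
  zero <- vapply(actions, function(a) all(a$intake == 0), logical(1))
  .check(sum(zero) == 1,
         "exactly one action must have an all-zero intake (the do-nothing action); found %d",
         sum(zero))

  .check(is.numeric(alpha_q) && length(alpha_q) == 1 &&
           alpha_q > 0 && alpha_q <= 1, "`alpha_q` must lie in (0, 1]")
  .check(is.numeric(alpha_khat) && length(alpha_khat) == 1 &&
           alpha_khat > 0 && alpha_khat <= 1, "`alpha_khat` must lie in (0, 1]")
  .check(is.numeric(beta) && length(beta) == 1 && is.finite(beta) && beta >= 0,
         "`beta` must be a single nonnegative number")
  .check(is.numeric(n_trials) && length(n_trials) == 1 && n_trials >= 1 &&
           n_trials == as.integer(n_trials),
         "`n_trials` must be a positive integer")

  if (!is.null(bias)) {
    .check(inherits(bias, "hrl_bias_params"),
           "`bias` must be built with bias_params()")
    .check(bias$biased_action %in% labels,
           "biased action '%s' is not among the action labels (%s)",
           bias$biased_action, paste(labels, collapse = ", "))
  }
  if (!is.null(ambient_stimulus)) {
    ambient_stimulus <- as.numeric(ambient_stimulus)
    .check(length(ambient_stimulus) == nd &&
             all(is.finite(ambient_stimulus)) && all(ambient_stimulus >= 0),
           "`ambient_stimulus` must be a nonnegative vector of %d dimensions", nd)
    .check(reward_mode == "predicted_taste",
           "an ambient oral stimulus requires reward_mode = 'predicted_taste'")
  }
  if (is.null(dim_names)) {
    dim_names <- if (nd == 1) "sodium"
                 else if (nd == 2) c("water", "sodium")
                 else paste0("dim", seq_len(nd))
  }
  .check(length(dim_names) == nd, "`dim_names` must have %d entries", nd)

  structure(list(
    n_dimensions = nd, dim_names = as.character(dim_names),
    actions = actions, action_labels = labels,
    drive = drive_p, decay = decay,
    alpha_q = as.numeric(alpha_q), alpha_khat = as.numeric(alpha_khat),
    beta = as.numeric(beta), reward_mode = reward_mode,
    bias = bias, ambient_stimulus = ambient_stimulus,
    initial_state = initial_state, n_trials = as.integer(n_trials),
    metadata = metadata), class = "hrl_config")
}

#' @export
print.hrl_config <- function(x, ...) {
  cat(sprintf("<hrl_config> %d dimension(s): %s\n",
              x$n_dimensions, paste(x$dim_names, collapse = ", ")))
  cat(sprintf("  setpoint H*: %s   tau: %s   H0: %s\n",
              paste(x$drive$setpoint, collapse = ", "),
              paste(x$decay$tau, collapse = ", "),
              paste(x$initial_state, collapse = ", ")))
  for (a in x$actions)
    cat(sprintf("  action %-16s K = (%s)  Khat0 = (%s)  Q0 = %g\n", a$label,
                paste(a$intake, collapse = ", "),
                paste(a$taste, collapse = ", "), a$q0))
  cat(sprintf("  alpha_q = %g, alpha_khat = %g, beta = %g, reward = %s, %d trials\n",
              x$alpha_q, x$alpha_khat, x$beta, x$reward_mode, x$n_trials))
  if (!is.null(x$bias))
    cat(sprintf("  bias on '%s': lpbn = %g, drd = %g, dreadd %s\n",
                x$bias$biased_action, x$bias$lpbn, x$bias$drd,
                if (x$bias$dreadd_on) "ON" else "off"))
  if (!is.null(x$ambient_stimulus))
    cat(sprintf("  ambient oral stimulus: (%s)\n",
                paste(x$ambient_stimulus, collapse = ", ")))
  invisible(x)
}

#' Derive a per-agent seed from a base seed and a counter
#'
#' Counter-based linear-congruential mixing modulo `2^31 - 1`, giving
#' distinct, platform-stable seeds for the members of a cohort.
#'
#' @param base_seed Integer base seed.
#' @param index Integer counter (vectorised); agents of a cohort use
#'   `0:(n_agents - 1)`.
#' @return Integer seed(s) in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(base_seed, index) {
  m <- 2147483647
  .check(is.numeric(base_seed) && length(base_seed) == 1 && is.finite(base_seed),
         "`base_seed` must be a single integer")
  .check(is.numeric(index) && all(index >= 0) && all(index < m),
         "`index` must be nonnegative and below 2^31 - 1")
  # exact in doubles: (2^31 * 69069) < 2^53
  as.integer(((as.numeric(base_seed) %% m) * 69069 + 12345 + as.numeric(index)) %% m)
}

#' Run one agent for a full episode
#'
#' Executes `n_trials` of the fixed trial cycle: (1) selection-time
#' effective values (bias applied if configured); (2) softmax choice
#' probabilities; (3) action draw; (4) reward-input vector (true intake
#' under `actual_intake`, taste predictor plus ambient stimulus under
#' `predicted_taste`); (5) drive-reduction reward; (6) Rescorla-Wagner
#' update of the taken action's value; (7) taste-predictor update of the
#' taken action; (8) state transition by decay plus the taken action's
#' true intake.  Each trial is recorded after the updates.
#'
#' @param config An [hrl_config()].
#' @param seed Integer seed; the episode is fully deterministic given it.
#' @param agent_id Integer identifier stored with the trajectory.
#' @return An object of class `hrl_trajectory`: a list with `records`
#'   (one data-frame row per trial: `trial` counted from 0, `action`,
#'   `reward`, the post-transition state `H_*`, post-update values `Q_*`,
#'   and the pre-draw choice probabilities `P_*`), the `seed`, the
#'   `agent_id`, the `config` and its `config_digest`.
#' @export
run_agent <- function(config, seed, agent_id = 0L) {
  stopifnot(inherits(config, "hrl_config"))
  .check(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
         "`seed` must be a single integer")
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647), kind = "Mersenne-Twister")

  nA <- length(config$actions)
  nd <- config$n_dimensions
  nt <- config$n_trials
  labels <- config$action_labels
  K <- do.call(rbind, lapply(config$actions, `[[`, "intake"))
  Khat <- do.call(rbind, lapply(config$actions, `[[`, "taste"))
  q <- vapply(config$actions, `[[`, numeric(1), "q0")
  names(q) <- labels
  H <- config$initial_state
  sp <- config$drive$setpoint
  en <- config$drive$exponent_n; em <- config$drive$exponent_m
  keep <- 1 - 1 / config$decay$tau
  ambient <- config$ambient_stimulus
  predicted <- config$reward_mode == "predicted_taste"
  bias <- config$bias
  bias_idx <- if (!is.null(bias)) match(bias$biased_action, labels) else 0L
  bias_term <- if (!is.null(bias))
    -bias$lpbn + (if (bias$dreadd_on) bias$drd else 0) else 0

  act <- integer(nt); rew <- numeric(nt)
  Hrec <- matrix(0, nt, nd); Qrec <- matrix(0, nt, nA); Prec <- matrix(0, nt, nA)

  for (t in seq_len(nt)) {
    v <- q
    if (bias_idx > 0L) v[bias_idx] <- v[bias_idx] + bias_term
    z <- config$beta * v
    e <- exp(z - max(z))
    p <- e / sum(e)
    a <- .sample_index(p)
    kr <- if (predicted) Khat[a, ] else K[a, ]
    if (!is.null(ambient)) kr <- kr + ambient
    r <- .drive(H, sp, en, em) - .drive(keep * H + kr, sp, en, em)
    q[a] <- q[a] + config$alpha_q * (r - q[a])
    Khat[a, ] <- Khat[a, ] + config$alpha_khat * (K[a, ] - Khat[a, ])
    H <- keep * H + K[a, ]
    act[t] <- a; rew[t] <- r
    Hrec[t, ] <- H; Qrec[t, ] <- q; Prec[t, ] <- p
  }

  records <- data.frame(trial = 0:(nt - 1L),
                        action = labels[act],
                        reward = rew,
                        stringsAsFactors = FALSE)
  colnames(Hrec) <- paste0("H_", config$dim_names)
  colnames(Qrec) <- paste0("Q_", labels)
  colnames(Prec) <- paste0("P_", labels)
  records <- cbind(records, as.data.frame(Hrec), as.data.frame(Qrec),
                   as.data.frame(Prec))
  structure(list(agent_id = as.integer(agent_id),
                 seed = as.integer(seed %% 2147483647),
                 config_digest = config_digest(config),
                 records = records,
                 config = config),
            class = "hrl_trajectory")
}

#' @export
print.hrl_trajectory <- function(x, ...) {
  cat(sprintf("<hrl_trajectory> agent %d, seed %d, %d trials, digest %s\n",
              x$agent_id, x$seed, nrow(x$records), x$config_digest))
  print(utils::head(x$records, 5))
  if (nrow(x$records) > 5) cat(sprintf("  ... %d more trials\n", nrow(x$records) - 5))
  invisible(x)
}

#' Run a cohort of independent agents
#'
#' Agent `i` (counted from 0) runs with the seed
#' `derive_seed(base_seed, i)`, so the cohort is reproducible from
#' `base_seed` alone and no two agents share a seed.
#'
#' @param config An [hrl_config()].
#' @param n_agents Number of agents (`>= 1`).
#' @param base_seed Integer base seed for the cohort.
#' @return An object of class `hrl_cohort`: a list with `trajectories`,
#'   the shared `config`, `base_seed` and the derived `seeds`.
#' @export
run_cohort <- function(config, n_agents, base_seed) {
  stopifnot(inherits(config, "hrl_config"))
  .check(is.numeric(n_agents) && length(n_agents) == 1 && n_agents >= 1,
         "`n_agents` must be >= 1")
  n_agents <- as.integer(n_agents)
  seeds <- derive_seed(base_seed, 0:(n_agents - 1L))
  .check(!anyDuplicated(seeds), "derived seeds collide; use a smaller cohort")
  digest <- config_digest(config)
  trajectories <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    tr <- run_agent(config, seeds[i], agent_id = i - 1L)
    tr$config_digest <- digest
    trajectories[[i]] <- tr
  }
  structure(list(trajectories = trajectories, config = config,
                 base_seed = as.integer(base_seed %% 2147483647),
                 seeds = seeds),
            class = "hrl_cohort")
}

#' @export
print.hrl_cohort <- function(x, ...) {
  cat(sprintf("<hrl_cohort> %d agents x %d trials (base seed %d)\n",
              length(x$trajectories), x$config$n_trials, x$base_seed))
  invisible(x)
}

#' @export
summary.hrl_cohort <- function(object, ...) summarize_cohort(object)
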