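# Declarative builders for the shipped simulation experiments, cohort
# summaries, and landmark-timing statistics.  The calibrated parameter
# values live in the YAML files under inst/extdata/configs/, which are the
# single source of truth; the build_* functions load and validate them.

#' Names of the shipped experiments
#'
#' @return Character vector of experiment names accepted by
#'   [build_experiment()] and the `run` CLI subcommand.
#' @export
experiment_names <- function() {
  c("sim1_intake", "sim1_density", "sim2_infusion",
    "sim3_two_bottle", "sim4_dreadd")
}

#' Build a shipped experiment definition
#'
#' Loads the named experiment's configuration file shipped with the
#' package and returns the fully validated definition.
#'
#' @param name One of [experiment_names()].
#' @return An object of class `hrl_experiment` (see [load_config()]).
#' @export
build_experiment <- function(name) {
  .check(is.character(name) && length(name) == 1 && name %in% experiment_names(),
         "unknown experiment '%s'; valid names: %s",
         as.character(name)[1], paste(experiment_names(), collapse = ", "))
  path <- system.file("extdata", "configs", paste0(name, ".yaml"),
                      package = "hrlsim", mustWork = TRUE)
  load_config(path)
}

#' Shipped experiment builders
#'
#' Convenience wrappers around [build_experiment()] for the five shipped
#' experiments:
#' * `build_sim1_intake()` — sodium intake test: one sodium dimension, a
#'   do-nothing and an intake action, sodium-depleted start (`H0 = 0`,
#'   `H* = 50`), reward from actual intake.
#' * `build_sim1_density()` — saltwater density preference: two groups of
#'   sodium-replete agents (`H0 = H*`) differing only in the intake
#'   action's sodium delivery (low vs high density).
#' * `build_sim2_infusion()` — intragastric infusion test: control
#'   (`H0 = 0`), IG infusion (`H0 = H*/2`) and oral-stimulation
#'   (`H0 = 0` plus a constant ambient salty stimulus) groups; taste acts
#'   as the reward predictor.
#' * `build_sim3_two_bottle()` — two-bottle preference test: water and
#'   sodium dimensions, three actions (do nothing, water intake,
#'   saltwater intake), four depletion groups.
#' * `build_sim4_dreadd()` — chemogenetic manipulation: the two-bottle
#'   setting with a tonic LPBN bias against the saltwater action,
#'   water-depleted and sodium-depleted conditions each with and without
#'   DREADD cancellation of the bias.
#' @return An object of class `hrl_experiment`.
#' @name shipped_experiments
NULL

#' @rdname shipped_experiments
#' @export
build_sim1_intake <- function() build_experiment("sim1_intake")

#' @rdname shipped_experiments
#' @export
build_sim1_density <- function() build_experiment("sim1_density")

#' @rdname shipped_experiments
#' @export
build_sim2_infusion <- function() build_experiment("sim2_infusion")

#' @rdname shipped_experiments
#' @export
build_sim3_two_bottle <- function() build_experiment("sim3_two_bottle")

#' @rdname shipped_experiments
#' @export
build_sim4_dreadd <- function() build_experiment("sim4_dreadd")

#' Run every group of an experiment definition
#'
#' Each group runs as an independent cohort; group `g` (counted from 0)
#' uses the base seed `derive_seed(base_seed, 7919 + g)` so groups have
#' disjoint agent seed sets for any practical cohort size.
#'
#' @param definition An `hrl_experiment` definition from
#'   [build_experiment()] or [load_config()].
#' @param n_agents Number of agents per group; defaults to the
#'   definition's value.
#' @param base_seed Base seed; defaults to the definition's value.
#' @return An object of class `hrl_experiment_result`: a list with `name`,
#'   `cohorts` (one [run_cohort()] result per group, named by group
#'   label), `n_agents` and `base_seed`.
#' @export
run_experiment <- function(definition, n_agents = NULL, base_seed = NULL) {
  stopifnot(inherits(definition, "hrl_experiment"))
  if (is.null(n_agents)) n_agents <- definition$n_agents
  if (is.null(base_seed)) base_seed <- definition$base_seed
  cohorts <- vector("list", length(definition$groups))
  names(cohorts) <- names(definition$groups)
  for (g in seq_along(definition$groups)) {
    gseed <- derive_seed(base_seed, 7919 + g - 1)
    cohorts[[g]] <- run_cohort(definition$groups[[g]], n_agents, gseed)
  }
  structure(list(name = definition$name, cohorts = cohorts,
                 n_agents = as.integer(n_agents),
                 base_seed = as.integer(base_seed %% 2147483647)),
            class = "hrl_experiment_result")
}

#' @export
print.hrl_experiment_result <- function(x, ...) {
  cat(sprintf("<hrl_experiment_result> %s: %d group(s) x %d agents (base seed %d)\n",
              x$name, length(x$cohorts), x$n_agents, x$base_seed))
  for (lab in names(x$cohorts)) cat("  -", lab, "\n")
  invisible(x)
}

.as_trajectory_list <- function(x) {
  if (inherits(x, "hrl_cohort")) return(x$trajectories)
  if (inherits(x, "hrl_trajectory")) return(list(x))
  .check(is.list(x) && length(x) >= 1 &&
           all(vapply(x, inherits, logical(1), "hrl_trajectory")),
         "expected an hrl_cohort or a non-empty list of hrl_trajectory objects")
  x
}

#' Per-trial and per-agent summary of a cohort
#'
#' Computes, across agents, the per-trial mean and standard deviation of
#' every recorded variable (internal states, action values, reward, choice
#' probabilities), and the per-agent total count of each action.  The
#' standard deviation treats the cohort as the full population (divisor
#' `n`), matching mean +/- 2 SD band plotting.
#'
#' @param x An `hrl_cohort` or a non-empty list of equal-length
#'   `hrl_trajectory` objects.
#' @return An object of class `hrl_cohort_summary`: `per_trial` (columns
#'   `trial`, then `<var>_mean` and `<var>_sd` per variable), `counts`
#'   (one row per agent, one column per action label), `n_agents`,
#'   `n_trials` and `actions`.
#' @export
summarize_cohort <- function(x) {
  trajectories <- .as_trajectory_list(x)
  nt <- vapply(trajectories, function(tr) nrow(tr$records), integer(1))
  .check(length(unique(nt)) == 1, "trajectories must have equal length")
  nt <- nt[1]
  vars <- setdiff(names(trajectories[[1]]$records), c("trial", "action"))
  n <- length(trajectories)

  per_trial <- data.frame(trial = 0:(nt - 1L))
  for (v in vars) {
    m <- vapply(trajectories, function(tr) tr$records[[v]], numeric(nt))
    if (nt == 1) m <- matrix(m, nrow = 1)
    mu <- rowMeans(m)
    sd_pop <- sqrt(rowMeans((m - mu)^2))
    per_trial[[paste0(v, "_mean")]] <- mu
    per_trial[[paste0(v, "_sd")]] <- sd_pop
  }

  labels <- trajectories[[1]]$config$action_labels
  counts <- vapply(trajectories, function(tr)
    vapply(labels, function(l) sum(tr$records$action == l), numeric(1)),
    numeric(length(labels)))
  counts <- if (length(labels) == 1) matrix(counts, nrow = 1) else counts
  counts <- as.data.frame(t(counts))
  names(counts) <- labels
  counts <- cbind(agent_id = vapply(trajectories, `[[`, integer(1), "agent_id"),
                  counts)
  structure(list(per_trial = per_trial, counts = counts,
                 n_agents = n, n_trials = nt, actions = labels),
            class = "hrl_cohort_summary")
}

#' @export
print.hrl_cohort_summary <- function(x, ...) {
  cat(sprintf("<hrl_cohort_summary> %d agents x %d trials\n",
              x$n_agents, x$n_trials))
  cat("  median total counts per action:\n")
  for (l in x$actions)
    cat(sprintf("    %-18s %g\n", l, stats::median(x$counts[[l]])))
  invisible(x)
}

#' Median total intake counts of a cohort
#'
#' @param x An `hrl_cohort`, list of trajectories, or `hrl_cohort_summary`.
#' @return Named numeric vector: cohort median of each action's total
#'   count over the episode.
#' @export
median_counts <- function(x) {
  s <- if (inherits(x, "hrl_cohort_summary")) x else summarize_cohort(x)
  vapply(s$actions, function(l) stats::median(s$counts[[l]]), numeric(1))
}

#' Landmark trials of a homeostatic episode
#'
#' For each agent of a cohort, locates three behavioural landmarks of the
#' sodium intake test: the first trial on which the intake-choice
#' probability exceeds a threshold, the first trial on which the tracked
#' internal state strictly exceeds its setpoint (the overshoot), and the
#' first trial after the overshoot on which the state falls strictly back
#' below the setpoint.  A landmark that never occurs is `NA`; cohort
#' medians are taken over the agents for which the landmark exists.
#'
#' @param x An `hrl_cohort` or list of `hrl_trajectory` objects.
#' @param probability_threshold Threshold in `(0, 1)` for the
#'   choice-probability landmark.
#' @param intake_action Label of the intake action; defaults to the single
#'   action with a non-zero intake when it is unique.
#' @param dimension Index of the internal-state dimension to track
#'   (default 1).
#' @return An object of class `hrl_landmarks`: `per_agent` (one row per
#'   agent with the three landmark trials, counted from 0) and `median`
#'   (named vector `first_high_prob`, `first_over_setpoint`,
#'   `first_return_below`).
#' @export
landmark_trials <- function(x, probability_threshold = 0.95,
                            intake_action = NULL, dimension = 1L) {
  trajectories <- .as_trajectory_list(x)
  .check(is.numeric(probability_threshold) && length(probability_threshold) == 1 &&
           probability_threshold > 0 && probability_threshold < 1,
         "`probability_threshold` must lie in (0, 1)")
  config <- trajectories[[1]]$config
  if (is.null(intake_action)) {
    nonzero <- config$action_labels[
      !vapply(config$actions, function(a) all(a$intake == 0), logical(1))]
    .check(length(nonzero) == 1,
           "several intake actions present; specify `intake_action` (%s)",
           paste(nonzero, collapse = ", "))
    intake_action <- nonzero
  }
  .check(intake_action %in% config$action_labels,
         "unknown intake action '%s'", intake_action)
  .check(dimension >= 1 && dimension <= config$n_dimensions,
         "`dimension` out of range")
  pcol <- paste0("P_", intake_action)
  hcol <- paste0("H_", config$dim_names[dimension])
  sp <- config$drive$setpoint[dimension]

  first_or_na <- function(idx) if (length(idx)) idx[1] else NA_integer_
  per_agent <- do.call(rbind, lapply(trajectories, function(tr) {
    rec <- tr$records
    t_prob <- first_or_na(rec$trial[rec[[pcol]] > probability_threshold])
    t_over <- first_or_na(rec$trial[rec[[hcol]] > sp])
    t_ret <- if (is.na(t_over)) NA_integer_ else
      first_or_na(rec$trial[rec$trial > t_over & rec[[hcol]] < sp])
    data.frame(agent_id = tr$agent_id, first_high_prob = t_prob,
               first_over_setpoint = t_over, first_return_below = t_ret)
  }))
  med <- vapply(c("first_high_prob", "first_over_setpoint",
                  "first_return_below"),
                function(v) stats::median(per_agent[[v]], na.rm = TRUE),
                numeric(1))
  structure(list(per_agent = per_agent, median = med,
                 probability_threshold = probability_threshold,
                 intake_action = intake_action, dimension = dimension),
            class = "hrl_landmarks")
}

#' @export
print.hrl_landmarks <- function(x, ...) {
  cat(sprintf("<hrl_landmarks> (P(%s) > %g, dimension %d), cohort medians:\n",
              x$intake_action, x$probability_threshold, x$dimension))
  cat(sprintf("  first P > threshold : trial %g\n", x$median["first_high_prob"]))
  cat(sprintf("  first overshoot     : trial %g\n", x$median["first_over_setpoint"]))
  cat(sprintf("  first return below  : trial %g\n", x$median["first_return_below"]))
  invisible(x)
}
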