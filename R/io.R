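# Configuration loading (YAML), result serialization (CSV/JSON), stable
# configuration digests and run manifests.

.required_group_keys <- c("label", "setpoint", "exponent_n", "exponent_m",
                          "tau", "alpha_q", "alpha_khat", "beta",
                          "reward_mode", "initial_state", "n_trials",
                          "actions")

.group_from_list <- function(g, where) {
  .check(is.list(g), "%s: each group must be a mapping", where)
  missing <- setdiff(.required_group_keys, names(g))
  .check(length(missing) == 0, "%s: missing required field(s): %s",
         where, paste(missing, collapse = ", "))
  .check(is.list(g$actions) && length(g$actions) >= 1,
         "%s: `actions` must be a non-empty list", where)
  actions <- lapply(g$actions, function(a) {
    .check(is.list(a) && !is.null(a$label) && !is.null(a$intake),
           "%s: every action needs `label` and `intake`", where)
    hrl_action(label = a$label, intake = unlist(a$intake),
               taste = if (is.null(a$taste)) unlist(a$intake) else unlist(a$taste),
               q0 = if (is.null(a$q0)) 0 else a$q0)
  })
  bias <- if (is.null(g$bias)) NULL else {
    b <- g$bias
    .check(!is.null(b$biased_action), "%s: `bias` needs `biased_action`", where)
    bias_params(lpbn = if (is.null(b$lpbn)) 0 else b$lpbn,
                drd = if (is.null(b$drd)) 0 else b$drd,
                dreadd_on = isTRUE(b$dreadd_on),
                biased_action = b$biased_action)
  }
  hrl_config(actions = actions,
             setpoint = unlist(g$setpoint),
             tau = unlist(g$tau),
             initial_state = unlist(g$initial_state),
             n_trials = g$n_trials,
             alpha_q = g$alpha_q, alpha_khat = g$alpha_khat, beta = g$beta,
             exponent_n = g$exponent_n, exponent_m = g$exponent_m,
             reward_mode = g$reward_mode,
             bias = bias,
             ambient_stimulus = if (is.null(g$ambient_stimulus)) NULL
                                else unlist(g$ambient_stimulus),
             dim_names = if (is.null(g$dim_names)) NULL else unlist(g$dim_names),
             metadata = if (is.null(g$metadata)) list() else g$metadata)
}

#' Load an experiment definition from a YAML configuration file
#'
#' The file must carry `name`, `n_agents`, `base_seed` and a non-empty
#' `groups` list; every group states all model parameters explicitly (no
#' hidden run-time defaults — the shipped files under
#' `system.file("extdata", "configs", package = "hrlsim")` are the single
#' source of truth for the calibrated values).  Every type invariant is
#' checked on load, and a violation raises an error naming the offending
#' field or group.
#'
#' @param path Path to a YAML experiment configuration.
#' @return An object of class `hrl_experiment`: `name`, `n_agents`,
#'   `base_seed`, and `groups` (a named list of [hrl_config()] objects).
#' @export
load_config <- function(path) {
  .check(is.character(path) && length(path) == 1, "`path` must be a file path")
  .check(file.exists(path), "configuration file not found: %s", path)
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) stop(sprintf(
                  "cannot parse configuration '%s': %s",
                  path, conditionMessage(e)), call. = FALSE))
  for (k in c("name", "n_agents", "base_seed", "groups"))
    .check(!is.null(y[[k]]), "configuration '%s': missing top-level `%s`",
           path, k)
  .check(is.list(y$groups) && length(y$groups) >= 1,
         "configuration '%s': `groups` must be a non-empty list", path)
  labels <- vapply(y$groups, function(g)
    if (is.null(g$label)) NA_character_ else as.character(g$label), character(1))
  .check(!anyNA(labels), "configuration '%s': every group needs a `label`", path)
  .check(!anyDuplicated(labels),
         "configuration '%s': group labels must be unique", path)
  groups <- lapply(seq_along(y$groups), function(i)
    .group_from_list(y$groups[[i]],
                     sprintf("%s, group '%s'", y$name, labels[i])))
  names(groups) <- labels
  structure(list(name = as.character(y$name),
                 n_agents = as.integer(y$n_agents),
                 base_seed = as.integer(y$base_seed),
                 groups = groups),
            class = "hrl_experiment")
}

#' @export
print.hrl_experiment <- function(x, ...) {
  cat(sprintf("<hrl_experiment> %s: %d group(s), %d agents, base seed %d\n",
              x$name, length(x$groups), x$n_agents, x$base_seed))
  for (lab in names(x$groups)) cat("  -", lab, "\n")
  invisible(x)
}

.group_to_list <- function(cfg, label) {
  out <- list(
    label = label,
    dim_names = as.list(cfg$dim_names),
    setpoint = as.list(cfg$drive$setpoint),
    exponent_n = cfg$drive$exponent_n,
    exponent_m = cfg$drive$exponent_m,
    tau = as.list(cfg$decay$tau),
    alpha_q = cfg$alpha_q, alpha_khat = cfg$alpha_khat, beta = cfg$beta,
    reward_mode = cfg$reward_mode,
    initial_state = as.list(cfg$initial_state),
    n_trials = cfg$n_trials,
    actions = lapply(cfg$actions, function(a)
      list(label = a$label, intake = as.list(a$intake),
           taste = as.list(a$taste), q0 = a$q0)))
  if (!is.null(cfg$bias))
    out$bias <- list(lpbn = cfg$bias$lpbn, drd = cfg$bias$drd,
                     dreadd_on = cfg$bias$dreadd_on,
                     biased_action = cfg$bias$biased_action)
  if (!is.null(cfg$ambient_stimulus))
    out$ambient_stimulus <- as.list(cfg$ambient_stimulus)
  if (length(cfg$metadata)) out$metadata <- cfg$metadata
  out
}

#' Serialize an experiment definition back to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(x, f))` yields an
#' equal resolved definition.
#'
#' @param definition An `hrl_experiment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(definition, path) {
  stopifnot(inherits(definition, "hrl_experiment"))
  y <- list(name = definition$name,
            n_agents = definition$n_agents,
            base_seed = definition$base_seed,
            groups = lapply(names(definition$groups), function(l)
              .group_to_list(definition$groups[[l]], l)))
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

# ---- stable digest ---------------------------------------------------------

.canonical_chr <- function(x) {
  if (is.null(x)) return("~")
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && any(nzchar(nm))) {
      ord <- order(nm)
      parts <- vapply(ord, function(i)
        paste0(nm[i], "=", .canonical_chr(x[[i]])), character(1))
      return(paste0("{", paste(parts, collapse = ";"), "}"))
    }
    return(paste0("[", paste(vapply(x, .canonical_chr, character(1)),
                             collapse = ";"), "]"))
  }
  if (is.numeric(x)) return(paste(sprintf("%.17g", as.numeric(x)), collapse = ","))
  if (is.logical(x)) return(paste(ifelse(x, "T", "F"), collapse = ","))
  paste(as.character(x), collapse = ",")
}

# 32-bit FNV-1a over the UTF-8 bytes of a string, exact in double arithmetic
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  for (b in bytes) {
    h <- .xor32(h, b)
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor of a 32-bit value (double) with a byte
.xor32 <- function(h, b) {
  low <- h %% 256
  h - low + bitwXor(as.integer(low), as.integer(b))
}

#' Stable digest of a configuration
#'
#' A short hexadecimal digest of the fully resolved configuration,
#' identical across platforms and sessions for identical resolved
#' configurations.  Used to tag trajectories and run manifests.
#'
#' @param x An `hrl_config` or `hrl_experiment`.
#' @return An 8-character hexadecimal string.
#' @export
config_digest <- function(x) {
  if (inherits(x, "hrl_experiment")) {
    y <- list(name = x$name,
              groups = lapply(names(x$groups), function(l)
                .group_to_list(x$groups[[l]], l)))
    return(.fnv1a(.canonical_chr(y)))
  }
  stopifnot(inherits(x, "hrl_config"))
  .fnv1a(.canonical_chr(.group_to_list(x, "config")))
}

# ---- trajectory tables -----------------------------------------------------

.records_table <- function(trajectories, extra = NULL) {
  dfs <- lapply(trajectories, function(tr)
    cbind(agent_id = tr$agent_id, tr$records))
  out <- do.call(rbind, dfs)
  if (!is.null(extra)) out <- cbind(extra, out)
  out
}

.format_table <- function(df) {
  fmt <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col)
    else as.character(col)
  })
  do.call(cbind, fmt)
}

.write_csv17 <- function(df, path) {
  m <- .format_table(df)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = ","), con)
  writeLines(apply(m, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Write trajectories to a long-format CSV table
#'
#' One row per (agent, trial) with columns `agent_id`, `trial`, `action`,
#' `reward`, one `H_<dimension>` column per internal dimension, one
#' `Q_<action>` column per action, and one `P_<action>` choice-probability
#' column per action.  Doubles are written at full precision (`%.17g`), so
#' a read-back reproduces the values bit for bit.
#'
#' @param x An `hrl_cohort` or non-empty list of `hrl_trajectory` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(x, path) {
  trajectories <- .as_trajectory_list(x)
  .write_csv17(.records_table(trajectories), path)
}

#' Read a trajectory CSV written by [write_trajectories()]
#'
#' @param path Path to the CSV file.
#' @return A data frame, one row per (agent, trial).
#' @export
read_trajectories <- function(path) {
  .check(file.exists(path), "trajectory file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a per-trial cohort summary to CSV
#'
#' @param summary An `hrl_cohort_summary` (or something [summarize_cohort()]
#'   accepts).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  if (!inherits(summary, "hrl_cohort_summary"))
    summary <- summarize_cohort(summary)
  .write_csv17(summary$per_trial, path)
}

#' Build a run manifest
#'
#' A small structured record sufficient to reproduce a run exactly: the
#' experiment name, the stable digest of the resolved configuration, the
#' base seed, the cohort size, the tool version and a timestamp.
#'
#' @param definition The `hrl_experiment` that was run.
#' @param n_agents,base_seed The values actually used.
#' @return A list of class `hrl_manifest`.
#' @export
run_manifest <- function(definition, n_agents = definition$n_agents,
                         base_seed = definition$base_seed) {
  stopifnot(inherits(definition, "hrl_experiment"))
  structure(list(
    experiment = definition$name,
    config_digest = config_digest(definition),
    base_seed = as.integer(base_seed),
    n_agents = as.integer(n_agents),
    groups = names(definition$groups),
    tool = "hrlsim",
    tool_version = as.character(utils::packageVersion("hrlsim")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "hrl_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest An `hrl_manifest` from [run_manifest()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "hrl_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
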