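# Shipped experiment builders, cohort summaries and landmark statistics.

test_that("the sodium intake test starts depleted with level values", {
  def <- build_sim1_intake()
  expect_length(def$groups, 1)
  g <- def$groups[[1]]
  expect_identical(g$n_dimensions, 1L)
  expect_identical(g$drive$setpoint, 50)
  expect_identical(g$initial_state, 0)
  expect_identical(g$reward_mode, "actual_intake")
  expect_setequal(g$action_labels, c("do_nothing", "intake"))
  expect_true(all(vapply(g$actions, `[[`, numeric(1), "q0") == 0))
  expect_identical(def$n_agents, 100L)
})

test_that("the density test differs only in the intake delivery, replete start", {
  def <- build_sim1_density()
  expect_length(def$groups, 2)
  lo <- def$groups$low_density; hi <- def$groups$high_density
  k <- function(g) g$actions[[which(g$action_labels == "intake")]]$intake
  expect_lt(k(lo), k(hi))
  expect_identical(lo$initial_state, lo$drive$setpoint)
  # all else identical
  strip <- function(g) { g$actions <- NULL; g }
  expect_identical(strip(lo), strip(hi))
  base <- build_sim1_intake()$groups[[1]]
  expect_identical(lo$drive, base$drive)
  expect_setequal(lo$action_labels, base$action_labels)
})

test_that("the infusion test has control, IG and oral-stimulation groups", {
  def <- build_sim2_infusion()
  expect_identical(names(def$groups),
                   c("control", "ig_infusion", "oral_stimulation"))
  for (g in def$groups) {
    expect_identical(g$reward_mode, "predicted_taste")
    expect_identical(g$n_trials, 100L)
    expect_identical(g$n_dimensions, 1L)
  }
  expect_identical(def$groups$control$initial_state, 0)
  expect_identical(def$groups$ig_infusion$initial_state,
                   def$groups$ig_infusion$drive$setpoint / 2)
  expect_identical(def$groups$oral_stimulation$initial_state, 0)
  expect_false(is.null(def$groups$oral_stimulation$ambient_stimulus))
  expect_gt(def$groups$oral_stimulation$ambient_stimulus, 0)
  expect_null(def$groups$control$ambient_stimulus)
})

test_that("the two-bottle test is two-dimensional with four depletion groups", {
  def <- build_sim3_two_bottle()
  expect_identical(names(def$groups),
                   c("control", "sodium_depleted", "water_depleted",
                     "water_salt_depleted"))
  for (g in def$groups) {
    expect_identical(g$n_dimensions, 2L)
    expect_identical(g$dim_names, c("water", "sodium"))
    expect_setequal(g$action_labels,
                    c("do_nothing", "water_intake", "saltwater_intake"))
    # saltwater relieves water as well as sodium
    salt <- g$actions[[which(g$action_labels == "saltwater_intake")]]$intake
    expect_gt(salt[1], 0); expect_gt(salt[2], 0)
  }
  sp <- def$groups$control$drive$setpoint
  expect_identical(def$groups$control$initial_state, sp)
  expect_identical(def$groups$sodium_depleted$initial_state, c(sp[1], 0))
  expect_identical(def$groups$water_depleted$initial_state, c(0, sp[2]))
  expect_identical(def$groups$water_salt_depleted$initial_state, c(0, 0))
})

test_that("the DREADD test biases saltwater with q0 = lpbn and drd = lpbn", {
  def <- build_sim4_dreadd()
  expect_length(def$groups, 4)
  for (lab in names(def$groups)) {
    g <- def$groups[[lab]]
    expect_identical(g$bias$biased_action, "saltwater_intake")
    expect_identical(g$bias$drd, g$bias$lpbn)
    expect_identical(g$bias$dreadd_on, grepl("dreadd$", lab))
    q0_salt <- g$actions[[which(g$action_labels == "saltwater_intake")]]$q0
    expect_identical(q0_salt, g$bias$lpbn)
  }
  expect_identical(def$groups$water_depleted_control$initial_state[1], 0)
  expect_identical(def$groups$sodium_depleted_control$initial_state[2], 0)
})

test_that("unknown experiment names are rejected with the valid list", {
  expect_error(build_experiment("bogus"), "valid names")
})

test_that("cohort summaries aggregate per trial and count actions per agent", {
  cfg <- sodium_config(n_trials = 25)
  co <- run_cohort(cfg, n_agents = 6, base_seed = 31)
  s <- summarize_cohort(co)
  expect_identical(s$n_agents, 6L)
  expect_identical(nrow(s$per_trial), 25L)
  # counts sum over actions to n_trials for every agent
  expect_true(all(rowSums(s$counts[, s$actions]) == 25))

  # single agent: SD identically zero, mean reproduces the series
  s1 <- summarize_cohort(list(co$trajectories[[1]]))
  sd_cols <- grep("_sd$", names(s1$per_trial), value = TRUE)
  expect_true(all(as.matrix(s1$per_trial[sd_cols]) == 0))
  expect_equal(s1$per_trial$H_sodium_mean, co$trajectories[[1]]$records$H_sodium)

  # an always-intake agent counts n_trials intakes
  greedy <- sodium_config(alpha_q = 1e-12, beta = 1e3, q0_intake = 5,
                          n_trials = 25)
  sg <- summarize_cohort(run_cohort(greedy, 1, 1))
  expect_identical(sg$counts$intake, 25)

  # population (divisor n) standard deviation
  m <- vapply(co$trajectories, function(tr) tr$records$reward, numeric(25))
  expect_equal(s$per_trial$reward_sd, apply(m, 1, function(x)
    sqrt(mean((x - mean(x))^2))))

  expect_error(summarize_cohort(list()), "non-empty")
})

test_that("landmarks locate threshold and setpoint crossings", {
  cfg <- sodium_config(n_trials = 50)
  rec <- run_agent(cfg, 1)$records

  # probability never above threshold: landmark absent
  rec$P_intake <- 0.5
  rec$H_sodium <- 0
  lm <- landmark_trials(list(fake_trajectory(rec, cfg)), 0.95)
  expect_true(is.na(lm$per_agent$first_high_prob))
  expect_true(is.na(lm$per_agent$first_over_setpoint))

  # P = 1 from trial 7; state ramps over the setpoint at trial 30 and
  # falls back below it at trial 44
  rec$P_intake <- ifelse(rec$trial >= 7, 1, 0.5)
  rec$H_sodium <- ifelse(rec$trial >= 44, 40,
                         ifelse(rec$trial >= 30, 55, 1.6 * rec$trial))
  lm <- landmark_trials(list(fake_trajectory(rec, cfg)), 0.95)
  expect_identical(lm$per_agent$first_high_prob, 7L)
  expect_identical(lm$per_agent$first_over_setpoint, 30L)
  expect_identical(lm$per_agent$first_return_below, 44L)
  expect_identical(unname(lm$median),
                   as.numeric(c(7, 30, 44)))

  expect_error(landmark_trials(list(fake_trajectory(rec, cfg)), 1.5),
               "(0, 1)", fixed = TRUE)
})

test_that("landmarks occur in behavioural order on a simulated cohort", {
  def <- build_sim1_intake()
  co <- run_cohort(def$groups[[1]], 20, def$base_seed)
  lm <- landmark_trials(co)
  pa <- lm$per_agent
  complete <- stats::complete.cases(pa)
  expect_gt(sum(complete), 0)
  expect_true(all(pa$first_high_prob[complete] <=
                  pa$first_over_setpoint[complete]))
  expect_true(all(pa$first_over_setpoint[complete] <
                  pa$first_return_below[complete]))
})

test_that("experiment results carry one cohort per group", {
  def <- build_sim1_density()
  res <- run_experiment(def, n_agents = 3, base_seed = 5)
  expect_identical(names(res$cohorts), names(def$groups))
  expect_length(res$cohorts$low_density$trajectories, 3)
  # group cohorts are driven by distinct derived seeds
  expect_false(identical(res$cohorts$low_density$base_seed,
                         res$cohorts$high_density$base_seed))
})
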