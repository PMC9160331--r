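---
title: "Homeostatic reinforcement learning of sodium and water appetite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeostatic reinforcement learning of sodium and water appetite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hrlsim` simulates appetitive behaviour as a reinforcement learning process
operating on a *homeostatic space*.  An agent carries an internal state
$H_t \in \mathbb{R}^N$ (here: water balance and/or sodium level, in abstract
internal-state units) and a drive function measuring the distance from the
ideal point $H^*$:

$$D(H_t) = \Big(\sum_{i=1}^{N} |H^*_i - H^i_t|^{n}\Big)^{1/m}.$$

Reward is *drive reduction*: for the transition produced by one trial,

$$r_t = D(H_t) - D\big((1 - 1/\tau)\,H_t + K_t\big),$$

where $(1 - 1/\tau)$ is the per-trial natural loss of each dimension (applied
on every trial, including do-nothing trials) and $K_t$ is the intake vector
delivered by the chosen action.  Moves toward the setpoint are rewards; moves
past it, or away from it, are punishments.  Action values follow a one-step
Rescorla–Wagner rule on the taken action only,
$Q_{t+1}(a) = Q_t(a) + \alpha_Q (r_t - Q_t(a))$, and actions are drawn from a
softmax with inverse temperature $\beta$.  There is a single external state,
so no temporal-difference bootstrapping across states is involved.

Two refinements turn this skeleton into the full model:

* **Taste as an interoceptive predictor** (`reward_mode = "predicted_taste"`).
  The reward is computed not from the actual intake but from the action's
  learned *taste predictor* $\hat K^a_t$ — the internal-state change the
  action's taste signals — updated by a delta rule
  $\hat K^a_{t+1} = \hat K^a_t + \alpha_{\hat K}(K^a_t - \hat K^a_t)$.  The
  true state transition always uses the actual intake.  An *ambient* oral
  stimulus (a taste present regardless of behaviour) adds to the predicted
  intake term of every action's reward, but never to the state.
* **A tonic selection-time bias**.  A constant `lpbn` is subtracted from the
  saltwater action's value *at selection time only*, modelling tonic
  parabrachial suppression of sodium appetite; chemogenetic silencing adds a
  cancelling `drd`.  Stored values are updated from rewards alone, so when
  `drd = lpbn` the biased agent's trajectory is bit-identical to an unbiased
  one with the same seed — a property the test suite asserts.

## The trial cycle

Each trial executes, in this order: bias-adjusted effective values →
softmax probabilities → action draw → reward-input vector (true intake or
taste predictor + ambient) → drive-reduction reward → Rescorla–Wagner update
of the taken action → taste-predictor update of the taken action → state
transition (decay, then the taken action's true intake).  The ordering is
fixed and tested; recorded per trial are the action, the reward, the
post-transition state, the post-update values and the pre-draw choice
probabilities.

## Parameters, defaults and calibration

The drive exponents are $n = 4$, $m = 3$, the geometry of the original
homeostatic reinforcement learning formulation; they make large deviations
disproportionately costly, which is what ultimately caps overshoot.  The
quantitative parameter set behind the published simulations is not available
in the main text of the source study, so the shipped configurations (the
YAML files under `system.file("extdata", "configs", package = "hrlsim")`,
the single source of truth) were fixed by calibration:

* **Sodium intake test** (`sim1_intake`): $H^* = 50$, $H_0 = 0$, intake
  $K = 1$ per trial, $\tau = 100$ trials, $\alpha_Q = 0.035$,
  $\beta = 1.6$, 200 trials, both initial values 0.  These values were
  calibrated once so that the 100-agent cohort medians of three behavioural
  landmarks match the narrative of the original sodium intake test: the
  intake probability becomes near-certain ($> 0.95$) around trial 20, the
  state first overshoots the setpoint around trial 80, and it first returns
  below it around trial 140.  With the shipped values the cohort medians are
  approximately 20 / 75 / 134, stable to a trial or two across base seeds.
* **Density preference** (`sim1_density`): identical agents starting replete
  ($H_0 = H^*$), with a dilute ($K = 0.4$) versus concentrated ($K = 2$)
  fluid.  A lick of the dilute fluid roughly replaces natural loss, while
  the concentrated fluid overshoots; hence replete agents prefer dilute
  saltwater, with a wide margin.
* **Infusion test** (`sim2_infusion`): 100 trials (the behavioural test
  maps 100 trials to 600 s, i.e. 6 s per trial, recorded as metadata only),
  predicted-taste reward, $\tau = 50$.  The faster loss makes intake of
  $K = 1$ approximately replace losses near the setpoint, so the total
  count is dominated by sustained regulation rather than by the initial
  deficit — which is why a gastric pre-load (start at $H^*/2$) leaves total
  intake essentially unchanged, as in the animal experiment.  The oral
  stimulation group receives an ambient stimulus of 50 units: a *strong*
  salty taste that by itself predicts full relief, so additional intake
  predicts overshoot and both actions end up with similar values — intake
  falls and behaviour becomes highly variable across agents, both features
  of the original observation.
* **Two-bottle test** (`sim3_two_bottle`): two dimensions (water, sodium),
  $\tau = 500$ per dimension, 200 trials; water delivers $(1, 0)$,
  saltwater $(0.5, 1)$ — saltwater carries a positive water component, so
  water-depleted agents find it partially relieving, which is what produces
  their non-negligible saltwater intake.  The slower decay keeps the
  fulfilled control group near its setpoint with little need to drink.
* **DREADD test** (`sim4_dreadd`): the two-bottle setting with
  `lpbn = drd = 1` on the saltwater action and the saltwater action's
  initial value set to `lpbn` (so the control group's effective values
  start level, giving an initial selection probability of $1/2$ between
  saltwater and doing nothing).  The bias magnitude was chosen so that
  cancelling it clearly raises saltwater intake in both depletion
  conditions while leaving water intake in the water-depleted groups within
  ordinary cohort variability (the package's tests bound the shift at 15%
  of control, the same bound used for the infusion comparison).

Taste predictors in the predicted-taste experiments initialise at the true
intake (a pre-learned taste): these simulations model animals that already
know the fluids, and the landmark dynamics then come from value learning,
not taste learning.  $\alpha_{\hat K} = \alpha_Q$ by default; setting it
near zero freezes the predictor, which is supported but not the default.
Only the taken action's predictor is updated.

## What the generator does and does not emulate

Cohorts are sets of independent agents differing only in their random
stream; agent $i$ uses the seed `derive_seed(base_seed, i)`, a counter-based
mix that is platform-stable and collision-free within a cohort, so any run
is reproducible from one integer.  The simulations reproduce *behavioural
patterns* — regulation around a setpoint, preference orderings, intake
counts — under abstract units where one trial is the time step.  They do not
model hormonal physiology, separate taste/gut/blood timescales, circuit
dynamics, or osmotic priority between water and sodium; passing tests
therefore show that the learning architecture suffices for these patterns,
not that its parameters are physiologically measured quantities.

## Numerical choices and degenerate inputs

* The softmax is computed with max-subtraction (exact by translation
  invariance); $\beta = 0$ yields the uniform policy.
* Action draws invert one uniform variate against the cumulative
  distribution, so an episode consumes exactly one draw per trial.
* $\tau \ge 1$ is enforced ($\tau = 1$ empties a dimension in one step;
  smaller values would oscillate in sign and are rejected at validation).
  With $\tau \ge 1$, intakes $\ge 0$ and a nonnegative start, states cannot
  become negative, so states are asserted, never clamped.
* Learning rates are restricted to $(0, 1]$; a value of exactly 0 is
  rejected by validation (pin a value by choosing a rate of `1e-12` and a
  large $\beta$ if a frozen-value agent is needed, as the test suite does).
* Ties in values need no special handling: sampling is from the softmax
  distribution itself.
* Equal-length checks, the unique all-zero do-nothing action, and the
  requirement that an ambient stimulus only appear under predicted-taste
  reward are all enforced at configuration time, so the trial loop itself
  never validates.

## Problem sizes

The shipped experiments use cohorts of 100 agents (the size whose mean ± 2 SD
bands the original figures display) and 100–200 trials, which run in a few
seconds each; the package's test suite and the bundled acceptance script use
those same sizes.

## Known limitations

Within an episode the environment has a single external state, so the model
cannot express context-dependent valuation; preference switches require
relearning over trials rather than the immediate switch that
incentive-salience accounts describe — the tonic selection-time bias is the
only non-learning channel.  Total intake in a fixed-length episode is a
count over a shared trial budget, so strong manipulations of one action
necessarily displace others slightly; comparisons should be read as
orderings, not absolute volumes.
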