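# hrlsim

Homeostatic reinforcement learning (HRL) simulation of sodium and water
appetite.

Animals approach salt when sodium-depleted and avoid it when replete: the
reward value of one and the same taste tracks the internal state.  `hrlsim`
implements the computational account in which this is ordinary reinforcement
learning on a *homeostatic space*: the internal state $H_t$ (water, sodium)
lives in a metric space with ideal point $H^*$ and drive function

$$D(H_t) = \Big(\textstyle\sum_{i=1}^{N} |H^*_i - H^i_t|^{n}\Big)^{1/m},$$

reward is drive reduction across the trial transition
$r_t = D(H_t) - D\big((1-1/\tau)H_t + K_t\big)$ (with $\tau$ the natural-loss
constant and $K_t$ the intake), action values follow the Rescorla–Wagner rule
$Q_{t+1}(a) = Q_t(a) + \alpha_Q (r_t - Q_t(a))$, and choices are drawn from a
softmax with inverse temperature $\beta$.  Taste can act as an interoceptive
*predictor* of internal-state change (the learned $\hat K$ replaces $K$ in
the reward, while the state itself moves only by real intake), and a tonic
parabrachial (LPBN) bias can subtract a constant from the saltwater action at
selection time only, with chemogenetic (DREADD) cancellation adding it back.

The package is for computational neuroscientists and behavioural
physiologists who want seed-reproducible cohort simulations of the classic
sodium-appetite assays: the sodium intake test, saltwater density preference,
the intragastric-infusion / oral-stimulation paradox, the two-bottle
preference test under water/sodium depletion, and chemogenetic silencing of
the tonic sodium-appetite suppression.

## Worked example

```r
library(hrlsim)

def <- build_sim1_intake()   # sodium intake test, shipped calibrated config
def
#> <hrl_experiment> sim1_intake: 1 group(s), 100 agents, base seed 857009
#>   - standard

res <- run_experiment(def)   # 100 agents x 200 trials, fully seeded
landmark_trials(res$cohorts$standard)
#> <hrl_landmarks> (P(intake) > 0.95, dimension 1), cohort medians:
#>   first P > threshold : trial 20.5
#>   first overshoot     : trial 75
#>   first return below  : trial 135

summary(res$cohorts$standard)
#> <hrl_cohort_summary> 100 agents x 200 trials
#>   median total counts per action:
#>     do_nothing         66
#>     intake             134
```

Starting sodium-depleted ($H_0 = 0$, $H^* = 50$) with both action values at
0, the first choice is a coin flip; intake is rewarded, so by about trial 20
the median agent selects intake near-deterministically, the state first
overshoots the setpoint around trial 75, intake turns into punishment, and
the state falls back below the setpoint around trial 135 — after which the
cycle of mild over- and under-shoot settles into regulation around $H^*$.
`plot(res$cohorts$standard)` draws the per-trial mean ± 2 SD panels (state,
values, intake probability, reward).

Custom agents are assembled directly:

```r
cfg <- hrl_config(
  actions = list(hrl_action("do_nothing", c(0, 0)),
                 hrl_action("water_intake", c(1, 0)),
                 hrl_action("saltwater_intake", c(0.5, 1))),
  setpoint = c(50, 50), tau = c(500, 500), initial_state = c(0, 50),
  n_trials = 200, alpha_q = 0.035, beta = 1.6,
  reward_mode = "predicted_taste")
co <- run_cohort(cfg, n_agents = 100, base_seed = 1)
median_counts(co)
```

## Command line

An `hrl` script is installed with the package (`exec/hrl` in the source
tree):

```sh
hrl list
hrl run sim1_intake --agents 100 --seed 42 --out out/
hrl summarize out/trajectories.csv
```

`run` writes `trajectories.csv` (one row per agent and trial, full float
precision), `summary.csv` (per-trial cohort means and SDs) and
`manifest.json` (experiment name, configuration digest, seed, version —
enough to reproduce the run exactly).  Experiment configurations are plain
YAML; the shipped files under
`system.file("extdata", "configs", package = "hrlsim")` are the single
source of truth for the calibrated parameter values and can be copied and
edited, then run with `hrl run name --config my.yaml`.

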