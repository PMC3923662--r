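# signtrackr

Dual-system reinforcement-learning simulation of sign- and goal-tracking in
Pavlovian autoshaping.

## The problem

In autoshaping, a lever (CS) is presented briefly and food (US) is delivered
into a magazine regardless of behaviour. Some rats come to engage the lever
itself (sign-trackers, STs), others the magazine (goal-trackers, GTs), and an
intermediate group oscillates. Only sign-trackers show the classical
reward-prediction-error-like dopamine pattern — a phasic burst that migrates
from the US to the CS over training — and only sign-tracking depends on
dopamine for its acquisition and expression. Classical single-system
reinforcement-learning models of conditioning cannot produce this individual
variation: they value *states*, so the lever and the magazine can never
acquire distinct motivational values in different animals, and a single RPE
stream predicts the same dopamine signature for everyone.

`signtrackr` is for computational/behavioural neuroscientists who want to
simulate, probe, and fit this dual-process account: a **Model-Based planner**
(learns transition and reward functions `T`, `R`; plans
`Q(s,a) = R(s,a) + γ Σ T(s,a,s') max Q(s',·)`; outputs advantages
`A(s,a) = Q(s,a) − max Q(s,·) ≤ 0`) combined with a **Feature-Model-Free
learner** that attaches TD values to *stimuli* rather than states
(`δ = r + γ max_{a'} V(f(s',a')) − V(f(s,a))`, updating only the focused
feature `f(s,a)`). Decision values are the convex combination

    P(s,a) = ω · V(f(s,a)) + (1 − ω) · A(s,a)

passed through a softmax with temperature β. The integration weight ω alone
spans the phenotype spectrum: high ω → sign-tracking, low ω → goal-tracking.
An inter-trial-interval mechanism depresses the magazine value by a fraction
`u` at every episode start, which is what lets the lever outvalue the
magazine for high-ω agents and what sustains the goal-trackers' persistent
US-time RPE. Simulated flupentixol attenuates positive RPEs (learning) and,
under systemic administration, flattens the softmax (expression), leaving the
planner untouched.

The package ships the task as a configurable episodic MDP, the two learners
and four published model variants, all experiment protocols (autoshaping,
conditioned-reinforcement probe, systemic and intra-accumbens flupentixol,
ITI manipulation), an NSGA-II multi-objective fitter with parameter-recovery
diagnostics, synthetic target-curve generators, and a command-line entry
point (`run_cli()`; wrapper script in `inst/cli/`).

## Worked example

Simulate the three default phenotype groups (14 agents each, 8 sessions of
25 trials, all parameters shared except ω = 0.95 / 0.3 / 0.03):

```r
library(signtrackr)
res <- run_autoshaping(default_groups(), schedule_spec(), seed = 1)
subset(res$engagement, block == 4)          # final 50-trial block
#>  group block stimulus probability   sem
#>     ST     4    lever       1.000 0.000
#>     ST     4 magazine       0.000 0.000
#>     IG     4    lever       0.834 0.018
#>     IG     4 magazine       0.089 0.015
#>     GT     4    lever       0.317 0.014
#>     GT     4 magazine       0.421 0.020
```

Sign-trackers end the experiment engaging the lever on every trial,
goal-trackers favour the magazine, intermediates sit between on both
measures. The same run carries the dopamine-analogue RPE curves:

```r
subset(res$rpe, session %in% c(1, 8))
#>  group session event mean_delta
#>     ST       1    CS      0.208
#>     ST       8    CS      0.826
#>     ST       1    US      0.392
#>     ST       8    US      0.043
#>     GT       1    US      0.507
#>     GT       8    US      0.541
#>     ...
```

For sign-trackers the US-time response collapses (0.39 → 0.04) while the
CS-time response grows (0.21 → 0.83) — the classical burst transfer. For
goal-trackers the US-time response persists across all sessions (≈ 0.5)
while a CS response develops alongside it. Downstream probes reuse the same
result object:

```r
probe_conditioned_reinforcement(res)   # P(engage lever | lever vs explore)
fmf_contribution(res)                  # feature-system share of engagement
```

and the pharmacology and prediction protocols are one call each:
`run_systemic_flu()`, `run_local_flu()`, `run_iti_manipulation()`. Fitting:

```r
target <- make_target(agent_config(omega = 0.8), n_agents = 56, seed = 1)
fit <- fit_nsga2(target, param_names = "omega",
                 ga = ga_config(pop_size = 40, generations = 50, reps = 5))
recovery_report(c(omega = 0.8), fit)
```

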