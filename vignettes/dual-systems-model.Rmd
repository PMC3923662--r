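---
title: "A dual-systems account of sign- and goal-tracking: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-systems account of sign- and goal-tracking: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signtrackr)
```

# The phenomenon

In autoshaping, a lever is inserted for a few seconds and then retracted,
after which a food pellet is delivered into a magazine regardless of what the
animal does. Although the contingency is purely Pavlovian, rats develop
vigorous approach responses — but not all toward the same target. Sign-trackers
(STs) come to approach and engage the lever itself; goal-trackers (GTs)
approach the food magazine as soon as the lever appears; an intermediate group
(IGs) oscillates between the two. The phenotypes also differ physiologically:
phasic dopamine in the accumbens core shows the classical reward-prediction-
error (RPE) pattern — a burst that migrates from food delivery (US) to lever
onset (CS) — only in sign-trackers, and dopamine antagonists block the
acquisition and expression of sign-tracking but not of goal-tracking.

`signtrackr` implements a dual-system reinforcement-learning agent that
reproduces this spectrum from a single integration weight, together with the
experiment protocols (autoshaping, conditioned-reinforcement probe, systemic
and intra-accumbens flupentixol, ITI manipulations), four lesioned model
variants, and an NSGA-II fitter with parameter-recovery diagnostics.

# The task

One trial is an episode of a small deterministic MDP (`build_default_mdp()`).
From an empty pre-CS state the agent can only explore; the lever then appears
and the agent chooses among going to the lever (`goL`), going to the magazine
(`goM`) or continuing to explore (`exp`). After one engagement step the lever
retracts and food is delivered; the agent reaches the magazine if it is not
already there, eats (`eat`, reward `r_food`), and the episode ends. The
goal-tracking path needs 4 actions, the sign-tracking and exploration paths 5,
so under discounting the plan-optimal policy is to goal-track.

Each legal state–action pair is mapped by a *feature function* `f(s, a)` to
the stimulus the action is directed at: `Lever`, `Magazine`, `Food`, or
`None` for undirected exploration. During the CS period, approaching or
engaging the magazine focuses the `Magazine`; once food has been delivered,
approaching the magazine is directed at the `Food` it now contains. This last
assignment is load-bearing and deliberate: it anchors the lever's learned
value (see below) to the food value rather than to the magazine value. Had
the US-period approach focused the `Magazine`, the engagement-step error
would anchor `V(Lever)` at `gamma/(2 - gamma)` times the decayed magazine
value — strictly below it for every `gamma < 1` — and no parameter setting
could ever produce sign-tracking, contradicting the behaviour the model
exists to explain. The task is data-driven (plain state/transition/feature
tables, YAML round-trip via `mdp_to_config()`), so alternative topologies and
feature assignments can be loaded from configuration.

# The two learning systems

**Model-Based (MB).** The planner learns a transition function `T(s, a, s')`
and reward function `R(s, a)` by exponential averaging with learning rate
`alpha`, and computes action values by value iteration on the learned model:

    Q(s, a) = R(s, a) + gamma * sum_s' T(s, a, s') * max_a' Q(s', a')

Its output is the (negative) advantage `A(s, a) = Q(s, a) - max_a' Q(s, a')`.
On the true task at `gamma = 0.9`, `Q(S_CS, goM) = 0.81`,
`Q(S_CS, goL) = 0.729`, `A(S_CS, goL) = -0.081`: the planner favours
goal-tracking. Because it learns from observed transitions rather than from a
dopamine-like error signal, this system is insensitive to simulated
flupentixol.

**Feature-Model-Free (FMF).** The second system keeps one value per stimulus,
shared across every state in which the stimulus occurs, and revises only the
focused feature with a temporal-difference error

    delta = r + gamma * max_a' V(f(s', a')) - V(f(s, a)),
    V(f(s, a)) <- V(f(s, a)) + alpha * delta

`V(None)` is pinned at zero: an undirected action neither learns nor
accumulates value, which is what keeps the CS-onset prediction error alive in
trained sign-trackers (the transition into lever appearance is taken from an
unvalued focus). `delta` is the model's dopamine analogue; session means of
`delta` at CS onset and at food delivery are the quantities compared with
voltammetry recordings.

**The inter-trial interval.** The episode graph does not model the ITI.
Its behavioural footprint — unrewarded magazine checks between trials — is
condensed into one multiplicative revision at each episode start:
`V(Magazine) <- (1 - u) * V(Magazine)`, with `u` in [0, 1]. This mechanism is
what differentiates the stimuli: the magazine value is knocked down every
trial and must be re-earned, while the lever value, anchored through the
engagement step to the (ITI-protected) food value, is not. Sign-tracking
becomes possible exactly when the decay depresses the decayed magazine value
below the lever's anchor; goal-trackers are the agents whose planner outweighs
that difference. The same mechanism produces the goal-trackers' persistent
US-time RPE (the magazine value sits below `gamma * V(Food)` at food delivery
in every trial) and the prediction that shortening the ITI (smaller `u`)
shrinks that burst and shifts the population toward goal-tracking
(`run_iti_manipulation()`).

**Integration and selection.** Decision values are the convex combination

    P(s, a) = omega * V(f(s, a)) + (1 - omega) * A(s, a)

and actions are drawn by softmax with temperature `beta`
(`prob(a) proportional to exp(P(s, a) / beta)`). `omega` is the phenotype
dial: the feature bonus dominates at high `omega` (sign-tracking), the
planner at low `omega` (goal-tracking).

**Variants.** `variant = "v1"` replaces the planner by state-level
Q-learning (both systems then RPE-dependent); `"v2"`/`"v3"` are
Pavlovian-impetus architectures where an `omega`-weighted bonus
`max_a' Q(s, a')` attaches to lever-directed (v2) or lever- and
magazine-directed (v3) actions; `"v4"` mixes the Model-Based and Model-Free
*advantages* with no feature values at all. v4 cannot sign-track at any
`omega` — both advantages converge to the same optimum, which favours the
magazine — and that failure is itself one of the package's reproduced
results.

# Pharmacology

Flupentixol, a nonspecific dopamine antagonist, is modelled as two
dose-proportional transforms (`drug_condition()`):

* **RPE attenuation** (learning): positive errors are reduced additively and
  clamped at zero, `delta' = max(0, delta - eta_rpe)`; negative errors pass
  unchanged. Receptor blockade silences the burst channel while the pause
  channel that signals negative errors is still read out. The asymmetry is a
  considered choice with a functional consequence: at equilibrium the lever
  value is maintained by small positive and negative errors that cancel, so a
  symmetric clamp would freeze an acquired sign-tracking response under the
  drug, whereas the asymmetric clamp lets unattenuated negative revisions
  relax it — which is how the dose-dependent loss of sign-tracking expression
  under intra-accumbens infusion arises, through relearning. (A multiplicative
  attenuation was considered and rejected: it only slows learning and can
  never disrupt an acquired response.)
* **Temperature elevation** (expression): `beta' = beta * (1 + eta_temp)`,
  active only under systemic administration; a saturating dose makes all
  actions near-equiprobable and masks whatever has been learned. Local
  (intra-accumbens) administration applies only the RPE transform, on the
  hypothesis that the feature learner, but not action selection, resides in
  the accumbens core.

Only Model-Free-type errors are attenuated (the FMF system always; the
variants' Q-learners too); the Model-Based learner is untouched. Under a
saturating systemic dose the feature values never move from their (zero)
initial state — acquisition of sign-tracking is blocked outright — while
goal-trackers learn their world model under the drug and express it the
moment the drug is removed.

A consequence worth stating plainly: the speed at which expression relaxes
under local blockade is set by the same small equilibrium RPEs that make the
trained sign-tracker's US-time response small. The relaxation time constant
is about `1 / (alpha * (1 - gamma))` lever engagements (~200 trials at the
defaults), which is why `run_local_flu()` defaults to a 16-session test phase
at doses `{0, 0.2, 0.5, 2}`; a short test phase shows nothing, not because
the effect is absent but because relearning is slow by construction.

# Parameters and defaults

All parameters are shared across the two systems and across groups; the
groups differ only in `omega` (this one-parameter account is itself one of
the reproduced results, `run_autoshaping()` on `default_groups()`).

| parameter | default | meaning and rationale |
|---|---|---|
| `omega` | 0.95 / 0.3 / 0.03 | integration weight of ST / IG / GT groups. The phenotype boundary sits near `omega* = |A| / (|A| + V_L - V_M)`, about 0.1 at the defaults; the three values place the groups firmly on either side and astride it. |
| `alpha` | 0.1 | learning rate of all learners (dimensionless per transition). |
| `gamma` | 0.95 | discount per MDP step. Sets both the planner's advantage gap `gamma^2 (1 - gamma)` and the trained sign-tracker's equilibrium US-time RPE `(1 - gamma) V(Lever)`; 0.95 keeps the latter small (the "burst moves to the CS" signature) while leaving the planner enough of a gap to hold goal-trackers. |
| `beta` | 0.1 | softmax temperature, in units of value. Small enough that committed agents are near-deterministic, large enough that early exploration seeds both paths. |
| `u` | 0.12 | per-episode fractional depression of the magazine value (the ITI mechanism). Large enough to hold the magazine value below the lever anchor for high-`omega` agents, small enough that goal-trackers' magazine value keeps some bonus value. |
| `r_food` | 1 | reward magnitude (dimensionless; sets the value scale). |
| `v0_magazine`, `v0_food` | 0, 0 | initial feature values. Zero initialisation makes the full-blockade freeze exact (every error from the zero state is nonnegative, hence blocked) and lets the CS-onset RPE rise from zero over training; the early US-time burst still appears because `V(Food)` is learned within the first session. |
| `r0` | 1 | initial learned reward `R(s, a)` (optimistic). With a pessimistic (zero) start, an agent that happens to exploit early leaves the other branch's model half-learned and locks onto whichever path it sampled first — a lottery that destroys group structure on a third of seeds. Optimism makes every agent's world model converge, so group behaviour is governed by the parameters, not by early luck. |
| `q0` | 0 | initial Model-Free Q (variants only). |
| `k_rpe`, `k_temp` | 0.1, 1 | dose-to-effect coefficients; the dose units are arbitrary, so these only fix the scale (a systemic "dose 100" saturates both transforms). |

Schedules follow the experimental conditions: 8 sessions of 25 trials,
engagement summarised in 50-trial (2-session) blocks, 14 agents per group,
group statistics reported as mean ± s.e.m. across agents. Each agent has its
own random stream derived from (group seed, agent index), so results are
reproducible and independent of execution order.

# What the synthetic-data generator does and does not emulate

`make_target()` turns a known configuration into lever/magazine engagement
curves (optionally with truncated Gaussian noise) and carries its generating
truth, standing in for behavioural group curves that exist only as published
figures; `make_shape_target()` provides simulator-independent logistic
curves for end-to-end fitter smoke tests. The generator emulates trial-level
engagement probabilities under the episodic task abstraction. It does not
emulate response latencies or within-trial timing (the task is discrete and
untimed: CS duration and the 30–150 s ITI schedule enter only through the
`u` mechanism), repeated within-trial lever presses, conditioned orienting,
or session-level nonstationarities such as satiety. Tests that pass against
these targets therefore validate the model's trial-resolution behavioural
claims, not its fit to the microstructure of real response streams.

# Fitting

`fit_nsga2()` fits chosen parameters to target curves by two-objective least
squares (lever and magazine curves are separate objectives) with the elitist
non-dominated-sorting genetic algorithm: binary tournament on (front rank,
crowding distance), simulated binary crossover (rate 0.5, eta 15), polynomial
mutation (rate 0.1, eta 20), elitist environmental selection. The published
budget (population 200, 1000 generations) is the default; tests and the
recovery experiment use a reduced budget (population 40, 50 generations, 5
simulated agents per evaluation).

Because candidate evaluations are stochastic, evaluation streams are common
to all candidates within a generation and re-drawn between generations, with
parents re-evaluated alongside their offspring. With static evaluation seeds
the elitist archive locks onto whichever candidate was flattered by that one
noise realisation (observed as a degenerate front far from the generating
parameters); re-drawing makes survival reflect average fitness while keeping
the whole fit deterministic given its seed. The representative individual is
chosen automatically as the front member minimising the sum of min-max
normalised objectives — a reproducible stand-in for the published practice of
picking it by eye.

Two identifiability caveats, measured with the package's own recovery
experiment (`recovery_report()`): above `omega` of roughly 0.6 the behaviour
saturates (fully committed sign-tracking), so expected engagement curves
change by only a few percent per 0.1 of `omega` and the recovery of a
generating value of 0.8 carries an error of roughly ±0.1–0.15 at the reduced
evaluation budget; and with few simulation repetitions the objective's
variance profile itself shifts the expected-least-squares minimum slightly
toward lower `omega`. Recovery of the phenotype *ordering* (a goal-tracking-
shaped target yields a lower recovered `omega` than a sign-tracking-shaped
one) is robust.

# Numerical choices

* Value iteration runs to a sup-norm tolerance of 1e-13 (capped at 500
  sweeps); on the acyclic task it terminates exactly after a handful of
  sweeps, and is re-run after every model update.
* Ties in max operators break by the fixed action order
  `goL, goM, eng, exp, eat`; with continuous learned values ties are
  measure-zero.
* Degenerate inputs are rejected at construction (bounds on all rates and
  weights; task validation checks the unique initial/terminal states,
  acyclicity, and total feature coverage).
* The compiled inner loop (`engine = "cpp"`) and the pure-R reference loop
  (`engine = "r"`) consume the random stream identically — one uniform per
  action selection — and a test asserts their logs agree step for step at
  fixed seeds; the R implementations of the operations remain the semantic
  definition.
* Problem sizes in the shipped tests: group runs of 14 agents × 200 trials;
  the dose-response protocol 3 groups × 4 doses × 24 sessions; the recovery
  fit 40 × 50 × 5 evaluations against a 56-agent target in 25-trial blocks.

# Known limitations

* With one shared parameter set, the goal-trackers' exploratory lever visits
  give them a sizeable lever value even though they rarely act on it. Two
  quantities inherit a small wrong-signed component from this: the ablation-
  based feature-system contribution of goal-trackers sits a few percent below
  zero (the ablation removes the competing lever bonus along with the
  magazine bonus), and the drug-free test-day difference between drugged and
  saline goal-trackers is near zero rather than clearly below. Both would
  resolve with group-specific ITI parameters, at the price of abandoning the
  single-parameter-set account.
* The group-mean US-time RPE of goal-trackers does not vanish at `u = 0`:
  exploration-path trials deliver food under an unvalued (`None`) focus and
  contribute a large prediction error regardless of `u`. The magazine-path
  component alone does converge to `(1 - gamma) V(Magazine)`.
* Drug effects require relearning; the instant expression changes seen with
  post-training infusions are outside the model (as is receptor-level
  pharmacokinetics).
* One feature is updated per step (the focused one); parallel multi-feature
  updates, eligibility traces and SARSA-style updates are not modelled.
* The softmax forces probability freed by a blocked response onto the
  alternatives, which is why blocking sign-tracking *increases* simulated
  goal-tracking where experiments show invariance; reproducing that artefact
  is intentional.
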