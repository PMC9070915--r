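---
title: "Modeling conflict between model-based and model-free control in the two-step task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling conflict between model-based and model-free control in the two-step task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlddmConflict)
```

## The scientific question

Human decisions in sequential tasks are thought to be driven by two
reinforcement-learning systems: a *model-free* system that caches
stimulus–value associations updated by reward prediction errors, and a
*model-based* system that plans over a learned transition model.  The two
systems usually disagree to some degree.  This package implements an
integrated reinforcement-learning / drift-diffusion analysis of the two-step
task that quantifies that disagreement trial by trial and asks how it shapes
the strength of each system's contribution to the decision and the amount of
caution (boundary separation) the decision maker applies.

Two forms of disagreement are distinguished at the first stage of each trial:

* **value conflict** — the continuous quantity
  $|\Delta Q_{mb} - \Delta Q_{mf}|$, where
  $\Delta Q = Q(s, \text{choice}_1) - Q(s, \text{choice}_2)$ for each system;
* **action conflict** — the binary indicator that
  $\Delta Q_{mb}\,\Delta Q_{mf} < 0$, i.e. the systems prefer different
  actions.  A product of exactly zero counts as *no* action conflict.

Alongside these, each system's *within-system* conflict is its own
$|\Delta Q|$ — how close its two options are.

## The hybrid learner

Learning follows the standard hybrid account of the two-step task.  The
model-free system is SARSA($\lambda$): the chosen first-stage value moves by
$\alpha$ toward the chosen second-stage value, plus an eligibility-weighted
step $\lambda \alpha$ toward the final reward, both reading the second-stage
value at its pre-trial state; the chosen second-stage value moves by
$\alpha$ toward the reward.  Every cached value *not* selected on a trial
decays by $\alpha$ toward the initial value — the decay is applied once per
trial, after the updates, to the unchosen first-stage option(s), the
unchosen option of the visited second-stage state, and both options of the
unvisited state.  The model-based system computes first-stage values by
expectation over the estimated transition model of the best second-stage
value, sharing the second-stage table with the model-free system.

Transition knowledge is variant-specific.  In the original task variant
(single first-stage pair, 0.7/0.3 transitions, binary rewards whose
probabilities follow Gaussian random walks with SD 0.025 reflected at
0.25/0.75), the learner assigns the true probabilities 0.7/0.3 by a majority
count over experienced transitions; on a tie — including the very first
trial — the "opposite" assignment $p(s_2\,|\,a_1) = 0.3$ is used, the
literal reading of the assignment rule.  In the newer variant (two
first-stage pairs, deterministic transitions, integer rewards in $-4..5$
rescaled by $1/9$), a pair's mapping starts at 0.5/0.5 and snaps to its
veridical 0/1 values at the first observed transition of that pair.

Two points the equations leave open are resolved as follows:

* **Initial value in the newer variant.**  Rewards are rescaled by $1/9$ and
  the initial value is the midpoint of the *rescaled* range, $1/18$, so
  initial values and rewards live on one scale.
* **Missed trials.**  A missed first stage leaves all values untouched
  except for decay, which applies to everything; a missed second stage
  (original variant) likewise triggers decay only, since the SARSA target is
  undefined.  The perseveration covariate `rep` is $\pm 1$ only when the
  previous trial of the same first-stage state had an observed choice and no
  missed deadline, and 0 otherwise — so after a miss the decision layer
  starts unbiased.  In the newer variant `rep` refers to the most recent
  trial sharing the same stimulus pair.

## The decision layer

Choices and response times are modeled by a two-boundary Wiener diffusion
with unit diffusion coefficient (the scale convention; drift and boundary
are identified only relative to it).  The upper boundary codes choice 1.
Per trial,

* the *strength* of each system is a regression on conflict:
  $v_{mb} = v_{mb,\text{base}} + v_{mb,cv}\,\text{cv} + v_{mb,ca}\,\text{ca}
  + v_{mb,int}\,\text{cv}\cdot\text{ca}$ (and analogously for the
  model-free system),
* the drift rate is
  $v_1 = v_{mf}\,\Delta Q_{mf} + v_{mb}\,\Delta Q_{mb} + v_{rep}\,rep$,
* boundary separation $a_1$ follows the same conflict regression with its
  own coefficients, and
* the start fraction is $\mathrm{logistic}(s_{rep}\,rep)$, which separates
  start-point from drift perseveration.

The original variant adds a second-stage diffusion with drift
$v_{2,\text{base}}\,\Delta Q_2$, fixed start 0.5, its own boundary, and a
non-decision time $\tau$ shared between stages.  A *within-system* variant
of the model replaces the between-system regressors: each system's strength
is modulated by the *other* system's within-conflict, and the boundary by
both, with no action-conflict terms (those would not be identifiable there).

The likelihood is the standard first-passage-time density of the Wiener
process, evaluated by the small-time/large-time series with the number of
terms chosen from the truncation error bound at tolerance $10^{-7}$.
Numerical and degenerate-input policies: a trial whose regressors drive
$a_1 \le 0$ contributes zero likelihood (the draw is rejected) rather than
being clamped; an observed RT at or below $\tau$ likewise, so the posterior
of $\tau$ respects the fastest observed response.  Trials with an RT under
0.2 s or a missing choice at either stage are excluded from the likelihood
(the exclusion criterion applied at the trial level); the learning sweep
still consumes every trial.

## Fitting procedure

Fitting is hierarchical and proceeds in the two-pass scheme the absolute
value and indicator in the conflict definitions force: they make the full
posterior non-differentiable, so a gradient sampler cannot target it
directly.  Pass one fits the learning model to choices only (softmax link,
inverse temperatures $\beta_{mb}, \beta_{mf}, \beta_{rep}$, and $\beta_2$
for the original variant), with subject-level $\alpha, \lambda$ passed
through a logistic transform.  Per-subject posterior medians of $\alpha,
\lambda$ then fix the Q-trajectories, and pass two fits the decision layer
to choices and RTs.  A *reduced* model closes the loop in a single pass: it
replaces the absolute/indicator conflict terms with squared value
differences (smooth everywhere) and samples $\alpha, \lambda$ jointly with
the decision parameters, Q-values recomputed inside the likelihood.

Priors: group means and SDs are Normal(0, 20) (SDs truncated at zero), with
three exceptions — conflict-related drift coefficients are Normal(0, 200)
because they multiply products of two small value differences; the mean
non-decision time is Normal(0.5, 1) with a Normal(0, 1) SD; base boundary
separations are Normal(1, 20), and boundary, non-decision time and all SDs
are constrained non-negative.  Subject-level parameters are Gaussian around
the group mean.

### The sampler

No gradient-based backend is used; the package ships its own
Metropolis-within-Gibbs engine, in the family of blocked samplers standard
for hierarchical diffusion models.  Each recorded iteration performs
`n_scans` full sweeps of:

1. per-parameter updates across all subjects (their conditionals are
   independent given the group level) — adaptive random-walk proposals
   targeting 0.44 acceptance, mixed with occasional independence proposals
   from the group prior, which traverse likelihood-flat directions (e.g. a
   saturated $\lambda$) in one move;
2. a joint per-subject block update with a Haario-style empirical-covariance
   proposal, which crosses posterior correlations such as boundary with
   non-decision time;
3. group-level updates — conjugate Gibbs for unconstrained means, slice
   sampling for constrained means and all SDs (whose truncated-normal
   normalization breaks conjugacy);
4. an interweaved non-centered move for unconstrained parameters that
   shifts the group mean and rescales the group SD while holding the
   standardized subject deviations fixed, the standard remedy for hierarchy
   funnels.

Convergence is assessed by split-chain $\widehat{R}$ over every sampled
quantity, with the conventional 1.1 threshold.  The paper-faithful
configuration (3 chains of 10,000 iterations, 1,000 warmup; 4,000 for
reduced models) is preserved as the `"paper"` preset; the `"desk"` preset
(3 × 1,500, 500 warmup) and the smaller settings used in the test suite are
sized for a single CPU.  An effect is reported "significant" when its
central 95% credible interval excludes zero, and derived effects (the
value-conflict effect under action conflict, and model-based minus
model-free differences) are summarized from per-draw sums and differences,
never from summed summaries.

## The synthetic-study generator

Because no behavioral data ship with the package, a generator produces
whole studies from known group-level truths: per-subject parameters are
Gaussian draws around the group means (logistic transform for $\alpha,
\lambda$; rejection below zero for boundaries and non-decision time), and
each session is simulated forward — pre-choice values and conflict, a
first-stage response sampled from the trial's diffusion (Euler steps of
$10^{-4}$ s with a Brownian-bridge crossing correction), the variant's
transition, a second-stage response where the variant has one, reward from
the schedule, then the learning updates.  Responses beyond the 2 s deadline
become missed trials organically; an optional independent lapse probability
(default 0) exists to exercise the exclusion filter.  Reward schedules
follow the tasks' design: four reflected Gaussian reward-probability walks
(SD 0.025, bounds 0.25/0.75, uniform initialization within the bounds,
fold-back reflection) in the original variant; integer payoff walks over
$-4..5$ with SD-2 increments rounded to integers in the newer one, whose
walk parameters the source literature does not pin down and which are
therefore configurable.

Default group truths are mid-range values chosen once for realism and then
frozen: $\alpha$ centred at 0.18 and $\lambda$ at 0.97 on the unit scale
(the newer-variant source study fixes $\lambda = 1$ in its canonical
learner, and low learning rates with near-full eligibility are typical of
fits in this paradigm), drift strengths strong enough for markedly
perseverative, sub-second first-stage decisions with only a small fraction
of deadline misses under boundary 1.4 and non-decision time 0.3 s, and all
conflict coefficients zero — the null configuration that calibration runs
require.  Under these defaults a simulated original-variant
study reproduces the task's descriptive structure: roughly a third of trials
show action conflict, fewer in the newer variant than the original, and
pooled between-system value conflict correlates with within-system
model-free conflict at about $\rho \approx 0.9$ — the generative model
caps this correlation near 0.9, since the scale of the model-based value
difference is fixed by the reward walks and the two systems share
second-stage values; empirical datasets reach somewhat higher values, which
evidently reflects behavioral structure beyond the generative model.  What
passing simulation-based tests show is therefore internal consistency of
the pipeline, not fidelity to every feature of human data: the generator
contains no contaminant RT distributions, no attention lapses beyond the
optional miss probability, and no drift of parameters within a session.

## Parameter recovery and calibration

`run_parameter_recovery()` repeats the full pipeline (simulate → exclusions
→ two-pass fit) on replicate studies and tabulates group-level truth against
posterior medians and 95% intervals.  The package's calibration suite uses
20 replicates of a null-conflict study at desk scale (6 subjects × 80
trials, short chains) and checks three properties: interval
coverage of the decision-layer group means, no systematic sign bias in the
recovered conflict drift coefficients, and a conflict-effect
false-significance rate at or below 10%.  With only six subjects the group
SDs are weakly identified and some posterior intervals are wide — coverage
is then conservative, which is the intended behavior of the broad priors.
The problem sizes here and throughout the test suite (reduced fits at 6 × 150,
recovery at 6 × 80) are the package's default desk-scale configuration;
full-scale analyses should use the `"paper"` preset and the empirical sample
sizes.

## Known limitations

* The two-pass procedure conditions pass two on point estimates of
  $\alpha, \lambda$; uncertainty in the learning parameters is not
  propagated (the reduced single-pass model quantifies the cost of that
  approximation).
* The sampler is gradient-free; for the largest models and datasets it
  needs correspondingly more iterations than a NUTS-class sampler would.
* Across-trial variability parameters of the diffusion (drift, start,
  non-decision time) are deliberately excluded from the model family.
* The newer variant's reward-walk details are configurable approximations
  to its source implementation.
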