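---
title: "Models and methods behind twostepr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind twostepr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

twostepr analyses behavior and spiking activity from the rat two-step
task. This vignette is the package's own account of the models it
implements, the choices that were genuinely open, and what its
synthetic-data tests do and do not establish.

## The task environment

Each trial, the rat chooses one of two choice ports. The choice leads
to one of two outcome ports through a fixed stochastic transition:
each choice has a "common" destination reached with probability
`p_common` (default 0.8) and reaches the other port otherwise. Which
destination is common is a per-rat constant (`transition_map`,
counterbalanced across rats). The outcome ports deliver water reward
with probabilities that reverse in blocks: one port rewards at
`p_high` (0.8), the other at `p_low` (0.2). Blocks last at least
`min_block_length` (10) trials; from the trial at which the minimum is
reached, the assignment reverses with probability `block_hazard`
(0.02) per trial. Under these defaults a policy that ignores the task
earns rewards at rate (p_high + p_low)/2 = 0.5, which is also the
baseline `expected_value_baseline` used by the split learning rule.

Two details are under-determined by the constants alone and were fixed
as follows:

- the first block's high port is drawn uniformly at random at each
  session start;
- the hazard is evaluated once per trial starting at the trial where
  the completed-trial count equals the minimum, so the shortest
  possible block is exactly `min_block_length` trials and the excess
  length is geometric with rate `block_hazard`. The acceptance tests
  check both properties on simulation.

## The mixture-of-agents model

Choice probabilities come from a softmax over a weighted sum of agent
values, Q_total(c) = Σ_A β_A Q_A(c). Four agents are implemented:

- **Model-based planning.** Q_plan(c) = Σ_o V(o) P(o|c), where P(o|c)
  is the rat's true transition function and V(o) is a learned outcome
  value. After each trial both outcome values update symmetrically:
  the visited port moves toward the reward, V ← (1 − α) V + α r, and
  the unvisited port moves away, V ← (1 − α) V − α r. Values are *not*
  clipped to [0, 1]: the symmetric rule can and does drive them
  negative (the sum V(left) + V(right) decays geometrically from its
  initial 1 toward 0), and the implementation preserves this.
- **Novelty preference.** After a common transition the chosen port's
  value is 0 and the other's 1; after an uncommon transition, the
  reverse. The weight β_np may be positive (novelty preferring) or
  negative (novelty averse).
- **Perseveration.** An exponential trace of past choices with decay
  rate α_persev.
- **Bias.** Fixed values +1 (left) and −1 (right).

At each session start V is (0.5, 0.5); the novelty and perseveration
values start at (0, 0): their initialization is not pinned down by
the model definition, and zeros make the first trial depend only on
the flat value prior and the bias. Within a
trial, the choice is scored with the pre-trial state and all updates
(novelty, perseveration, values) are applied afterwards, matching the
learn-after-outcome structure of the model. The softmax is computed in
the log domain with max-subtraction; probabilities are exact up to
floating point for |Q_total| ≤ 700.

### The split learning rule

For synthetic inactivation experiments the value update generalizes to

V(o_t) ← α_value V(o_t) + α_reward r_t + (1 − α_value − α_reward) E[V]

(minus α_reward r_t for the unvisited port), with α_value, α_reward ≥ 0
and α_value + α_reward ≤ 1. Setting α_value = 1 − α and α_reward = α
reproduces the compact rule exactly — a property-tested identity.
`translate_params()`, however, deliberately maps a fitted compact-form
α to α_value = α and α_reward = 1 − α: the synthetic inactivation
experiments are defined relative to this translation, which
re-interprets the fitted rate as the value-retention rate, and the
package keeps it even though it is not the algebraic identity. The
`simulate_rat()` impairments then multiply one parameter by 0.3:
α_value or α_reward on the value update of trials with inactivation
scheduled in the outcome or both periods, and β_plan on the choice of
trials *following* any scheduled trial (the choice-period inactivation
extends into the next trial's choice; `impairment_spec()` exposes the
triggering types if a different reading is wanted).

## Fitting

`fit_map()` minimizes the session negative log-likelihood plus the
negative log prior: Normal(0, 0.5) on each weight and Beta(3, 3) on
each learning rate (mode 0.5, so an empty dataset returns β = 0,
α = 0.5). Optimization is quasi-Newton (BFGS) on a transformed space —
identity for weights, logit for rates — with 8 seeded restarts by
default, the first at the prior mode. No change-of-variables Jacobian
is added, so the optimum is the natural-space MAP under box
constraints, merely reached through an unconstrained parameterization.
Convergence is reported (optimizer status plus a per-trial-normalized
gradient bound), never silently assumed. In practice the posterior
surface for the four-agent model is benign — restarts agree to many
digits — which is why the tests and the acceptance script use 3–4
restarts to keep runtimes proportionate.

Weights are standardized by the spread of their agent's values across
trials. Two modes exist because dividing a weight by its value spread
(the convention this analysis tradition reports) is the inverse of the
conventional standardized coefficient (multiplying by the spread):
`standardize_weights()` defaults to `divide` and records the mode in
its output. Tests that
compare weights across datasets use the `multiply` mode, where a
weight's standardized magnitude is its actual leverage on the log-odds
and tolerances like ±0.15 are meaningful. The spread is taken over the
stacked per-port values (2n values for n trials); the bias agent's
values are constants and its weight is never standardized. The
likelihood resets state per session, so fits are invariant to session
order — also property-tested. `crossval_compare()` scores model
variants by summed held-out log-likelihood with leave-one-session-out
folds (sessions are the natural exchangeable unit here; the fold
scheme is configurable in principle by subsetting sessions).

## Trial-history regression and indices

`encode_history_design()` codes each of the T = 3 most recent trials
by outcome type (CR, CO, UR, UO) and side (+1 left, −1 right); exactly
one of the four blocks is nonzero per (trial, lag). Lags that cross a
session boundary are zero-padded rather than dropping early trials,
keeping per-condition trial counts balanced. `fit_history_logistic()`
estimates the weights by penalized Newton iteration with step-halving
under Normal(0, 1) priors by default (`prior_sd = Inf` gives the MLE,
with a complete-separation warning); a weak prior is used because the
unregularized fit is occasionally ill-posed on short datasets. An intercept
capturing side bias is included by default and shares the prior. The
MLE path is verified against `stats::glm()` to 4+ decimals.

`compute_indices()` forms the planning, model-free and stay indices as
linear combinations of the weights. Two forms of the
common-stay/uncommon-switch index circulate, and one of them
duplicates the model-free index algebraically; the package defaults to
the conventional transition-dependence contrast
Σ (β_CR + β_CO) − (β_UR + β_UO) and keeps the reward-symmetric form
behind `csus_form = "alternate"` rather than guessing intent.

`fit_inactivation_history()` estimates one weight set per condition of
the *previous* trial (control, outcome-, choice-, both-period
inactivation) in a single joint MAP problem: control weights have
Normal(0, 1) priors and each condition weight a Normal(β_cntrl, 1)
prior. The joint formulation (rather than a two-stage plug-in) is used
because the control weights genuinely appear in both roles; its
gradient is analytic and a condition with no trials lands exactly on
the control weights, flagged. `planning_contrast()` then computes per
rat the per-condition planning index, its per-lag contributions, and
the relative change versus control, with one-sample, paired and
two-sample t-tests across rats; rats whose control planning index is
within `zero_tol` of zero are flagged because the ratio is unstable.

## Spike encoding and CPD

`align_and_bin()` counts spikes in half-open 200 ms bins around the
four port-entry events; the default window (−0.5 s, 0.5 s) gives the
five bins of the 1 s window used for unit-event statistics. Trials
whose total count deviates from a unit's median by more than 3 scaled
MADs (1.4826 × raw MAD; MAD = 0 flags nothing) are excluded for that
unit.

The encoding design has ten z-scored regressors over adjacent-trial
pairs: the earlier trial's choice, outcome port, reward, their three
interactions (choice × outcome is the transition), the later trial's
choice, the value of the visited outcome port V(o_t) (taken pre-update,
i.e. the value the rat held when visiting), and the later trial's
planning-value difference Q(left) − Q(right) and chosen value. Value
regressors come from `agent_values()` under the rat's fitted
parameters.

`fit_spike_glm()` fits the Poisson model unregularized and along the
L1 path λ = 10⁻¹⁰ … 10⁻¹, returning the weakest penalty whose weights
are identifiable. No single standard criterion defines
identifiability here; the package's rule is: the fit converged, all coefficients
are finite, and the active-set design has condition number below 10⁶.
`compute_cpd()` reports (SSE_reduced − SSE_full) / SSE_reduced with
SSEs pooled before the ratio (over an event's bins, over all bins, or
over units). Two numerical points deserve note:

- SSE is computed on the count scale, (y − μ̂)², matching the
  sum-squared-error definition even though the fit maximizes Poisson
  likelihood. Nesting guarantees monotonicity of the *deviance*, not
  of count-scale SSE, so weak regressors can produce slightly negative
  CPDs; the property tests allow this at the observed magnitude
  (|CPD| of a few 10⁻³ on small fixtures) instead of pretending
  exact nonnegativity.
- The unregularized fits inside the CPD and permutation machinery use
  a package-authored iteratively-reweighted-least-squares solver with
  step-halving (deviance non-increasing per accepted step, linear
  predictor clamped at ±30), written in C++ because the permutation
  loop refits on the order of 10⁵ small GLMs; it is verified against
  `stats::glm()`.

`permutation_inference()` builds surrogate datasets by circularly
shifting each session's trial labels — one uniform draw from
1 … n_session − 1 per session per surrogate, applied identically to
all units — preserving autocorrelation while breaking trial-specific
alignment. p-values are (1 + #{null ≥ observed}) / (n_perm + 1), so
they lie in (0, 1]; `n_perm` defaults to 500 and fewer than 100 earns
a warning. Population timecourses are reported null-mean-subtracted so
they compare fairly to zero. Calibration (≈1% of cells below p = 0.01
under a true null, p-values uniform by a Kolmogorov–Smirnov bound) is
asserted in the acceptance tests.

## The synthetic-data generator

`simulate_cohort()` produces every input the pipeline consumes, with
the statistical structure the analyses assume: block-reversal reward
schedules, 80/20 transitions, behavior from the mixture-of-agents
model, inactivation scheduled independently on 7% of even-numbered
trials per type (even-numbered in the 1-based trial numbering of the
rig software; no trial carries two types), and Poisson spike counts
whose log rate is a baseline plus planted gains times the design
columns. Cohorts default to 9 rats (the size of an optogenetics
cohort) with 100,000 trials per rat, partitioned into 1,000-trial
sessions (the trial total is the protocol's constant; the session
partition is the package's choice). `cohort_params()` draws per-rat
parameters around values typical of well-trained rats — strong
planning (β_plan ≈ 1.5), modest novelty preference of either sign,
clear perseveration, small bias, moderate learning rates — chosen once
as the package's study conditions. Schedules are drawn fresh per
simulation from the seeded stream; each trial consumes a fixed number
of random draws, so cohorts sharing a seed are trial-by-trial
comparable across impairment variants and a multiplier-1 "impairment"
reproduces the control cohort byte for byte (both are tested).

What passing tests on these data establish — and what they do not: the
generator emulates exactly the structure the analyses assume
(stationary parameters, exchangeable sessions, Poisson noise,
log-linear planted coding). Real rats have session-to-session drift,
satiety, violation trials, port-entry latencies, and spike-sorting
artifacts beyond the single burst type the MAD rule targets; real
inactivation has variable duration and physiological spillover. Tests
passing here show the estimators are correct and calibrated under the
model's assumptions, not that the assumptions hold for any particular
recorded dataset; the package makes no claims about quantities
computed on real recordings.

## Problem sizes and seeds

The test suite and `scripts/acceptance.R` run the full analyses at
sizes chosen to make every check sharp but proportionate: 10⁵-trial
simulations for generator statistics, 8–10 simulated rats × 20,000
trials for parameter recovery (standardized-weight errors bounded at
0.15 and Spearman ρ ≥ 0.9 for β_plan), 9 rats × 20,000 trials × four
cohort variants for the inactivation dissociation, and spike fixtures
of 6–12 units with 150–200 permutations for CPD calibration and
planted-coding detection. Statistical bounds in tests are set at ≥ 4
standard errors of the quantity under test wherever feasible (e.g. the
null history-weight bound of 0.05 is checked at 3 × 10⁵ trials because
the uncommon-transition predictors are nonzero on only ~20% of trials
and their standard errors shrink accordingly). All randomness flows
through seeds fixed in the tests or derived from the acceptance
script's `--seed`.

## Known limitations

- Only the four standard agents are implemented; alternative agents
  (model-free TD, win-stay/lose-switch, …) can be emulated only by
  zeroing weights, not added, though the fitting layer accepts agent
  subsets.
- No hierarchical pooling across rats: each rat is fitted
  independently and across-rat inference is by t-tests on per-rat
  summaries, as in the source analyses.
- `fit_spike_glm()`'s λ selection reports per-unit-bin choices; the
  CPD machinery itself runs unregularized, which is the selected model
  whenever the design is well-conditioned (always true of the z-scored
  synthetic designs).
- Trial timing, reaction times and violation trials are out of scope;
  the spike generator plants coding directly in binned counts rather
  than in continuous spike trains.
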