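---
title: "Modeling prosocial reinforcement learning: assumptions, defaults, and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling prosocial reinforcement learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosolearn)
```

This vignette documents the modeling choices behind `prosolearn`: the task
generative model, the learning model and its estimation, what the synthetic
cohort does and does not emulate, and the numerical decisions a user should
know before trusting (or extending) the pipeline.

## The task generative model

The simulated task is a two-armed probabilistic learning game played under
three beneficiary conditions (`self`, `other`, `no_one`). The default
`task_config()` encodes the design this package targets: 3 runs × 3
conditions × one 16-trial block × 48 trials per condition (144 total), a
75/25 reward contingency, outcomes of ±1 point, and a €0.25/point payout
clamped to [€1, €12].

Three design points are underdetermined by the published description of such
tasks and were fixed here once:

* **Reinforcement schedule.** Outcomes are i.i.d. Bernoulli(0.75) draws per
  trial, not an exact 12-of-16 per-block ratio. This is the simplest process
  consistent with stating probabilities alone; an exact-ratio schedule would
  reduce outcome variance slightly and make late-block outcomes predictable
  from early ones.
* **Condition order.** Orders are counterbalanced by a seeded cyclic Latin
  square: one random permutation of the three conditions per session, rotated
  by one position per run, so each condition occupies each serial position
  exactly once across the three runs.
* **Timing.** Onsets use the task's jittered fixation (uniform 1–2 s before
  the outcome) and inter-trial interval (uniform 1–8 s). Timing exists only
  so that exported event files are realistic; no model component reads it.

Missed ("too late") trials are generated only through an explicit per-agent
miss probability (default 0), carry no choice, outcome, or value update, and
are excluded from every analysis denominator.

## The learning model

Each block presents a fresh stimulus pair, so values are reset to `q0` at
each block boundary and never transfer across blocks or conditions. Within a
block the chosen option's value follows the Rescorla-Wagner delta rule
\(Q_{t+1} = Q_t + \alpha (R_t - Q_t)\); the unchosen option is never updated
(no fictive learning). Choices follow a softmax with inverse temperature
\(\beta\), computed with max-shifting so extreme \(|\beta Q|\) cannot
overflow.

Fixed conventions:

* **Initial value** `q0 = 0`, the symmetric midpoint of the ±1 outcome
  range. Any value in [−1, 1] keeps all Q-values inside [−1, 1] forever
  (each update is a convex combination of the current value and an outcome).
* **Two-rate gating** is by outcome valence (reward value → `alpha_gain`,
  punishment value → `alpha_loss`), not by prediction-error sign. With
  outcomes ±1 and values strictly inside (−1, 1) the two conventions
  coincide; fixing one removes the boundary ambiguity at \(|Q| = 1\).
* **Parameter support.** Learning rates live strictly inside (0, 1); β may
  be any finite real, including negative (value-averse choice) and zero
  (value-blind, uniformly random choice).

## MAP estimation

Fits are per agent × condition, independently (three optimizations per
agent), by maximizing likelihood × prior:

* Priors: Beta(1.2, 1.2) on each learning rate, Normal(mean 0, **sd** 10)
  on β. The Gaussian's second parameter is interpreted as a standard
  deviation — a weakly informative scale over the β range where softmax
  behavior actually varies; reading it as a variance (sd ≈ 3.2) would
  change fits only for extreme agents.
* Optimization: bounded L-BFGS-B in the natural parameter space, box
  (1e-6, 1−1e-6) on rates and (−100, 100) on β, from 10 seeded multi-starts
  (rates drawn from the prior, β from a dispersed grid spanning ±15). Priors
  are evaluated in natural space, so no Jacobian terms arise. The likelihood
  inner loop is compiled (Rcpp); a pure-R replay (`replay_trajectory()`)
  implements the identical recursion and the test suite holds the two to
  1e-10 agreement, so the compiled path never goes unchecked.
* **BIC convention:** `−2·loglik + k·ln(n)` with the log-likelihood
  evaluated at the MAP point and `n` the count of non-missed trials in that
  condition. Using the MAP-point likelihood (rather than a separate MLE)
  treats the prior purely as an estimation regularizer, which is the role it
  plays here; `k` is 2 or 3 for the one- and two-rate variants. Ties in
  model preference go to the simpler model.
* **Degenerate input:** an empty (all-missed) condition yields a prior-only
  fit — the prior modes α = 0.5, β = 0 — with a warning and `bic = NA`.

The test suite checks the optimizer against an exhaustive 101 × 201 (α, β)
grid search. Two properties are asserted: the continuous optimum must never
fall below the exhaustive grid maximum (this catches any local-optimum
regression outright), and its location must agree with the grid argmax to
within one grid step except where the posterior ridge is flat enough that
the continuous optimum strictly dominates every grid cell — on a correlated
α–β ridge the discrete argmax can legitimately sit more than one cell from
the continuous maximum, so location agreement alone would be an unreliable
oracle there.

## The synthetic cohort

`cohort_spec()` defines a generative model for a 74-agent cohort spanning
ages 9.03–21.77 years (uniform), built so that every downstream stage —
fitting, comparison, recovery, behavioral statistics — can be exercised with
known ground truth:

* Learning rates: `plogis(intercept + slope · z_age + noise)` per condition,
  with defaults `qlogis(0.30)/qlogis(0.42)/qlogis(0.40)` intercepts
  (self lowest) and `−0.35/−0.70/−0.10` slopes per SD of age (other
  steepest, no-one near flat), logit noise sd 0.5.
* Inverse temperature: one β per agent shared across conditions,
  `3.0 + 0.8 · z_age + N(0, 0.6)` — positive, so all conditions are learned
  above chance, and increasing with age (choices become more value-guided).
* Empathy: a 0–4 Likert-mean-scale score, marginally Normal(2.2, 0.6)
  clipped to the scale, correlated with age at a target of 0.309 through a
  Gaussian copula. The age-orthogonal empathy component additionally lowers
  the other-condition learning rate (−0.25 logit units per SD; set
  `empathy_alpha_slope = 0` to remove the link), giving the partial-Spearman
  analysis a known ground-truth structure to detect.

These effect sizes are free parameters of the generator, chosen once to
reproduce the qualitative effect structure — direction and ordering of the
age slopes, above-chance learning everywhere, the empathy links — rather
than any particular regression coefficient: published mixed-model
coefficients on scaled metrics do not pin down a generative model, so no
attempt is made to match them numerically.

What the generator does **not** emulate: the real age distribution (the
cohort is uniform in age), miss behavior (default none), within-agent β
differences across conditions, sex or IQ structure, quadratic age effects,
perseveration/choice-kernel strategies, and any nonstationarity in
attention. Passing tests therefore show that the pipeline recovers the
effects this generator plants at realistic noise levels — not that real
adolescent data contain those effects.

## Behavioral statistics

The package implements only the statistics this pipeline defines
operationally:

* Learning curves: mean correct-choice indicator per trial position,
  averaged across blocks within agents, then across agents (SEM over
  agents). "Correct" means choosing the high-contingency stimulus,
  regardless of the realized outcome.
* Above-chance tests: one-sample t against 0.5 on per-agent fractions;
  zero-variance input is flagged (t = 0 or ±∞) rather than raised.
* Partial Spearman correlations: all variables rank-transformed, partial
  correlation from the inverse of the rank correlation matrix, p by the t
  approximation with df = n − 2 − #covariates. A covariate that (nearly)
  perfectly explains x or y is a degenerate limit, returned as ρ = 0 with a
  flag. The test suite pins this implementation to an independent
  lm-residualization oracle at 1e-10.
* Age trends: Pearson and Spearman correlation screening. Mixed-model
  analyses (logistic GLMMs, robust LMMs) are deliberately out of scope: they
  are routine computations for `lme4`-family tools, and the package's job is
  to hand them tidy per-trial and per-agent tables.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed; batched simulations derive
per-agent sub-seeds with `derive_seed()` (an affine hash mod 2³¹−1) so any
agent's data can be regenerated in isolation. The test suite runs at the
study's own scale where that is what is being claimed (74-agent cohorts, 48
trials per condition; 20 replicate cohorts for the effect-structure checks;
200 sessions for chance-level checks) and at reduced scale for pure
plumbing checks; large-sample consistency uses 1,600–4,800 trials per
condition. These sizes are the package's definition of "desk-scale"
evidence: large enough for the asserted signs and orderings to be stable
across seeds, small enough to re-run routinely.

## Known limitations

* The MAP fitter estimates each condition independently; shared-β or
  hierarchical (empirical-Bayes) pooling across agents would stabilize
  small-n fits but is intentionally not implemented.
* With β near 0 the likelihood is flat in α — learning rates are then
  unrecoverable, and the recovery report will (correctly) show
  correlations indistinguishable from zero. This is a property of the
  model class, not of the optimizer; the test suite documents it rather
  than hiding it.
* BIC with small n (48 trials) favors the one-rate model unless the
  gain/loss asymmetry is large; the model-selection tests show the richer
  model is only reliably identified at much larger trial counts.
* Events are exported raw; orthogonalization and HRF convolution belong to
  the downstream neuroimaging software (an optional per-run mean-centering
  flag is provided).
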