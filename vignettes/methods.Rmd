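---
title: "Models and methods in twostepfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in twostepfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepfit)
```

## The scientific problem

Sequential decision making draws on two dissociable controllers: a
*model-free* (habitual) system that caches action values updated by reward
prediction errors, and a *model-based* (goal-directed) system that evaluates
actions prospectively through a transition model of the environment. The
two-step task separates them behaviourally: a stage-1 choice leads, via a
fixed probabilistic transition (one state "common", the other "rare"), to
one of two stage-2 states, where a second choice yields reward with slowly
drifting probabilities. How a subject's stage-1 choices react to the
conjunction of the previous reward and the previous transition type
identifies the controller: a purely habitual learner repeats rewarded
actions regardless of how the reward arose; a goal-directed learner repeats
a rewarded action only when the reward came through the action's common
state.

`twostepfit` implements the full analysis stack around this paradigm for
three-condition within-subject neurostimulation designs: the task
environment, the hybrid learning model and its per-subject likelihood
fitting, a delayed-estimation working-memory precision analysis, the
statistical battery, and a synthetic-cohort generator with sealed ground
truth so that every stage can be validated against known truth.

## Task environment

The environment follows the standard design: two stage-1 actions, two
stage-2 states, a fixed transition matrix with common-transition
probability 0.7 (the task's printed material does not state the value; 0.7
is the convention of the task family and is configurable), and four
independent reward probabilities following Gaussian random walks (step SD
0.025) reflected into [0.25, 0.75]. Reflection rather than clamping keeps
the stationary distribution off the boundaries. Sessions have 67 trials;
inter-trial intervals are uniform on [0, 3.6] s (mean 1.8 s). Three walk
sets are pre-generated from fixed sub-seeds of the master seed, and each
subject is assigned one, mirroring the practice of randomizing reward
trajectories across participants.

## The hybrid learning model

Seven parameters: stage-wise softmax reliabilities $\beta_1, \beta_2 \ge
0$, learning rates $\alpha_1, \alpha_2 \in [0,1]$, eligibility $\lambda \in
[0,1]$, an unbounded perseveration rate $p$, and the model-based weighting
$w \in [0,1]$, the quantity of primary scientific interest.

Stage-2 values update by a SARSA rule,
$Q_2(s,a) \mathrel{+}= \alpha_2\,\delta_2$ with
$\delta_2 = r - Q_2(s,a)$. The stage-1 model-free value of the chosen
action updates toward the visited stage-2 value,
$Q_{MF}(a) \mathrel{+}= \alpha_1 (Q_2(s, a_2) - Q_{MF}(a))$, and
additionally receives the eligibility-weighted reward prediction error
$\alpha_1 \lambda\, \delta_2$. Model-based stage-1 values are computed
(not stored) from the true transition matrix,
$Q_{MB}(a) = \sum_s P(s \mid a) \max_{a'} Q_2(s, a')$. Stage-1 choice
follows a softmax over
$\beta_1\,[w\,Q_{MB} + (1-w)\,Q_{MF}] + p\,\mathrm{rep}(a)$, where
$\mathrm{rep}(a)$ marks the previous *valid* stage-1 choice; stage-2 choice
follows a softmax over $\beta_2 Q_2(s, \cdot)$.

Numerical choices: Q values initialize at 0 (0.5 available via
`q_init`); choice probabilities are floored at $10^{-12}$ before taking
logs so the optimizer's objective stays finite; missed (invalid) trials
contribute no likelihood and trigger no update. The likelihood recursion
runs in a small C++ kernel for speed, with a pure-R reference
implementation kept in the package and cross-checked in the test suite.

## Per-subject maximum likelihood

Fitting maximizes the session log-likelihood by BFGS in an unconstrained
reparameterization (log for the betas, logit for the unit-interval
parameters, identity for perseveration; boundary values clipped inward by
$10^{-6}$), from `n_restarts = 10` random starts drawn uniformly in a
box of half-width 2.5 in unconstrained space, with relative objective
tolerance $10^{-6}$. The best restart is returned with the data
log-likelihood at the optimum. This is plain MLE; a ridge-like MAP option
(`fit_settings(prior_sd = )`, an independent normal prior on each
unconstrained parameter) is available but off by default, since the study
design this package emulates reports no priors.

Parameter recovery is the package's accuracy yardstick: simulate agents
with known parameters, refit, correlate. At 500-trial sessions with
$\beta = 5$ the true-versus-fitted correlation for $w$ is high (the
acceptance suite requires $r \ge 0.7$ and typically observes far more). At
the study's own 67-trial sessions recovery is markedly weaker — see
*Known limitations*.

## Working-memory precision

Reports of line orientations live on a period-$\pi$ circle. Errors are
computed as the wrapped difference mapped to $(-\pi/2, \pi/2]$ (the exact
half-period boundary maps to $+\pi/2$ by convention). Dispersion uses the
circular estimator: errors are doubled onto the full circle, the resultant
length $R$ of $e^{2i\epsilon}$ is computed, and
$\mathrm{SD} = \sqrt{-2 \ln R}\,/\,2$. Recall precision is $1/\mathrm{SD}$
(rad$^{-1}$), log-transformed before parametric analysis. A degenerate
$\mathrm{SD} = 0$ yields a missing precision rather than an infinity; a
zero resultant (uniform errors) yields the documented maximum SD with a
flag. Chance correction — subtracting the precision expected from uniform
responding, estimated by permuting responses across trials — is provided
but off by default: the headline definition of the outcome is the plain
reciprocal SD, and the flag is recorded in all outputs so either variant
is reproducible.

The synthetic generator produces response noise as von Mises on the
doubled circle (Best–Fisher rejection sampling), with concentration
$\kappa = 8$ at set size 3 and $\kappa = 2$ at set size 6. These values
give mean precisions near 5.5 and 2.4 rad$^{-1}$ — a load effect of the
magnitude delayed-estimation studies report — and a subject-level
log-normal factor (SD 0.3) on $\kappa$ carries realistic between-subject
reliability. Guess and swap contamination are deliberately omitted, so
passing tests say nothing about mixture-model behaviour on real data.

## Statistical battery

* **Normality**: Lilliefors-corrected Kolmogorov–Smirnov
  (`nortest::lillie.test` behind `ks_normality()`).
* **RM-ANOVA** (`rm_anova()`): univariate `aov` with
  `Error(subject/within)` strata; the condition-order covariate (the day a
  subject received control stimulation) enters as a 3-level
  between-subjects factor.
* **Planned contrasts** (`paired_contrast()`): paired t with df $n-1$,
  reporting *both* effect-size conventions — $r_t = \sqrt{t^2/(t^2+df)}$
  and $r_Z = |Z|/\sqrt{2n}$ from the matching signed-rank test — because
  published reports use either without always saying which; neither is
  asserted as canonical. The two active-vs-control contrasts carry a
  Bonferroni-corrected alpha of .025 in pipeline reports.
* **Wilcoxon signed-rank** (`wilcoxon_signed_rank()`): zeros dropped,
  mid-ranks for ties; exact two-tailed p by full $2^n$ sign enumeration
  (dynamic programming over doubled mid-ranks) for $n \le 20$, otherwise a
  tie-corrected normal approximation with continuity correction.
* **Rank ANCOVA** (`rank_ancova()`): the outcome is rank-transformed
  across all observations and the same covariate-adjusted repeated-measures
  model is applied to the ranks. The df follow the within-subject error
  stratum of the rank model; published rank-ANCOVA df conventions vary and
  pooled-observation variants proved badly miscalibrated under subject
  heterogeneity in our null simulations, so the within-subject variant is
  the one implemented.
* **Reliability**: ICC(3,k) — two-way mixed, consistency, average
  measures — from the subjects-by-sessions ANOVA decomposition, with its F
  test. Under the null the estimator is mildly negatively biased
  ($E[1 - 1/F]$), which the tests acknowledge.
* **Bayesian correlation** (`bayes_cor_logbf()`): log BF$_{10}$ by
  numerical integration of Jeffreys' approximate sampling density of $r$
  under a stretched-beta width-1 (uniform) prior on $\rho$.
* **Power** (`paired_ttest_power()`, `solve_n()`): exact noncentral-t
  power for the two-tailed paired t-test; `solve_n(0.7, 0.95, 0.05)`
  returns 29, the design's sample size.
* **Behavioural signatures** (`stay_probability_table()`): stay
  probabilities by previous reward and transition, plus a logistic
  regression on effect-coded predictors (+1 rewarded/−1 not; +1 common/−1
  rare), so a positive interaction is the model-based signature.
  Separation is flagged and coefficients withheld rather than reported at
  absurd magnitudes.
* **RT slowing** (`rt_by_transition()`): per-subject mean stage-2 RT by
  transition type; rare-minus-common slowing tested across subjects.

## Synthetic cohorts

`cohort_config()` defines the generative study: 29 subjects, three
stimulation conditions (`control`, `LPFC_to_IPS`, `IPS_to_LPFC`) with
order counterbalanced over all six permutations, one 67-trial two-step
session and one 150-trial (75/75 by load) working-memory session per
condition. Baseline parameters per subject: $\beta \sim$ Gamma(6, 1.5)
(mean 4), $\alpha \sim$ Beta(3, 3), $\lambda \sim$ Beta(3, 2),
perseveration $\sim N(0.1, 0.3)$, and control-condition
$w \sim$ Beta(1.3, 2.5) — a right-skewed distribution (skewness $\approx$
0.9) chosen because the emulated study found strongly positively skewed
goal-directedness under control stimulation. The stimulation effect is
modelled as the simplest mechanism consistent with a condition shift: an
additive change of the true $w$ in one condition (default +0.15 for
IPS→LPFC, 0 elsewhere), clipped to $[0,1]$. Stage-2 RTs are
`base + rare_slowing * (1 + gain * w)` on rare transitions plus Gaussian
noise, so RT slowing scales with goal-directedness; 2% of trials are
marked missed uniformly at random. Questionnaire totals are opaque draws
(no item model). All of this is configurable and every dataset carries a
sealed ground-truth table.

What the generator does *not* emulate: trial-by-trial mechanisms of the
stimulation effect, condition-dependent missingness, guess/swap errors in
working memory, session-order learning effects. Passing tests therefore
validate the pipeline's statistical machinery and its sensitivity under
this generative model, not those aspects of real data.

## Pipeline

`run_pipeline()` chains simulate → fit → analyse, writing every
intermediate CSV and a JSON report; the run is a pure function of
(inputs, configuration, seed), with per-stage and per-session sub-seeds
derived deterministically from the master seed. `validate_inputs()`
checks schemas, the fixed condition label set, orientation ranges, and
design balance, distinguishing warnings from fatal errors. A thin
command-line wrapper (`inst/cli/twostepfit.R`) exposes the same stages as
shell subcommands; the R functions are the canonical interface.

## Problem sizes used by the test and acceptance suites

Simulation-backed checks in this package use deliberately chosen sizes:
likelihood-mass conservation enumerates all choice sequences of 1–2-trial
sessions for 100 random parameter vectors; recovery uses 40 agents at
500 trials (and reports, without thresholding, the same design at 67
trials); behavioural signatures use 50 replicate 150-trial sessions per
agent type; type-I calibration uses 2000 replicate null outcome tables
drawn directly from the generator's ground-truth distributions (subject
effect from the control-w Beta plus N(0, 0.15) within-subject noise) —
calibrating the tests themselves without refitting 2000 cohorts; the
end-to-end study runs 100 replicate simulate–fit–test pipelines per
condition in the test suite (60 in the acceptance script) with 4 optimizer
restarts per fit.

## Known limitations

* **Short-session identifiability.** A single 67-trial session identifies
  $w$ only weakly once realistic between-subject variation in $\beta$,
  $\alpha$, $\lambda$ and perseveration is allowed: in our simulations
  the true-versus-fitted correlation for $w$ falls from ~0.9 (500 trials,
  $\beta = 5$) to ~0.5 (67 trials, $\beta = 5$) to ~0.1–0.3 at the full
  cohort's parameter heterogeneity. Consequently a +0.2 shift of true $w$
  in one condition yields a paired effect of only $d_z \approx 0.25$ on
  *fitted* $w$ and roughly one-third power at $n = 29$ — the end-to-end
  sensitivity one might hope for from the design is not there under this
  generative model, and the package reports this honestly rather than
  tuning the generator to mask it. The scientific reading: single-session
  point estimates of $w$ from 67 trials carry large measurement error, and
  detection of moderate shifts at $n = 29$ is not guaranteed; weak-prior
  MAP fitting (provided) does not materially change this.
* **No hierarchical fitting.** Group-level shrinkage would substantially
  improve short-session estimates but is out of scope by design.
* **Fixed, known transition matrix.** Model-based values use the true
  transition probabilities; transition learning is not modelled.
* **The statistical battery mirrors a specific study design** (three
  conditions, order covariate, two planned contrasts); it is not a
  general-purpose ANOVA package.
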