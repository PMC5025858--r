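---
title: "Observational reversal learning: models and analyses in oblearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observational reversal learning: models and analyses in oblearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oblearn)
```

## The problem

In observational learning, an agent learns the value of options not only
from its own outcomes but by watching other agents choose and win or lose.
`oblearn` implements a complete, testable analysis pipeline for a two-deck
card-game paradigm in which a subject plays one trial per round and then
watches two other players play the same decks, while single-neuron spiking
activity is recorded. Because clinical recordings of this kind are not
publicly distributable, the package pairs every analysis with a synthetic
data generator that carries the statistical structure the analyses assume,
so that every stage — from the Bayesian observer to cluster-permutation
inference on spike trains — can be exercised, calibrated, and stress-tested
end to end.

## The task generator

`task_config()` encodes the paradigm: 12 games of 5 rounds, each round one
self trial followed by two observed trials, giving 180 card trials per
session (60 self, 120 observed). One deck pays out with probability 0.7 and
the other with 0.3; at every game boundary the assignment flips with
probability 0.5. Win and loss magnitudes are $10 or $100, equiprobable and
signed by the outcome. After the card game a slot machine wins with
probability 0.5, doubling the running total on a win and halving it on a
loss (a non-negative total can never go negative). Event times sit on a
session clock in seconds: the chosen card is highlighted 1 s before the
outcome, which stays on screen for 3 s; all outcome-aligned analyses treat
outcome onset as t = 0.

The decision rule of the two observed players is not part of the paradigm's
public description, so it is pluggable: the default draws decks uniformly
at random, and a `variance_seeking` alternative alternates decks in a
balanced schedule. The first game's good deck is assigned uniformly at
random. Slot sessions default to 80 trials, matching the scale of ad-lib
play in the recorded sessions.

## The Bayesian observer

The learner is a normative hierarchical Bayesian observer over the reward
contingency $q$ (the probability that the left deck wins) and the reversal
hazard $v$. Because the two decks are inversely related, a single observed
outcome is fully informative: a left-deck win (equivalently a right-deck
loss) has likelihood $q$, the complementary events $1-q$. The belief is a
joint probability mass on a $101 \times 21$ grid over $(q, v)$ — about
0.01 resolution in $q$ at negligible cost — initialised uniform, with
trapezoidal quadrature weights so that grid expectations match continuous
integrals to second order in the spacing (an equal-weight endpoint grid
biases the posterior mean at first order, which is visible against the
Beta–Bernoulli closed form).

At a reversal opportunity the posterior is passed through the mixture
transition $m'(q \mid v) = (1-v)\,m(q \mid v) + v\,m(1-q \mid v)$, applied
column-wise over the hazard grid and marginalised wherever an expectation
is needed. The task reverses only at game boundaries, but a hazard "of
unknown value" can also be read as acting every trial; both modes are
provided (`hazard = "boundary"` is the default as the task's ground truth,
`"per_trial"` the alternative, `"none"` for oracle checks). The belief is
never reset within a session — only the transition mixes it — which is what
produces the characteristic slow re-learning after an actual reversal.

Per trial, before that trial's outcome is absorbed, the observer emits:

* **expected values** $EV_\text{left} = E[q]$, $EV_\text{right} = 1 - E[q]$;
* **choice entropy** $CE = -\sum p \log_2 p$ over the two-deck value pair,
  in bits (1 at complete uncertainty, 0 at certainty);
* **prediction errors** in two codings: binary,
  $\delta = \mathbb{1}\{\text{win}\} - EV_\text{chosen} \in [-1, 1]$, and
  amount, $\delta = \text{amount} - EV_\text{chosen} \times 55$, where 55
  is the mean winning magnitude of the $10/$100 schedule and puts value
  expectations on the dollar scale. The amount coding is the package's
  default for the neural and lagged-PE analyses; both are always emitted.

Choices follow a softmax on the expected values with subject-specific
temperature $\tau$:
$p(\text{left}) = 1 / (1 + e^{-(EV_\text{left} - EV_\text{right})/\tau})$.
`fit_temperature()` maximises the choice likelihood on a log-$\tau$ scale
over $[10^{-3}, 10^{3}]$ with three bracketed golden-section restarts;
boundary solutions and flat likelihoods (e.g. purely random choices, which
push $\hat\tau$ to the upper bound) are flagged in the diagnostics. The
expected values entering the fit are computed without reference to $\tau$.

`reversal_learner()` is the package's central fitted object, with the usual
`print`, `summary`, `coef`, `predict`, `simulate`, `residuals` (the
prediction errors), `plot` and `logLik` methods.

## Behavioural analyses

All group inference reduces to a one-sample t-test across per-subject
coefficients (df = subjects − 1), one-tailed in the direction the effect is
predicted: positive for the EV difference in the choice model, positive
(slowing) for entropy in the choice-time model, positive for past-outcome
and past-PE effects.

* `fit_choice_model()`: per subject, logistic regression of choosing the
  left deck on $V_{L-R}$ and $CE$; coefficients are natural-log odds
  changes. Suspected separation (huge estimate with huge standard error)
  excludes a subject from the group test with a warning.
* `fit_choice_time_model()`: linear regression of choice time on the same
  terms; non-positive or missing choice times are dropped and counted.
* `lagged_outcome_regression()`: predicts the current self choice from the
  win/no-win outcomes (win = 1, no win = 0, separately per chosen deck) of
  the previous six trials. The fixed round order (self, obs1, obs2) makes
  lags 3 and 6 the subject's own previous outcomes and lags 1, 2, 4, 5 the
  observed ones; this is asserted from the data, never hard-coded. Each
  lag contributes an evidence contrast — (left-outcome coefficient minus
  right-outcome coefficient)/2 — and the contrasts are averaged within the
  self and observed lag classes. The model is a linear probability model
  as specified for this analysis, with a logistic variant behind the
  `family` flag. Histories never cross a session boundary.
* `lagged_pe_regression()`: the same design with the most recent
  prediction errors as predictors (lag 3 self; lags 1 and 2 observed).
* `rt_descriptive_tests()`: two-tailed t-tests (objectively better vs worse
  deck; after an observed win vs loss; left vs right), a Spearman
  correlation of choice time with the count of coherent immediately
  preceding outcomes, and one-way ANOVAs across rounds 1–5 and 2–5. Trials
  are pooled across subjects, which is the mode whose trial counts match
  the ns such analyses report; per-subject aggregation is deliberately not
  duplicated here.

## The synthetic cohort

`simulate_behaviour()` replays a generated session closed-loop: the belief
is propagated trial by trial, self choices are drawn from the softmax at
the current expected values, and outcomes are re-drawn under the ground
truth of the chosen deck. Choice times follow
$CT = a + b \cdot CE + c \cdot \mathbb{1}\{\text{round 1}\} + \varepsilon$,
truncated at 150 ms, with defaults $a = 0.8$ s, $b = 0.4$ s/bit,
$c = 0.3$ s, $\sigma = 0.3$ s and $\tau = 0.2$. No reaction-time
distribution is on public record for this task, so the linear-Gaussian
model is a deliberate minimal choice: it plants exactly the effects the
behavioural analyses test (entropy-dependent slowing, round-1 slowing,
value-guided choice) and nothing else. Note that because round-1 trials
also have high entropy, the fitted entropy slope absorbs part of the
round-1 effect and comes out above the planted 0.4 s/bit; this is a
property of the regression, not a bug in the generator.

`simulate_unit()` draws inhomogeneous Poisson spike trains. The rate is a
constant baseline (default 2.3 Hz, the scale of the recorded populations)
plus event-locked half-cosine bumps with onset 250 ms and duration 600 ms
after their event — placing the response inside the 300–900 ms analysis
window — clipped at zero before sampling, discretised at 5 ms with uniform jitter
within bins, and thinned by a 2 ms refractory dead time. Coding profiles
plant: outcome sign coding (with a self/observed sign flip for the
"shadenfreude" profile), signed-amount coding with a configurable
self-trial sign (same-sign = amygdala-like, opposite-sign = rACC-like), and
the tripartite observational-PE scheme — positive expected value at the
observed choice, positive amount and negative expected value after the
outcome. Expected-value modulators are centred within trial type before
planting so they do not shift mean rates.

True per-neuron effect sizes are unknowable from published summaries, so
the default planted gains (8 Hz per unit regressor for outcome/amount
profiles; 12/12/20 Hz for the tripartite EV-choice/amount/EV-outcome terms;
4 Hz main outcome response) were chosen once for testability: large enough
that each downstream analysis recovers its own planted effect at the
recorded population sizes (22 tripartite units of 138; 30 amount coders of
125), small enough that rates stay in a physiological few-to-tens-of-Hz
range. The weakest link is deliberately preserved: the model-free
early-versus-late win comparison is low-powered by construction, because
stochastic outcomes leave some late trials with large prediction errors
and the early/late expected-value gap among amount-matched wins is small
(about 0.05–0.12 in EV units per session).

What the generator does *not* emulate — and what passing tests therefore do
not establish about real recordings: non-Poisson spiking statistics
(bursting, adaptation, slow drift), correlated noise across simultaneously
recorded units, electrode instabilities, non-stationary baselines,
realistic reaction-time distributions, and any systematic behaviour of the
observed players beyond the pluggable policies.

## The neural analysis engine

Firing rates are estimated with a 300 ms moving window stepped by 10 ms;
time stamps are window centers relative to the alignment event and windows
are half-open $[c - 150, c + 150)$ ms, so an edge spike is counted exactly
once. `compute_psth()` returns a trials × bins rate matrix.

The trial GLM has nine columns: a main effect per player role and, per
role, the expected value of the chosen deck and the signed amount as
parametric modulators, mean-centred within trial type (so main effects
capture trial-type means) and scaled to unit variance (single-regressor
t-statistics are invariant to this; contrasts that mix dollar-scaled and
probability-scaled columns are balanced by it). The observational
contrasts are: observed EV = the two observed-EV modulators, observed
amount = the two observed-amount modulators, and observed PE = amount −
EV. `fit_sliding_glm()` runs OLS per window position over −1000..1500 ms
around the outcome and returns t-statistic time-courses per regressor and
contrast; rank-deficient designs fail with the collinear columns named.
Slot-machine trials never enter the GLM; they appear only in the
response-difference analyses.

Cluster inference (`cluster_permutation_test()`) follows the
threshold-and-sum scheme: the mean t-course over the test-set units is
thresholded at ±0.2, consecutive supra-threshold values are summed into
signed cluster masses, and each observed mass is compared with the
distribution of the most extreme sign-matched mass from null draws in
which the same number of units is resampled with replacement from the
area's pool and each drawn unit contributes one random trial-label
permutation of its t-course. A cluster is significant when its mass lies
outside the 99th percentile of that null (P < 0.01). Permuting trial
labels is implemented by row-permuting the design, which is algebraically
identical and allows the per-bin residual variance to be updated from the
permutation-invariant $Y'Y$.

Unit selection mirrors the analyses' logic:

* `select_outcome_responsive()`: one of three conservative criteria on the
  −900..−300 vs 300..900 ms windows — paired one-tailed t-test P < 0.01;
  P < 0.05 together with a response-strength score ≥ 1; or score ≥ 1.5.
  The score is a bootstrap standardised response magnitude (mean over
  trial-bootstrap replicates of mean difference / SD of differences),
  serving as the pluggable response-strength criterion; both the
  implementation and its thresholds are exposed for substitution.
* `tripartite_pe_test()`: selection requires a positive observed-EV
  contrast in at least one window position of the choice period (−900 to
  −300 ms, one-sided P < 0.05/2, Bonferroni over the two signs). Because
  selection happens before the outcome, the post-outcome cluster tests on
  observed amount (expected positive) and observed EV (expected negative)
  are unbiased; the selection-bias guard in the test suite checks this
  literally on null data (KS comparison of outcome-window statistics
  between selected and unselected units).
* `select_and_test_amount_coding()`: selection on a positive observed
  amount effect in 300–900 ms, then a cluster test of the *self*-amount
  regressor, for which no selection bias exists.

`bootstrap_envelope()` resamples units with replacement, smooths each
replicate mean with a 50 ms SD Gaussian (the smoothing bandwidth is a
package choice, config-exposed), and measures response amplitude above the
−3000..−1000 ms pre-choice baseline and onset as the first post-event bin
crossing half the peak; confidence intervals are percentile intervals over
replicates. `mean_response_difference()` computes baseline-corrected
|win − lose| courses with a trial-bootstrap exceedance bound, and
`response_difference_correlation()` correlates these across units between
trial types (self, observed, slot) at α = 0.01/3.

Two model-linearity-free checks complement the GLM:
`quartile_pe_population()` flags units whose upper-PE-quartile rate minus
s.e.m. exceeds the lower quartile's plus s.e.m. at some response-period
bin, testing the population count against a chance rate estimated from
PE-label shuffles (the chance rate of this compound event has no clean
closed form, hence the empirical null, with a numeric override);
`pe_tercile_summary()` reports response-period means per PE tercile with a
monotonicity indicator, ties broken by stable trial order. The early/late
analysis (`model_free_early_late()`) compares wins in rounds 1–2 against
rounds 4–5 (round 3 enters neither class), separately per amount so that
identical outcomes are compared, averaged over amounts, with group tests
per trial class and paired between classes; game/player cells missing an
early or late win are skipped and logged.

## Numerical and design choices

* **Determinism.** Every stochastic function takes a seed; multi-stream
  procedures derive sub-seeds from one root by counter
  (`derive_seed`), and cohort generation is byte-identical across runs
  with the same seed.
* **Degenerate inputs** fail loudly and specifically: constant predictors
  name the term, constant PEs refuse the quartile split, empty event lists
  and mismatched alignments are errors, zero-variance units are excluded
  from selection with a reason.
* **Windows** are drawn from one configuration object
  (`pipeline_config()`): baseline −3000..−1000 ms, choice −500..0 ms,
  early 500..1000 ms, late 1500..2000 ms, pre-outcome −900..−300 ms,
  post-outcome 300..900 ms, GLM span −1000..1500 ms.
* **Problem sizes in the test suite.** The calibration suites run at sizes
  chosen to give tight binomial confidence bands at reasonable cost: the
  behavioural null calibration permutes responses within subject 1000
  times; the cluster-permutation calibration runs 1000 independent null
  cohorts (pools of 12 simulated units, 6-unit test sets, 40 label
  permutations per unit) at 1000 null draws per test, checking the 1%
  flag rate separately for positive and negative clusters; recovery runs
  use the recorded population sizes (10 subjects × ~3 sessions; 138
  rACC-like and 125 AMY-like units). Full-scale analyses of real data
  would raise the shuffle counts (the cluster null to 10,000 draws and
  1000 permutations per unit, envelopes to 10,000 bootstraps) without any
  code change.

## Known limitations

The observer assumes the task's true generative structure (known 0.7/0.3
contingency values are *not* imposed — the grid spans all of [0, 1], which
makes the model strictly more general than the task); the observed-player
policy is a stand-in; the GLM treats per-bin rates as Gaussian, which is
standard but approximate at low counts; and the h-style response-strength
score is a documented surrogate, so selection counts under criteria 2 and
3 are comparable only within this package's definition.
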