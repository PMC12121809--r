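---
title: "Modeling biases in human random number generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling biases in human random number generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rngbias)
```

## The choice model

`rngbias` treats each response in a random number generation (RNG) task as
a draw from a multinomial softmax over the `K = 9` digits, whose weights
depend on the history of the sequence through four features: a one-hot
repetition indicator `r` of the previous response, a side-switch code `s`
(+1 for digits on the opposite half of the keypad, −1 for the same half, 0
at the neutral digit 5), the Euclidean distance `d` from the previous
response in the keypad geometry, and the gap `g` — for each digit, the
number of steps since it was last produced, initialized at 1, reset to 1 on
selection and incremented otherwise.

Four nested variants are implemented (`model_params()`): the original
two-parameter repetition + side-switching model (`yousif2`), a
two-parameter repetition + distance model (`dist2`), and three-parameter
models that add a cycling bias either linear in the gap (`cyc3_lin`) or on
a base-2 logarithmic gap scale (`cyc3_log`). The logarithmic scale
expresses saturation: once a digit has been unused for a long time, one
more step matters little. The base of the logarithm is fixed at 2; a
different base would only rescale β and break comparability with published
estimates.

The first response of a sequence has no defined features, so feature
encoding, likelihood and prediction all start at the second response. The
linear predictor is evaluated with log-sum-exp stabilization, since
parameters range over `[-10, 10]` and linear gaps grow with sequence
length.

### Parameters, units, defaults

* **ε (repetition)** — weight on the repetition indicator; ε > 0 favors
  immediate repetitions. At ε = +10 (all else 0) the repeat probability is
  e¹⁰/(e¹⁰+8) = 0.9996, the calibration anchor for the `[-10, 10]` box.
* **δ (distance)** — weight per grid unit of keypad distance; δ < 0 favors
  digits adjacent to the previous one. Distances are raw Euclidean
  distances in the unit-spaced 3×3 grid (digits 1–3 on the top row);
  no normalization is applied, so δ is interpretable per grid unit. A
  one-dimensional layout (`keypad_layout("line1d")`) uses numerical
  distance instead, e.g. distance 3 for the pair 4–7.
* **β (cycling)** — weight on the (log-)gap; β > 0 is the
  gambler's-fallacy tendency to favor long-unused digits.
* **η (side-switching)** — only in `yousif2`; defined only for the
  nine-digit task, hence rejected for other alphabets.

## Estimation

`fit_mle()` maximizes the sequence log-likelihood by L-BFGS-B inside the
`[-10, 10]` box, from a fixed table of five starting points, making the
result deterministic. It exists because a per-sequence point estimate is
cheap (fractions of a second) and is all that the predictive scorer, the
recovery study and most tests need. On degenerate sequences (e.g. one with
no repetitions at all) the likelihood is monotone in ε and the estimate
pins at the box boundary, which is the correct constrained optimum.

`fit_hierarchical()` implements the population model: each participant's
parameter vector is a draw from independent normals, `θ_nj ~ N(μ_j,
σ_j²)`, with uniform hyperpriors `μ_j ~ U(−10, 10)` and `σ_j ~ U(0, 10]`.
Sampling is by an adaptive Metropolis-within-Gibbs scheme written for this
posterior:

* each participant's parameter vector is updated by joint random-walk
  Metropolis, three sweeps per iteration, with per-coordinate proposal
  standard deviations that track the running posterior SD during warmup
  and a global scale adapted toward an acceptance rate of 0.3;
* each population mean μ_j is a conjugate Gibbs draw from a truncated
  normal;
* each population SD σ_j is an exact Gibbs draw: under the uniform prior
  on σ, the conditional of σ² is scaled-inverse-chi-square with N−1
  degrees of freedom, truncated at σ = 10.

Chains are initialized uniformly in `[-2, 2]` (population SDs in
`(0.1, 2]`). Adaptation stops at the end of warmup, so the kept draws come
from a fixed transition kernel. Convergence is monitored by split-R-hat
and effective sample size for every hyperparameter (`check_convergence()`,
threshold 1.01); violations attach a warning to the result rather than
failing, so long runs are never silently discarded. Desk-scale defaults
are 4 chains × (1000 warmup + 1000 kept) draws; on a 30-participant cohort
of 200-response sequences this takes on the order of a minute or two and
yields hyperparameter effective sample sizes in the hundreds to thousands.
Larger configurations are a matter of passing `iter`/`warmup`/`chains`.

Two structural choices deserve note. The hyperprior bounds are enforced by
truncation on the sampled scale (the uniform prior simply zeroes the
density outside the box). And the per-participant posterior summaries are
plain posterior means; predictive scoring plugs these in rather than
averaging accuracy over posterior draws — draw-averaging is a one-line
change but the plug-in convention is what the reported accuracies mean
here.

## Simulation

`simulate_sequence()` draws the first response uniformly (the model needs
a starting number) and each later response from the model probabilities
under the evolving history. A master seed spawns one child stream per
sequence, so cohorts (`simulate_cohort()`) are reproducible and
order-independent; the full provenance of every simulated object is its
parameter set plus one integer. `permute_sequence()` provides the
benchmark of randomly re-ordered sequences with identical digit counts.

The extreme-parameter calibration is simulated with the `dist2` variant
with all non-repetition parameters at zero; with the other parameters at
zero the variant choice does not affect the likelihood, so this choice is
immaterial and merely fixes a concrete code path.

## Randomness measures

Four sequence-level indices (`randomness_profile()`):

* **phi index (block 4)** — over all overlapping windows of length 4,
  `100 · (p_obs − p_exp)`, where `p_obs` is the fraction of windows whose
  first and last digits coincide and `p_exp = Σ n_k(n_k−1) / (L(L−1))` is
  the without-replacement coincidence probability implied by the digit
  counts. Negative values: too few lag-3 repetitions.
* **block entropy (block 3)** — Shannon entropy (bits) of the empirical
  distribution of overlapping length-3 windows; 0 for a constant
  sequence, at most `log₂(L−2)`.
* **coupon score** — mean number of responses to complete the full digit
  set, scanning with reset; undefined (NA) when no set completes. For
  uniform draws the coupon-collector expectation is 9·H₉ = 25.46.
* **mean gap** — mean positional distance between successive occurrences
  of the same digit, pooled over digits; undefined when nothing recurs.

The literature behind these indices does not print formulas and does not
say whether blocks overlap; the definitions above (overlapping windows,
plug-in entropy, without-replacement expectation for phi) are fixed here
because they reproduce the published sign and magnitude patterns — e.g.
strongly negative phi for cycling-biased sequences, near zero for
permutations. Undefined measures propagate as NA and are excluded
pairwise in downstream means.

## Evaluation procedures

**Predictive accuracy** (`predictive_accuracy()`): for each trial,
probabilities are computed from the true history; the realized response
earns 1 if it is the unique modal prediction, 1/n in an n-way tie among
modal candidates, else 0. Ties are detected at a relative tolerance of
1e-9 on probabilities — with the symmetric keypad, exact ties are
structural (the all-zero model ties all nine digits every trial, which is
why its score is exactly 1/9). **Paired comparison**
(`paired_model_comparison()`): paired t-test plus Cohen's d for dependent
measures, `d = mean(diff) / (sd(diff) / sqrt(2(1−r)))`.

**Bootstrap classification** (`bootstrap_classification()`): per
iteration, `n_draw` units are drawn with replacement from the pooled
labeled measure values, an intercept+slope logistic regression is fitted,
and the out-of-bag units are classified at threshold 0.5; the mean and
2.5/97.5 percentiles of the correct rate over iterations are reported.
`n_draw` defaults to twice the first group's size, matching the design of
pairing each sequence of one source with one of the other. Out-of-bag
units are classified per unit, not per pair.

**Recovery study** (`recovery_study()`): true parameters are drawn
uniformly in per-parameter ranges, one sequence is simulated per draw,
and the simulated cohort is refitted; true-vs-fitted correlations plus
the cross-correlation matrix of fitted values are reported. By default
the refit is hierarchical — all simulated sequences jointly, per-sequence
posterior means as the estimates — matching how estimation is done
everywhere else. This matters: under the simulation ranges a substantial
fraction of sequences contain no immediate repetition at all, leaving
their repetition weight unidentified from below; hierarchical shrinkage
keeps those estimates in a sensible range, whereas per-sequence maximum
likelihood (`fit_method = "mle"`) pins them at the −10 boundary and
visibly depresses the recovery correlation for ε. The published design
derived its
ranges from the 2.5th/97.5th percentiles of 830 human individual-level
estimates; as that cohort is not shipped, the default ranges are the
normal-implied percentiles μ ± 1.96σ of the published population
hyperparameters (ε: −0.41 ± 1.96·1.48, δ: −0.32 ± 1.96·0.69, β: 0.77 ±
1.96·0.37).

## What the simulations show — and what they do not

The generator emulates the study conditions: 200-response sequences on
the 3×3 keypad, cohorts with participant-level parameters drawn from the
published population distributions, 20 model-driven replicates and 20
permutations per participant where the design calls for them. Passing
tests therefore show that the estimation and evaluation machinery is
self-consistent under the model: parameters generate data from which they
can be re-estimated (true-vs-fitted correlations above 0.9 at length 200,
cross-correlations below 0.2), the cycling model out-predicts the
distance model on cycling-generated cohorts, and the measures respond to
the cycling bias in the published direction (negative phi, short
coupons). They do not show that human sequences follow the model: real
data carry structure the model does not encode (motor stereotypies,
drifts in attention, favored multi-digit patterns), which is exactly what
the residual classification rates above 50% in the published comparison
reflect. Analyses of human cohorts require the external dataset as input.

## Numerical choices and problem sizes

Validation studies run at sizes chosen to make their Monte-Carlo error
comfortably smaller than the effects they check, while staying desk-scale:
length-100,000 sequences for the calibration anchors (binomial SE ≈
6e-5), 100 sequences for the recovery study (correlation SE ≈ 0.02 at r =
0.9), 40-participant cohorts for model-ordering comparisons, a
30-participant cohort with 4 chains × (1000 warmup + 2000 kept) draws for
hyperparameter recovery, and 300–1000 bootstrap iterations for
classification anchors. Optimizer non-convergence in the MLE recovery
path is recorded and the affected sequence excluded; boundary estimates
at ±10 are legitimate constrained optima, not failures.

## Known limitations

* The repetition weight ε is only partially identifiable from a single
  200-response sequence when repetitions are strongly suppressed: once a
  sequence contains no immediate repetition at all, its likelihood is
  flat in ε below roughly −1, and neither maximum likelihood nor
  hierarchical shrinkage can order the true values within that region.
  Recovery correlations for ε are therefore systematically lower than
  for δ and β under simulation ranges that reach far into repetition
  avoidance; longer sequences are the only real remedy.
* The side-switching feature is only defined for the nine-digit task;
  other alphabets must use the distance or cycling variants.
* The sampler is a random-walk scheme: adequate at cohort scales of tens
  to hundreds of participants, but a gradient-based sampler would scale
  better to very large cohorts with long sequences. Its centered
  parameterization also mixes more slowly when a population SD is
  essentially zero (all participants sharing one parameter value) — the
  funnel regime; estimates remain sensible there but split-R-hat can
  exceed the 1.01 threshold and the attached warning should be heeded.
* Only discrete `1..K` response formats are supported — no continuous
  (free-click) response lines, no reaction-time modeling, and no
  time-varying parameters within a sequence.
* Bayes-factor model comparison is not implemented; model selection here
  is by predictive hit rate and paired tests.
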