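---
title: "Models and methods: prediction-error-gated risk preferences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: prediction-error-gated risk preferences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peirs)
```

## The task

The package implements a two-alternative value/risk bandit. Four stimuli
cross two generative means (60 vs 40 points) with two generative
standard deviations (20 vs 5 points): risky-high (stimulus 1), safe-high
(2), risky-low (3), safe-low (4). Rewards are approximately Gaussian
integers in 1–99. A session has 4 blocks of 120 trials; within every
block each of the 12 ordered stimulus pairs appears exactly 10 times, in
a uniformly shuffled order with no further constraints. Trials fall into
three conditions by the value classes of the shown pair: *different*
(one high-mean, one low-mean stimulus), *both-high* (1 vs 2) and
*both-low* (3 vs 4). The matched-mean conditions are the measurement
instrument: with means equal, choice between the risky and the safe
member isolates risk preference.

Because the mid-range reward expectation is 50, a learner holding
accurate values experiences a reward prediction error at stimulus onset
("stimulus PE") of $+10$ in both-high and $-10$ in both-low — opposite
signs in otherwise symmetric conditions, which is what lets the gating
hypothesis be tested behaviourally.

`sample_reward()` realizes "approximately Gaussian integers" as a
normal draw rounded to the nearest integer and clipped into [1, 99].
Clipping (rather than resampling) keeps the realized risky-arm mean
within 0.2 points of the nominal 60; rounding adds 1/12 to the variance,
negligible at both spread levels. Whether the original task clipped,
truncated or resampled is not documented; clipping is this package's
choice.

## The model family

All twelve models are Rescorla–Wagner variants. The shared core is a
delta rule on the value $Q_i$ of the chosen stimulus $i$,

$$\delta_{\text{out}} = r - Q_{\text{chosen}}, \qquad
  \Delta Q_{\text{chosen}} = \alpha\,\delta_{\text{out}},$$

with softmax choice $p_i = e^{\beta A_i} / \sum_j e^{\beta A_j}$ over the
two shown options. $Q_0 = 50$ (the mid-range) for every model; values
and spreads of unchosen stimuli never change; all latents reset at every
block boundary, because each block uses a new set of stimulus images.
The variants differ in exactly one dial:

* **Utility families** (`concave-UTIL`, `convex-UTIL`, `s-shaped-UTIL`,
  `inverse-s-UTIL`): rewards pass through a utility function before the
  prediction error, $\delta_{\text{out}} = U(r) - Q_{\text{chosen}}$,
  with $z = (r-m)/\sigma$, $\sigma = m = 50$ fixed. The exponential
  family is $U = m + \sigma\,(1 - e^{-kz})/k$ (concave $k>0$, convex
  $k<0$); the sign-preserving power family is
  $U = m + \sigma\,\mathrm{sign}(z)\,|z|^{k}$ (s-shaped $k \in [0,1]$,
  inverse-s $k > 1$). Note the transform enters only the prediction
  error: $Q$ then lives on the utility scale while the softmax still
  consumes $Q$ directly.
* **Rate rules** (`pos-neg-RATES`, `variance-RATES`,
  `attention-RATES`): the learning rate depends on the sign of
  $\delta_{\text{out}}$ ($\alpha_+/\alpha_-$), on whether the chosen
  arm is risky ($\alpha_{\text{risky}}$ for stimuli 1 and 3,
  $\alpha_{\text{safe}}$ for 2 and 4), or on surprise,
  $\Delta Q = \alpha\,|\delta|^{k_{\text{att}}}\,\delta$. The attention
  rate can exceed 1 for large surprises; no clamp is applied, and
  run-away dynamics are held in check only by the fitting priors.
* **Scaled prediction errors** (`scaled-PE`): a learned spread
  normalizes the PE, $\tilde\delta = (r - Q)/S$, with
  $\Delta Q = \alpha_Q \tilde\delta$ and
  $\Delta S = \alpha_S(|\tilde\delta| - 1)$.
* **Risk gating** (`PEIRS`, `PIRS`, `OEIRS`): alongside $Q$, the model
  tracks the reward spread
  $\Delta S_{\text{chosen}} = \alpha_S(|\delta_{\text{out}}| -
  S_{\text{chosen}})$, so $S$ converges to the mean absolute deviation
  of the arm's rewards ($\sigma\sqrt{2/\pi}$ for a Gaussian arm, about
  16 points for the risky arms). The spread enters the action value
  through a tanh gate,
  $$A_i = Q_i + \tanh(\omega\,\delta)\,S_i,$$
  so positive gating signals make uncertain options attractive and
  negative ones make them repulsive. The gate $\delta$ is the stimulus
  PE — pair mean of $Q$ minus the grand mean over all four $Q$ — for
  PEIRS, the raw pair-mean prediction for PIRS, and the previous
  trial's outcome PE for OEIRS (initialized to 0 at block start, where
  no previous outcome exists). The $\tanh$ argument is $\omega$ times
  the gate in raw points, without normalization. This form is the
  reduced expression of a basal-ganglia account in which dopamine
  shifts the balance between the direct ("Go") and indirect ("NoGo")
  pathway, which encode the upper and lower ends of the learned reward
  distribution; the package works entirely at this reduced behavioural
  level.

With $\omega = 0$, equal rates, unit/vanishing curvatures,
$k_{\text{att}} = 0$, or $\alpha_S = 0, S_0 = 1$ (scaled-PE), every
variant collapses to RW trial-by-trial — the test suite asserts all
eleven reductions give identical choice probability streams.

## Parameters, transforms and priors

Fitting works on an unconstrained ("raw") parameterization: logit for
rates and the s-shaped curvature, log for $\beta$, $k_{\text{concave}}$
and $S_0$, $\log(-k)$ for the convex curvature, $\log(k-1)$ for the
inverse-s curvature, identity for $\omega$. Independent Gaussian priors
on raw values (mean, variance): all learning-rate logits $(-1, 2)$;
$\log\beta$ $(-2, 2)$; curvature parameters $(-3, 4)$ except the
s-shaped logit $(3, 4)$; $\omega$ $(0, 20)$; $\log S_0$ $(2, 2)$. Shared
parameters share priors across models. The attention exponent has no
documented prior; this package assigns raw-space $N(0, 4)$, a scale
comparable to the other shape parameters — users fitting
`attention-RATES` should be aware this choice is the package's own.

`fit_map()` maximizes log-likelihood plus log-prior with multi-start
BFGS (numerical gradients; default 10 starts: the prior mean plus prior
draws; relative convergence tolerance $10^{-9}$, ties broken by the
best objective value). The original analysis behind this design used a
variational-Bayes toolbox; maximum a posteriori estimation with the
same priors is deterministic and dependency-light, and the comparison
currency — BIC rankings — is preserved. BIC is computed at the MAP
point as $k \ln n - 2\,\mathcal{L}$ with $n$ the number of trials per
participant (480 at full size); a per-block convention would shift all
models equally and leave rankings unchanged. Cohort-level comparison is
fixed-effects: BIC summed over participants (`compare_models()`), not
random-effects model selection.

The likelihood replay runs in C++ for speed; the simulator is
independent R code, and the tests cross-check the two paths trial by
trial, besides checking both against a third, plain reference
implementation.

## Synthetic cohorts and what they do and do not show

`generate_cohort()` produces fully specified ground-truth agents:
parameters from the priors, from per-model documented defaults
(learning rates 0.3, $\beta = 0.2$, and for the gated models
$\alpha_S = 0.1$, $\omega = 0.5$, $S_0 = 10$), or from a fixed list.
Master seed to per-participant seed uses a fixed-stride counter, so any
cohort is reproducible from one integer. The optional sanity filter
redraws parameter sets whose agent fails the behavioural inclusion rule
(more than 65% high-value choices, strictly, in the late
different-condition trials); without it, wide prior draws produce many
random responders and recovery statistics mostly measure noise. The
filter caps at 100 redraws and treats unlearnable configurations (for
example $\beta = 0$) as errors.

The generator emulates the schedule, reward statistics, and
model-driven choice of the task — not reaction times, screen-side
effects, attention lapses, session fatigue, or any between-participant
correlation structure beyond independent parameter draws. Passing tests
therefore certify the pipeline (simulation, likelihood, optimizer,
statistics) on data that obey the model assumptions exactly; they do
not certify that empirical data satisfy those assumptions.

The simulation-study protocol follows a fixed aggregation order:
risk-preference traces and condition differences are averaged over
experiment repetitions within each simulated participant first, then
over participants. Test-scale studies use tens of repetitions rather
than the 1000-repetition production setting; the acceptance checks run
20 replicate 27-agent cohorts, parameter recovery uses 30 agents, and
model recovery 20 datasets per generating model with all 12 candidate
models — sizes chosen so the whole battery completes in minutes on one
core while keeping Monte-Carlo error well inside the asserted margins.

## Behavioural analyses

`analyze_cohort()` applies the inclusion rule ("second half of the
blocks" is read as within-block trials 61–120, pooled over blocks,
matching the per-block latent resets), then computes the binned
accuracy trace (participant means per bin first, then cohort mean and
SE), per-condition risk preferences with a paired two-tailed t-test
(both-high vs both-low) and one-sample tests against 0.5, and an
emergence-speed test. The original emergence analysis was a mixed
model with a Monte-Carlo likelihood-ratio test; the package uses a
simpler two-stage design testing the same interaction: per participant
and decision type, a logistic regression of the preferred-choice
indicator on within-block trial number, then a t-test of the
slope differences. "Preferred" is the high-value option in the
different condition, the risky option in both-high and the safe option
in both-low — the asymptotic preferences of a gated agent; this coding
is an explicit package choice, as the original dependent-variable
coding for risk trials is not documented. Logistic fits with complete
separation are slope-clipped at ±1 and flagged. Degrees of freedom are
reported as computed from the data at hand.

## Numerical choices and degenerate inputs

* Softmax probabilities are computed max-subtracted; likelihood replay
  uses the numerically stable two-option logistic form. $\beta = 0$
  yields exact chance probabilities and a finite likelihood.
* In `scaled-PE`, the spread update $\Delta S = \alpha_S(|\tilde\delta|-1)$
  can cross zero; $S$ is floored at $10^{-3}$ to keep the divisor
  positive. The gated models need no floor (their $S$ update is a convex
  combination of non-negative quantities).
* Zero prediction errors skip the value update, which also guards the
  attention rule's $|\delta|^{k}$ at $\delta = 0$, $k < 0$.
* Moving-average smoothing of traces shrinks its window at the edges
  instead of padding, so no pre-trial data is fabricated.
* The 2-D preference density uses per-axis Silverman bandwidths and a
  bandwidth floor (with a warning) for degenerate point clouds; contour
  levels are spread over each density's own value range.
* Non-positive schedule sizes, identical-member pairs, out-of-range
  parameters, choices outside the shown pair, and incomplete
  model-comparison grids raise immediate errors rather than propagating.

## Known limitations

* MAP + BIC is a deliberate, documented replacement for variational
  inference; absolute BIC values need not match other toolboxes, only
  rankings are comparable.
* A plain RW learner in this task is *not* exactly risk-neutral: with a
  learning rate around 0.3, asymmetric sampling produces risk aversion
  in both matched-mean conditions and a systematic positive condition
  difference of roughly 0.04 (it vanishes only for rates below about
  0.15). This is a real property of delta-rule learning with softmax
  exploration under unequal sampling, reproduced here by two
  independent implementations — worth keeping in mind when using RW
  cohorts as a "no effect" baseline.
* $\omega$ is weakly identified once $|\omega\,\delta|$ saturates the
  tanh; recovered magnitudes shrink toward the prior while the sign is
  recovered reliably.
* The package analyzes choices only; response times and physiological
  measures are out of scope.
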