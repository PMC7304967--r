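---
title: "The boosted-anticipation choice model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The boosted-anticipation choice model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(savor)
```

## The model

Why do people (and many animals) pay for information about a future outcome
they cannot change? The savoring account holds that waiting itself carries
utility: anticipating a reward of value $R^+$ delivered after a delay $T$ is
worth, at time $t$ of the wait, $a(t) = R^+ e^{-\nu^+(T-t)}$, an anticipation
signal that ramps up as the outcome approaches at rate $\nu^+$ (1/s).
Discounted at rate $\gamma$ and integrated over the wait, anticipation
contributes
$$A^{\pm}(T) = \frac{R^{\pm}}{\nu^{\pm}-\gamma}\left(e^{-\gamma T} - e^{-\nu^{\pm} T}\right)$$
per unit of anticipation weight, on top of the conventionally discounted
outcome $B^{\pm}(T) = R^{\pm} e^{-\gamma T}$. The two valences are separate:
participants also assign a *negative* value $R^- \le 0$ to the no-reward
outcome, so waiting for bad news carries negative anticipation (dread) at its
own rate $\nu^-$. We fix $R^+ = 1$, which defines the value unit.

The model's key move is that the anticipation weight is not constant. An
advance-information cue (reward-predictive $S^+$, shown with probability $q$,
or no-reward-predictive $S^-$) elicits a prediction error over
anticipation-plus-reward value (aRPE), and the *magnitude* of that surprise
boosts anticipation for the whole waiting period:
$$\eta = \eta_0 + C\,|\delta_{aRPE}|.$$
Because the boosted weight feeds back into the cue values that define the
prediction error, the aRPE must be determined self-consistently. Under the
linear boosting ansatz the coupled system collapses to the closed form
$$\delta^{+} = \frac{(1-q)\,\big(\eta_0(A^+ - A^-) + B^+ - B^-\big)}{1 - C\big((1-q)A^+ - qA^-\big)},
\qquad
\delta^{-} = \frac{-q\,\big(\eta_0(A^+ - A^-) + B^+ - B^-\big)}{1 - C\big((1-q)A^+ - qA^-\big)},$$
implemented in `solve_arpe()`. The independent fixed-point iteration of the
unreduced system (`arpe_fixed_point()`) is kept in the package as a
cross-check; the two agree to near machine precision throughout the
admissible region, and the test suite asserts this on hundreds of random
draws.

Self-consistency fails when the denominator reaches zero: boosting then
feeds on itself without bound (an addiction-like runaway). Since $A^+(T)$
peaks at $T = \ln(\gamma/\nu)/(\gamma - \nu)$, the admissible gains are
$$C < C_{\max} = \min\left(\frac{\gamma}{R^+}\Big(\frac{\gamma}{\nu^+}\Big)^{\frac{\nu^+}{\gamma-\nu^+}},\;
 \frac{-\gamma}{R^-}\Big(\frac{\gamma}{\nu^-}\Big)^{\frac{\nu^-}{\gamma-\nu^-}}\right),$$
computed by `stability_bound()` (with the analytic limits at $\gamma = 0$ and
$\nu = \gamma$). All fitting code reparameterizes
$C = C_{\max} \cdot \mathrm{logistic}(h_C)$ so that every candidate during
optimization is admissible by construction.

Choice between the *immediate-information* target (value
$V_{II} = qQ_{S^+} + (1-q)Q_{S^-}$, with
$Q_{S^\pm} = (\eta_0 + C|\delta^\pm|)A^\pm + B^\pm$) and the
*no-information* target
($V_{NI} = \eta_0(qA^+ + (1-q)A^-) + qB^+ + (1-q)B^-$; no cue, no prediction
error, no boosting) passes through a sigmoid,
$$p(II) = \frac{1}{1 + e^{-(V_{II}-V_{NI})/\sigma}}.$$
Whether the noise parameter divides or multiplies the value difference is a
convention; we adopt the temperature form ($\sigma$ divides), the standard
softmax convention in which $\sigma \to \infty$ yields indifference. The
alternative convention only rescales the fitted $\sigma$.

Two reductions matter throughout. With $C = 0$ the probability weighting of
anticipation cancels exactly between the targets, so $V_{II} \equiv V_{NI}$:
*anticipation alone, however strong, assigns no value to advance
information*. With $\eta_0 = C = 0$ the model is plain exponential
discounting, again indifferent. Only boosting ($C > 0$) makes information
valuable, increasingly so at longer delays when discounting is weak — the
behavioral signature this model exists to capture.

```{r preference-curve}
p <- savor_params(R_minus = -0.2, eta0 = 0.5, C = 0.08, nu_plus = 0.15,
                  nu_minus = 0.15, gamma = 0.002, sigma = 0.15)
g <- condition_grid()
round(tapply(choice_prob(p, g$q, g$T_s), g$T_s, mean), 3)
```

## Parameters and their transforms

| parameter | meaning | units | constraint | transform |
|---|---|---|---|---|
| $R^-$ | no-reward value | value | $\le 0$ | $-e^{h}$ |
| $\eta_0$ | base anticipation weight | — | $\ge 0$ | softplus |
| $C$ | boosting gain | 1/value | $0 \le C < C_{\max}$ | $C_{\max}\,\mathrm{logistic}(h)$ |
| $\nu^+,\nu^-$ | anticipation rates | 1/s | $> 0$ | $\log$ |
| $\gamma$ | discount rate | 1/s | $> 0$ in fits | $\log$ |
| $\sigma$ | choice noise | value | $> 0$ | $\log$ |

Boundary values ($R^- = 0$, $\eta_0 = 0$, $C = 0$) are clamped to $h = -30$,
the resolution limit of the transform; `transform_params()` and
`untransform_params()` round-trip to $10^{-12}$ on the interior. The
$\nu = \gamma$ degeneracy of $A^\pm$ is a removable singularity handled by
switching to the analytic limit $R\,T e^{-\gamma T}$ when
$|\nu - \gamma| < 10^{-9}$.

## Hierarchical fitting

`fit_savor()` treats each subject's transformed parameter vector as a draw
from a diagonal Gaussian population distribution and finds the
maximum-likelihood population moments by approximate
expectation-maximization. The E step computes each subject's MAP under the
current prior by multi-start BFGS and a Laplace (inverse-Hessian) Gaussian
approximation of the posterior; the M step averages MAPs into the new mean
and average second moments (MAP squared plus Laplace variance) minus the
squared mean into the new variances. Choices depend on the condition only,
so each subject's likelihood is evaluated from condition-level counts (at
most 25 cells), with the hot loop compiled; a per-trial likelihood floor of
$10^{-12}$ guards against $-\infty$ under extreme candidates.

Numerical choices: the Hessian uses central differences with relative step
$10^{-4}$ and a ridge of $10^{-6}$ (escalated tenfold until positive
definite); BFGS runs up to 200 iterations from the previous MAP, the prior
mean, and restarts drawn from the prior; EM stops when the prior mean moves
less than $10^{-3}$.

Two departures from textbook EM deserve explanation, both consequences of
the approximate E step. First, with an approximate E step the EM objective
is *not* guaranteed monotone, and on this model it genuinely is not: the
likelihood has soft ridges — $\eta_0$, $R^-$, $C$ and $\sigma$ trade off
almost freely at small effect on the choice probabilities — and along such
ridges the iteration can random-walk away from its own optimum,
occasionally into a degenerate basin with collapsed population variances.
`fit_savor()` therefore scores every iterate's marginal likelihood directly
by Monte-Carlo integration (`mc_samples` draws per subject, with common
random numbers across iterates so the comparison is low-noise), returns the
best-scoring iterate, and stops after `em_patience` iterations without
improvement; the Laplace approximation of the same quantity is logged in
the trace alongside. Second, the final solution depends on the starting
prior. The default initialization centres the starting prior on the
*pooled* MAP (all subjects' trials fitted as one) with variance
`init_var` (0.1), which lands in the main basin far more reliably than a
fixed guess; `n_em_inits` runs the whole EM from additional jittered starts
and keeps the best objective. These are optimizer safeguards, not changes
to the model: the estimand is unchanged.

## Model comparison by integrated BIC

`ibic()` estimates $\log p(D \mid \theta)$ by drawing $K$ parameter vectors
per subject from the fitted prior (default $K = 1000$; the Monte-Carlo
standard error is reported) and averaging the data likelihood with
log-sum-exp stabilization, then penalizes the number of fitted prior
parameters: $\mathrm{iBIC} = -2\log p + |M| \log |D|$, where $|M|$ counts
prior means and variances (14, 12 and 10 for the full, no-boost and
no-anticipation variants) and $|D|$ the total choices.
`compare_savor_models()` fits and scores all variants.

One structural fact shapes what model comparison can and cannot do here: the
no-boost ($C = 0$) and no-anticipation ($\eta_0 = C = 0$) variants are
*behaviorally identical* — both predict exact indifference on every trial,
so their data likelihoods coincide and the smaller model always wins the
penalty. Model recovery can therefore distinguish "boosting" from "no
boosting", but no choice data can separate unboosted anticipation from no
anticipation in this task. Simulation studies with this package show exactly
that pattern: cohorts generated with boosting recover the full model;
cohorts generated from either reduced variant recover the no-anticipation
variant (the smallest indifferent model).

## From fitted model to imaging regressors

During a wait the model predicts, per valence, an anticipatory-utility
signal $V_{Ant,\pm}(t) = R^\pm \eta\,(e^{-\gamma(T-t)} -
e^{-\nu^\pm(T-t)})/(\nu^\pm - \gamma)$, its generating *urgency* signal
$R^\pm \eta\, e^{-\nu^\pm(T-t)}$ (anticipation is the discounted integral of
urgency — an identity the tests verify by quadrature), and the discounted
outcome value $R^\pm e^{-\gamma(T-t)}$. After a predictive cue the matching
valence carries the boosted weight $\eta = \eta_0 + C|\delta^\pm|$; after a
no-information choice both valences run unboosted, scaled by $q$ and $1-q$,
with no prediction error. At cues the aRPE amplitudes (zero for NI) form a
parametric modulator; state prediction errors $|1-q|$, $|0-q|$ and the
standard RPE $(1-q)(B^+-B^-)$, $-q(B^+-B^-)$ are available as control
modulators.

`build_design_matrix()` assembles these into a GLM: signals are built at a
0.1-s microtime step (waiting-period dynamics are sub-TR), convolved with
the canonical double-gamma HRF (response delay 6 s, undershoot delay 16 s,
dispersions 1, ratio 6, 32-s kernel, unit integral) and sampled at the scan
times (TR default 3.36 s). Events enter as unit-area impulses and interval
signals with trapezoid edge weights, which makes the sampled regressors
second-order accurate in the microtime step (halving the step changes
columns by under $10^{-3}$ relative RMS). Parametric modulators are
mean-centered across their events and never orthogonalized. Cues before the
shortest (1-s) delay get their own onset column, and 1-s trials are excluded
from the time-varying and parametric cue columns, so outcome-evoked variance
cannot leak into prediction-error estimates. Nuisance columns: a
waiting-period boxcar, per-run intercepts and a discrete-cosine basis
implementing the 128-s high-pass. Optional control columns (constant
expected value; a linear ramp over each wait) sit behind configuration
flags. PPI regressors are centered products of a seed series and a
psychological series (optionally z-scored); no hemodynamic deconvolution is
applied — the product is formed in signal space, a configuration hook one
should keep in mind when comparing against deconvolution-based pipelines.

## The phase-randomization test

Slowly varying model regressors can correlate spuriously with slowly
varying noise. `randomization_fwe_test()` addresses this with surrogate
data: the tested regressor is Fourier-transformed, the phases of its
positive frequencies are redrawn uniformly on $(-\pi, \pi]$ (conjugates
mirrored; DC and Nyquist kept real, so the surrogate is real with exactly
the original power spectrum), and the GLM is refit with only that column
replaced — 100 surrogates per subject. A second level then draws one
surrogate result per subject, takes a one-sample t across subjects per
channel, and records the maximum over the channel family; 1000 such
resamples form the null of the familywise maximum. Corrected p-values use
the add-one rule $p = (1 + \#\{\mathrm{null} \ge t\})/(R+1)$ (never exactly
zero). A cluster-mean statistic is available instead of the maximum. On null
synthetic BOLD the test holds its level — familywise rejections at the 5%
threshold occur at or below the nominal rate in the package's calibration
runs, with a slight conservative tendency from the second-level resampling.

## The synthetic task generator

`generate_trials()` reproduces the study design: probabilities
$\{0.05, 0.25, 0.5, 0.75, 0.95\}$ crossed with delays $\{1, 5, 10, 20, 40\}$
s, three runs per subject, each run one randomized pass through all 25
conditions (the conditions appear random to the participant while remaining
exhaustively balanced within runs), a 3-s response window, 1-s outcome
display and 1-s blank; 39 subjects by default. Outcomes are Bernoulli($q$);
choices come from the model's own sigmoid via `simulate_choices()`, with
per-subject parameters drawn from a group prior when one is given.
`default_group_prior()` is the package's reference population: moderate
negative $R^-$ (≈ −0.3), $\eta_0 ≈ 0.5$, boosting at 40% of the stability
bound, rates ≈ 0.2/s, weak discounting (γ ≈ 0.01/s) and noise σ ≈ 0.2,
giving information-choice rates that rise from near indifference at 1 s to
roughly 70–80% at 10–20 s. `simulate_bold()` adds design-times-weights
signal, two low-order cosine drifts and AR(1) noise (coefficient 0.3) — it
emulates the statistical structure of preprocessed BOLD, not raw images:
no motion, no spatial structure, no physiological noise. Passing tests on
this generator demonstrate the machinery is correct and calibrated under
its assumptions; they do not certify performance on real scanner data.

## Simulation scales and what the experiments show

The package's simulation experiments (test suite and `scripts/acceptance.R`)
use sizes chosen to give stable Monte-Carlo answers at desk scale: parameter
recovery on 30 subjects × 150 trials (and × 600 to show error shrinkage);
model recovery on 12 cohorts per generating variant at 10 subjects × 75
trials with a lightened EM control; randomization-test calibration over
dozens of repetitions of 6-subject, 8-channel null cohorts at the full 100
scrambles / 1000 resamples.

Parameter recovery deserves honest framing. The choice probabilities depend
on the parameters only through 25 condition-wise value differences, and
several parameter directions move those differences almost identically
($\eta_0$ against $R^-$ and $C$; the overall value scale against $\sigma$;
$\nu^-$ is informed only through the negative-valence branch, whose weight
is $|R^-|$). The consequence, verified in this package's recovery
experiments, is a soft likelihood *ridge* at the population level: blind
fits reach marginal likelihoods equal to or better than the
truth-initialized fit while their group means sit 0.2–0.6 (transformed
space) away on $\eta_0$, the anticipation rates and $\gamma$, and the
displacement does not shrink with more trials per subject — extra trials pin
each subject's choice curve, not its position along the ridge. What *is*
recovered, tightly and increasingly with data, is the behavioral content of
the fit: the cohort-mean predicted choice probabilities match the generating
ones to RMSE below 0.01 at these sizes. Group means in parameter space
should therefore be read jointly (through the predicted curves), not
coordinate by coordinate. This is a property of the experimental design,
not of the optimizer: the 25-condition grid simply does not separate these
directions.

## Known limitations

* Only the linear boosting ansatz is implemented; a saturating (tanh)
  boosting variant would bound the gain without a hard stability constraint
  but is deliberately out of scope.
* The GLM assumes i.i.d. noise (no prewhitening); drift is handled by the
  DCT basis and autocorrelation enters only the synthetic noise generator.
  The phase-randomization test is the package's answer to autocorrelated
  null structure.
* The no-boost and no-anticipation variants cannot be distinguished from
  choice data in this paradigm (see above); iBIC resolves them by parsimony
  alone.
* Subject-level parameters are softly identified; interpret individual MAPs
  through the group posterior, not in isolation.
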