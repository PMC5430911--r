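---
title: "Modelling prior-by-evidence interplay in intention inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling prior-by-evidence interplay in intention inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intentprior)
library(dplyr)
```

## The problem

When we watch someone act, we infer *why* they act — their intention — by
weighing what the action scene shows (sensory, "visuomotor" evidence)
against what we already expect (priors built from the recent history of
that person's behaviour). The balance between the two shifts: the scarcer
the evidence, the more the prior dominates, and the more abstract the
intention (a superordinate goal, or a social intention such as cooperation),
the stronger the prior's grip.

`intentprior` implements the full computational chain used to study this
trade-off with a two-alternative intention-inference task and ROI-level
fMRI time series, entirely on synthetic data:

1. a **trial-sequence generator** with a biased intention frequency,
2. a **memory-decay Bayesian observer** providing trial-by-trial priors,
3. a **logistic prior-by-evidence choice model** with joint decay-parameter
   fitting,
4. behavioural summaries (**prior-effect scores**, repeated-measures ANOVA),
5. a **parametric GLM** design-matrix builder with serially orthogonalized
   modulators and ROI-level fitting,
6. **PPI** (psychophysiological interaction) regressor construction and
   estimation, and
7. a **bilinear DCM** model space with BIC evidence and random-effects
   Bayesian model selection.

## Task design

A run has an *induction* phase of 36 fully disclosed action sequences
(1880 ms action clips) followed by a *testing* phase of 108 trials using
only the three shortened clip durations (1480, 1560, 1640 ms — evidence
levels 1–3; 1880 ms is level 4). The "likely" intention occurs on 2/3 of
trials. We realize the 2:1 ratio by exact integer allocation (72:36 overall,
24:12 within each testing level), not Bernoulli sampling: fixed counts per
run are what a balanced design implies. The induction phase uses the same
2:1 allocation — it is the phase that *induces* the bias, so it must carry
it. Twelve colour-patch control trials (a count the design leaves open; it
is configurable) are interleaved at random positions.

Each trial is fixation (0.5–2.5 s), preparation (1–1.5 s), action (the
evidence duration), delay (0.5–1 s) and a 1.5 s response window, with all
jitters uniform and trials scheduled back to back. In the social task the
first actor's move is fully visible and the second actor mirrors it
(tit-for-tat) with probability 2/3 — the TFT bias magnitude is unspecified
by the design, so we default it to 2/3 for symmetry with the non-social
bias. The "likely" event in the social task is the mirroring move itself,
and the recorded intention is the second actor's actual move.

```{r}
run <- generate_run(task_config("basic", seed = 1))
count(run$trials, phase)
```

## The memory-decay observer

Before trial $t$ the observer's probability for intention $i$ is

$$
\mathrm{prob}(e_t = i) \;=\; \frac{w_i + 1}{\sum_j (w_j + 1)},
\qquad
w_i \;=\; \sum_{p=1}^{t-1} \alpha^{-p}\,[\,e_{t-p} = i\,],
$$

with $p$ the lag backwards from $t$ and $\alpha \ge 1$ the memory-decay
parameter: $\alpha = 1$ is lossless counting (the ideal observer), larger
$\alpha$ discounts older events. Two implementation notes. First, the
pseudo-count is added once *per intention* in the denominator, so the
probabilities sum to exactly 1 — this is the only normalization under which
the row-stochasticity invariant can hold and be tested. Second, the event
indicator is evaluated at lag $p$ (otherwise the lag weight would multiply
a constant). Priors reset to a flat distribution at each task boundary and
are carried across runs within a task; in the social task the counts are
kept separately per first-actor move, and each trial is evaluated under its
own context.

The "prior" value attached to trial $t$ is the observer's probability of
the intention actually enacted on $t$ (equivalently, of the correct
response) — not the probability of the likely intention; the two coincide
in sign but the enacted-intention convention is the one that enters the
choice model naturally.

One subtlety worth recording: the probability of the most recent event is
*not* monotone in $\alpha$. As $\alpha \to \infty$ all weighted counts
vanish and every probability is pulled to the flat prior by the
pseudo-counts, and mixed histories are non-monotone even without smoothing.
What is true — and what the test suite checks — is a recency-order
property: for $\alpha > 1$, swapping the last two (distinct) events raises
the probability of whichever intention now occupies lag 1, with exact
indifference at $\alpha = 1$.

## The choice model and decay fitting

Correct responses are modelled as

$$
\mathrm{logit}\,P(CR_t = 1) = \beta_0 + \beta_{prior}\,z(prior_t)
 + \beta_{evid}\,z(evid_t) + \beta_{prior\times evid}\,z(prior_t)z(evid_t),
$$

fit by maximum likelihood on z-scored predictors (the interaction is the
product of the standardized terms), with evidence entering as the ordinal
level 1–4, not milliseconds. A negative interaction coefficient is the
behavioural signature of interest: reliance on the prior grows as evidence
shrinks. Perfect separation triggers a ridge-penalized IRLS fallback
(penalty $10^{-4}$ on the slopes) and a flag; flagged coefficients should
not be interpreted.

$\alpha$ is fitted by minimizing the sum of squared residuals between the
observed correct responses and the fitted choice probabilities (a
Brier-type least-squares criterion) over a grid on $[1, 3]$ with step 0.05,
ties broken toward the smaller $\alpha$, refined by golden-section search
(tolerance $10^{-3}$) within the bracketing grid interval. The design gives
no search range or optimizer; the grid-plus-refinement choice makes the
objective curve inspectable and the minimum reproducible.

```{r}
d <- tibble(prior = runif(500, 0.3, 0.8),
            evidence = sample(1:4, 500, TRUE))
zp <- scale(d$prior)[, 1]; ze <- scale(d$evidence)[, 1]
d$correct <- rbinom(500, 1, plogis(0.5 + zp + ze - 0.5 * zp * ze))
tidy(fit_choice_model(d))
```

## Behavioural summaries

The *prior effect* at an evidence level is the percent-correct on
likely-intention trials minus the percent-correct on unlikely ones;
positive values mean responses are pulled toward the biased intention. (The
verbal definition of the subtraction is ambiguous in direction; we fix the
sign so that a stronger pull toward the likely intention is positive, which
is the direction in which the effect is plotted and interpreted.) The
four-level profile pools the induction phase for the very-high level, since
testing trials only use the three shortened durations.

`rm_anova_2x()` runs the classical two-factor within-subject ANOVA (via
`stats::aov` error strata) on a complete balanced table and reports partial
eta squared $SS_e/(SS_e + SS_{err})$; an all-constant table returns $F = 0$
rather than 0/0. Post-hoc comparisons are uncorrected paired t-tests
(Fisher-LSD style), matching the uncorrected post-hoc convention, and
`correlate()` gives the Pearson r/t used to relate per-subject behavioural
and neural estimates.

## Synthetic subjects and BOLD

`simulate_subject()` inverts the behavioural model: generative observer
prior (with a true $\alpha$), z-scoring within session, the logistic
linear predictor, an optional lapse mixture
$p = \mathrm{lapse}/2 + (1-\mathrm{lapse})\,\sigma(\eta)$, and a Bernoulli
draw. `simulate_bold()` produces $y = X\beta + \text{drift} + \varepsilon$
with AR(1) Gaussian noise (default $\rho = 0.3$) — the minimal noise model
that exercises the 128 s high-pass filtering and the optional prewhitening.
The BOLD geometry follows the acquisition this pipeline targets: TR 2.5 s
and 285 usable volumes per run (290 acquired, first 5 discarded).

## The parametric GLM

Per condition, four categorical regressors (preparation and inference
boxcars, a control-trial boxcar, and a motor stick at the button press) and
four parametric modulators: the prior on the preparation phase, and
evidence, prior and their interaction on the inference phase — 16 task
regressors for a two-condition experiment (8 categorical + 8 parametric).
The preparation-phase prior modulator uses the same trace as the
inference-phase one. Modulators are mean-centered within condition before
convolution (the standard parametric-modulation convention), everything is
built at a 0.1 s microtime resolution, convolved with the canonical
double-gamma HRF (peak delay 6 s, undershoot delay 16 s, dispersions 1 s,
undershoot ratio 1/6, peak-normalized; "canonical" fixes no parameter
values, these are the conventional ones), and sampled at the volume times.

The three inference modulators are then *serially orthogonalized* in the
fixed order evidence → prior → interaction: each column is residualized
against its predecessors, so shared variance is attributed to the earlier
regressor and the interaction column is clean of both main effects. The
orthogonalization acts on the convolved, TR-sampled columns, which makes
the orthogonality exact at the level at which the GLM is fit (dot products
below $10^{-8}$, checked against a QR factorization). A 128 s discrete
cosine high-pass basis and arbitrary nuisance columns (e.g.
`expand_motion()`, the second-degree polynomial expansion of motion
parameters) complete the matrix. `fit_glm()` is OLS with closed-form
contrast t statistics and optional one-step Cochrane–Orcutt AR(1)
prewhitening (off by default, since no autocorrelation model is prescribed).

## PPI

A seed region's "physiological" series is deconvolved with the canonical
HRF by ridge-regularized inversion of the convolution operator
($(K'K+\lambda I)^{-1}K'y$, default $\lambda = 10^{-2}$; the original
empirical-Bayes deconvolution is unspecified at this scale), multiplied by
the signed psychological contrast (+1 for inference events of one
condition, −1 for the other, 0 elsewhere), reconvolved and mean-centered.
`estimate_ppi()` then regresses the target on physiological, psychological,
PPI and nuisance terms. With ±1 coding the condition-specific coupling
slopes are $b_{phys} \pm b_{PPI}$, and the slope difference — the PPI
effect proper — is $2 b_{PPI}$.

Two lessons from calibrating this estimator are worth keeping. The task
main-effect regressors must enter as nuisance covariates: without them,
task-evoked variance leaks into the PPI term and the null test rejects far
above its nominal level. And the PPI term only has power when the seed's
trial responses vary: a perfectly stereotyped seed makes the PPI regressor
collinear with the psychological main effect. Our power conditions
therefore draw each trial's inference-input amplitude from U(0.2, 1.8),
modulate the backward mPFC→TPJ coupling by 1.2 (against intrinsic
connections of 0.4), and add BOLD noise of SD 0.3 — under which the sign of
the slope difference is recovered in ≥ 90% of runs, while the
stereotyped-amplitude null stays at its nominal 5% level. Conversely, with
trial-amplitude variability the classical t test on the PPI coefficient is
anticonservative; this is a known caveat of PPI, reproduced here, not a
defect of the implementation.

## The DCM model space

Neural dynamics follow the bilinear form
$\dot z = (A + \sum_j u_j B_j)z + Cu$ over three regions: a preparatory
region (SMA or dACC), mPFC, and TPJ. Five anatomical families remove
connections progressively from a fully connected network to a minimal
prep→mPFC link (the exact family table comes from supplementary material we
treat as unavailable; `enumerate_families()` takes a replacement table):

| family | connections |
|---|---|
| 1 | prep↔mPFC, mPFC↔TPJ, prep↔TPJ |
| 2 | prep↔mPFC, mPFC↔TPJ |
| 3 | prep↔mPFC, mPFC→TPJ |
| 4 | prep→mPFC, mPFC↔TPJ |
| 5 | prep→mPFC |

Within each family, 8 models cross the modulated mPFC–TPJ connection
(forward TPJ→mPFC vs backward mPFC→TPJ) with the modulator set on it (INT;
PE; INT+PE; INT+PE+PE×INT), with the intention type INT always modulating
the forward prep→mPFC connection. The textual description is ambiguous
between several 8-model factorials; this one is encoded as a replaceable
default, and modulation masks are intersected with the family's intrinsic
connections so the `B`-inside-`A` invariant always holds. Driving inputs
are fixed: the preparation input enters the preparatory region, the
inference input enters TPJ.

Integration is fixed-step RK4 (compiled) at 0.1 s by default (0.5 s in the
model-comparison simulations, where the RK4 refinement test shows the
coarser step is accurate to well below the noise level). `fit_dcm_bic()`
estimates the free (nonzero-template) off-diagonal `A`, `B` and `C` entries
by Levenberg–Marquardt least squares on the HRF-convolved prediction, with
the self-decay diagonal fixed at −1 for identifiability, and approximates
the log evidence as $-\tfrac12 \mathrm{BIC}$. This is a deliberate,
documented simplification relative to variational-Bayes DCM with a
haemodynamic state model: at desk scale there is no haemodynamic-parameter
estimation, and BIC preserves the accuracy/complexity trade-off that drives
the model comparison.

Random-effects model selection follows the standard variational Dirichlet
scheme: subject-wise posterior model assignments are iterated against the
Dirichlet concentrations, and exceedance probabilities — the posterior
probability that a model (or family) is the most frequent in the population
— are computed by Monte-Carlo sampling of the fitted Dirichlet. Family
evidences aggregate member models by log-sum-exp minus log family size
(a uniform within-family prior); aggregating evidences rather than
posterior probabilities is a choice we document because the original
procedure does not specify it.

```{r}
fams <- enumerate_families()
length(enumerate_models(fams))
```

## Problem sizes and determinism

All stochastic steps are seeded, and generators save/restore the caller's
RNG state. The simulation studies shipped with the package use sizes chosen
to make each property measurable while keeping a full run of the suite
inexpensive: 50 replicates of n = 5000 trials for decay/coefficient
recovery (grid step 0.05, tolerance ±0.15), 500 null simulations of 200
volumes for PPI calibration, 20 noisy datasets of 100 volumes for the
40-model identification study, 18-subject cohorts for the prior-effect
profile, and $2\times10^5$ Monte-Carlo draws for exceedance probabilities
(checked at ±0.01 against the two-model Beta quadrature).

## What the synthetic data does and does not show

The generator reproduces the statistical structure the analyses assume —
biased stationary event streams, logistic choices, linear HRF convolution,
AR(1) BOLD noise, bilinear neural coupling. Real data violate most of these
in small ways: priors may drift non-stationarily, the HRF varies across
regions and subjects, noise is neither AR(1) nor stationary, and neural
dynamics are not bilinear. Passing recovery tests therefore demonstrates
the *internal consistency* of the pipeline (each stage inverts its own
generative counterpart) and its calibration under its assumptions — not
that the same numbers would be recovered from a scanner. Group-level
quantities from the original 18-participant study (F statistics, effect
sizes, behavioural–neural correlations, the 75%/71% winning-model
exceedance probabilities) depend on real between-subject variability and
are deliberately out of scope; the package instead checks the *pattern*:
prior effects largest at the lowest evidence, backward- over
forward-modulation models selected when backward modulation generated the
data, and PPI slope differences whose sign agrees with the generative
coupling.

## Known limitations

* BIC-based DCM evidence ignores haemodynamic-parameter uncertainty;
  absolute evidences are not comparable to variational free energies.
* The deconvolution grid defaults to the sampling TR; sub-TR neural
  structure is not recovered.
* The classical PPI t test is anticonservative under strong trial-amplitude
  variability (see above).
* `rm_anova_2x()` requires complete balanced tables and does not apply
  sphericity corrections.
* The observer assumes a fixed intention alphabet of two alternatives per
  task.
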