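# intentprior

Simulation and analysis of the prior-by-evidence trade-off in intention
inference.

When observers judge the intention behind an action (two alternatives:
transport vs rotate, one cube pattern vs another, cooperate vs defect),
their choices mix the visuomotor evidence in the action clip with prior
expectations learned from the recent trial history. `intentprior`
implements the full computational chain used to study that trade-off
behaviourally and with ROI-level fMRI — entirely on synthetic data, so
every stage is testable end to end:

* **Task generator** — induction/testing runs with an exact 2:1
  likely:unlikely intention allocation, four action durations
  (1480–1880 ms) coding evidence levels, tit-for-tat structure in the
  social task, BIDS-style `events.tsv` export.
* **Memory-decay Bayesian observer** — trial-by-trial priors
  `prob(e_t = i) = (w_i + 1) / Σ_j (w_j + 1)` with lag weights `α^(-p)`;
  `α = 1` is the lossless ideal observer, `α > 1` discounts the past.
* **Choice model** — `logit P(correct) = β0 + β_prior z(prior) +
  β_evid z(evid) + β_prior×evid z(prior)z(evid)`, with `α` fitted by a
  least-squares (Brier) criterion over a grid plus golden-section
  refinement.
* **Behavioural summaries** — prior-effect scores (%correct likely −
  %correct unlikely per evidence level), two-factor repeated-measures
  ANOVA with partial η², Fisher-style post-hocs, between-subject
  correlations.
* **Parametric GLM** — per condition: preparation/inference/control/motor
  categorical regressors plus prior, evidence and prior×evidence
  modulators, mean-centered, HRF-convolved at microtime and *serially
  orthogonalized* (evidence → prior → interaction); 16 task regressors for
  a two-condition experiment; 128 s DCT high-pass; OLS with contrast t
  statistics and optional AR(1) prewhitening.
* **PPI** — ridge deconvolution of the seed series, multiplication by the
  signed psychological contrast, reconvolution; condition slopes
  `b_phys ± b_PPI` and their difference as the interaction effect.
* **DCM + BMS** — a 5-family × 8-model bilinear space over
  {preparatory region, mPFC, TPJ} with modulators INT, PE, PE×INT;
  compiled RK4 integration, Levenberg–Marquardt fitting with BIC-based
  evidence, and random-effects Bayesian model selection with Monte-Carlo
  exceedance probabilities.

See `vignettes/intention-inference.Rmd` for the models, assumptions,
default parameters and design choices.

## Worked example

Simulate one subject on a basic-intention run and fit the observer + choice
model:

```r
library(intentprior)

run  <- generate_run(task_config("basic", seed = 42))
subj <- simulate_subject(
  run,
  subject_params(alpha_true = 1.3, beta_true = c(0.5, 1, 1, -0.5)),
  seed = 7
)
fit <- fit_alpha(subj$intention, subj$evidence_level, subj$correct,
                 grid = seq(1, 2, by = 0.05))
fit
#> <observer_fit> alpha_hat = 1.7872 (objective = 20.1729)
#> # A tibble: 4 × 5
#>   term             estimate std.error statistic    p.value
#>   <chr>               <dbl>     <dbl>     <dbl>      <dbl>
#> 1 beta0               0.565     0.226      2.50 0.0126
#> 2 beta_prior          0.986     0.251      3.93 0.0000855
#> 3 beta_evidence       1.21      0.272      4.44 0.00000904
#> 4 beta_interaction   -0.960     0.312     -3.08 0.00208
```

The four coefficients sit near the generating values (0.5, 1, 1, −0.5):
the subject uses both prior and evidence, and the negative interaction
means the prior matters most when evidence is weakest. (`alpha_hat` from a
single 144-trial run is imprecise by nature; the package's recovery study
uses 5000-trial simulations, where it lands within ±0.15 of the truth.)
The same data summarised as prior-effect scores:

```r
prior_effect(subj)
#> # A tibble: 4 × 7
#>   evidence_level n_likely n_unlikely pct_correct_likely pct_correct_unlikely
#>            <int>    <int>      <int>              <dbl>                <dbl>
#> 1              1       24         12               45.8                 8.33
#> 2              2       24         12               79.2                25
#> 3              3       24         12               83.3                83.3
#> 4              4       24         12               91.7                58.3
#> # ℹ 2 more variables: prior_effect <dbl>, missing_cell <lgl>
```

Accuracy rises with evidence, and the likely-intention advantage (the
prior effect) is largest at the lowest evidence levels — the behavioural
signature the whole pipeline is built around. `plot_prior_effect()`,
`autoplot()` methods and `tidy()`/`glance()` accessors are available for
every result type.

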