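---
title: "Sequential CART synthesis of athlete-monitoring panels: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential CART synthesis of athlete-monitoring panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Longitudinal athlete-monitoring panels — one row per player-week carrying a
weekly acute training load (AL), a multi-week chronic load (CL), and a binary
injury indicator — are rarely shareable: loads and injury timings can
re-identify professional athletes. A data-driven synthetic panel replaces the
sensitive columns with model-generated values while trying to preserve (a) the
joint distribution of the variables (global utility) and (b) the answer a
specific analysis gives (specific utility). This package implements the full
loop: a calibrated panel simulator, sequential tree-based synthesis under
named predictor-specification conditions, propensity-score global utility,
and replication of a marginal injury regression as the specific-utility probe.

## Data model and feature engineering

A `MonitoringPanel` is a long-format data frame with columns `PlayerID`,
`WeekID` (1-based weeks), `AcuteLoad` (arbitrary load units, non-negative),
`ChronicLoad` and `Injury` (0/1), sorted by (player, week) with unique keys.

Chronic load is the *uncoupled* trailing mean of acute load: with the default
4-week block, `CL[t] = mean(AL[t-1], AL[t-2], AL[t-3])` — the acute week is
excluded from its own chronic window, so the ratio `ACWR = AL / CL` does not
contain `AL` on both sides. The exact window of an "uncoupled 4-week chronic
load" is genuinely ambiguous (3 prior weeks, 4 prior weeks, or 4 weeks
including the current one); we fixed the 4-week-block-excluding-the-acute-week
reading as the default and left `block_weeks` and `uncoupled` configurable.
Weeks without a full window get a missing CL rather than a partial-window
value: fabricating early-season chronic loads would silently change the row
set every downstream model sees. `ACWR` is missing wherever CL is missing or
zero, keeping regression design matrices finite.

Lag features `AL_Lag1..3`, `CL_Lag1..3` are per-player shifts; the first `k`
weeks of each player are missing by construction.

## The panel simulator

The original monitoring dataset the pipeline is designed around is not
publicly deposited, so the package ships a generator
(`generate_fixture()`) whose defaults define the study conditions used by the
tests and the acceptance script. It is deliberately the *minimal* structure
the downstream analyses exploit:

* **Loads.** `AL[p,t] = max(0, mu + u[p] + phi * (AL[p,t-1] - mu - u[p]) + e[p,t])`,
  a player-level random intercept `u[p] ~ N(0, sd_player)` plus a stationary
  AR(1) within player. Defaults: `mu_load = 2000` load units (a realistic
  weekly session-RPE-scale total), `sd_player = 300` (moderate between-player
  heterogeneity, ~15% of the mean), `ar_phi = 0.5` (week-to-week persistence
  strong enough that lag predictors matter), `sd_week = 350`.
* **Chronic load** is derived from the simulated AL with the panel rule, so
  the fixture obeys the same coupling identity the `"calculated"` synthesis
  scenario enforces.
* **Injury.** `Injury[p,t] ~ Bernoulli(plogis(beta0 + beta1 * ACWR[p,t] + b[p]))`
  with frailty `b[p] ~ N(0, sd_frailty)`, `sd_frailty = 0.3` (mild
  within-player clustering, matching the exchangeable working-correlation
  assumption of the analysis model). `beta1 = 0.90` on the log-odds scale is
  the published effect size the analysis replicates. `beta0 = -4.147` was
  calibrated once, via `calibrate_baseline_risk()`, so the defaults give a
  marginal injury rate of ~0.04 per player-week on ACWR-complete rows — the
  rate is not reported for the original data, so 0.04 is a stated assumption
  typical of weekly time-loss injury rates in professional football. Weeks
  with undefined ACWR are forced injury-free so the injury model is estimable
  on exactly the ACWR-complete rows.
* **Feedback.** `post_injury_multiplier` scales the week-after-injury load
  (injuries reduce subsequent training); it defaults to 1 (off) because the
  analysis model the pipeline replicates ignores this pathway.

Each player consumes a deterministically derived sub-seed, so a panel is
reproducible from its seed and grows consistently with `n_players`.

**What the generator does not emulate:** seasonal periodicity, match
congestion, skewed or multimodal load distributions, injury severity, and any
injury→load feedback by default. Consequences are discussed under
*Limitations* below: tests passing on this fixture demonstrate the pipeline's
correctness and the metrics' calibration, not that real monitoring data would
score the same utility values.

## The CART synthesis engine

Each synthesized variable is modelled by a classification or regression tree
(`fit_tree()`) grown by greedy binary recursive partitioning:

* impurity is the within-node sum of squared deviations (continuous) or the
  Gini index (categorical);
* numeric predictors are scanned exhaustively over every distinct threshold
  using cumulative-sum identities;
* categorical predictors are ordered by mean response (continuous) or event
  rate (binary) and scanned as ordered — the classical exact shortcut, which
  makes the 34-level `PlayerID` predictor feasible;
* splitting stops when `min_leaf` (5), `min_split` (10), `complexity`
  (1e-8 of the root impurity) or the optional depth cap binds — the
  conventional defaults of tree-based synthesis engines;
* ties between equally good splits go to the earlier predictor, then the
  smaller threshold, making fits fully deterministic.

Generation (`synthesize_variable()`) routes each row to its leaf and draws
one *observed donor value* uniformly with replacement — no smoothing, so
every synthetic value is a value that occurs in the training column.
`proper = TRUE` bootstrap-resamples each leaf's donor pool first (proper
synthesis); the improper direct draw is the default, matching standard
practice. A category unseen at a split routes to the side that held the
majority of that node's training records, so prediction is total.

## Sequential synthesis plans

A `synthesis_plan` is an ordered visit sequence of per-variable
specifications: `fixed` (copied, usable as a predictor, never synthesized),
`cart`, `random_sample` (i.i.d. draws from the observed marginal), or
`derived` (deterministic rule). Each CART predictor carries a source:
`original` predictors feed observed values at generation time; `synthetic`
predictors feed the values generated earlier in the sequence. Model *fitting*
always uses observed values; the original/synthetic distinction only governs
generation — this directly encodes the starred-variable convention of the
study design.

`build_condition()` provides the seven named conditions (`base`, `base_week`,
`time_lag_1wk`, `time_lag_3wks`, `time_lag_injury`, `injury_time_lag`,
`no_playerid`) crossed with two chronic-load scenarios: `"independent"`
(CL synthesized by CART conditional on the synthetic AL) and `"calculated"`
(CL recomputed from the synthetic AL by the uncoupled trailing-mean rule, so
the deterministic AL→CL coupling holds exactly in every output).

Two row-handling rules the plans need on panels with lag features:

* rows whose generation-time predictors are missing (each player's first
  weeks) are excluded from tree fitting and receive marginal draws from the
  observed response over those same row positions, keeping output shape equal
  to input;
* rows whose *observed response* is missing (early-window CL) stay missing in
  the synthetic panel, so original and synthetic analyses drop identical rows.

Order among fixed variables is irrelevant by construction (they are never
refit), so the plans keep the documented visit order without relying on it.

## Global utility

`global_utility()` stacks the original and synthetic panels with an indicator
(1 = synthetic), fits a main-effects logistic propensity model, and reports:

* `pmse = mean((p_i - c)^2)` with `c` the synthetic fraction;
* `s_pmse = pmse / ((k - 1) (1 - c)^2 c / N)` — pMSE divided by its
  expectation under the null that the synthetic data were drawn from a
  correctly specified model *fitted to the original sample* (`k` counts
  fitted parameters including the intercept, after zero-variance predictors
  are dropped);
* `po50` = percentage of stacked rows classified correctly at the 0.5
  threshold, minus 50, with ties counted half-correct.

Two conventions deserve emphasis, because they are easy to get wrong:

* The denominator of `s_pmse` is the *fitted-model* null. A synthetic panel
  built by row-bootstrapping the original scores ≈ 1 (this is asserted in the
  test suite). Two *independent* draws from the same population score
  ≈ 1/(1−c) even for i.i.d. rows, and far more when rows are clustered —
  independent panels are not the null this standardization is defined
  against.
* The default propensity design uses the numeric core variables (`WeekID`,
  `AcuteLoad`, `ChronicLoad`, `Injury`). `PlayerID` dummies can be added with
  `include_player = TRUE`, but because the synthetic panels copy `PlayerID`
  verbatim, those dummies compare row *counts* (identical by construction)
  and contribute ~0 signal each while inflating `k`, deflating `s_pmse`. A
  permutation-null z-score is available via
  `standardization = "permutation"`; the expected-null ratio remains the
  default and every report records which convention produced it.

On the shipped fixture, CART conditioning captures essentially all of the
structure a main-effects propensity model can see, so replicate-mean `s_pmse`
sits *below* 1 (donor resampling within cells varies less than a fresh model
draw). Values near 1 on real data indicate residual structure the synthesis
missed; this gap is a property of the fixture's simplicity, and is the main
caveat when reading the fixture-based utility numbers as a stand-in for
real-data behaviour.

## Specific utility

`fit_injury_gee()` replicates the original analysis: a marginal logistic
model `logit P(Injury) = b0 + b1 * ACWR`, estimated by GEE with exchangeable
working correlation clustered on `PlayerID` and robust (sandwich) standard
errors. The GEE solver is implemented in the package (closed-form
exchangeable inverse per cluster, moment estimators for the scale and the
common correlation); the test suite pins it against an independent reference
implementation to 1e-7 on a frozen dataset, against ML logistic regression in
the independence limit, and against a clustered-sandwich covariance oracle.
The ACWR enters untransformed by default ("log odds model" is read as the
logit link, not a log-transformed regressor); `acwr_transform = "log"` is
available. The published single-predictor model is the one implemented; no
additional covariates are recoverable from the source analysis.

`specific_utility_mae()` reports the mean absolute error of the replicated
estimate, standard error and p-value across replicate syntheses against the
reference fit, excluding (and counting) failed fits rather than imputing
them. `observation_mae()` compares aligned player-weeks value by value, and
`adjacent_pair_consistency()` applies any two-panel metric along consecutive
replicate pairs to quantify the variability of the generation process itself.

## The study harness

`run_study()` crosses conditions with scenarios, derives one seed per cell
and per replicate from the master seed (so runs are exactly reproducible and
trivially parallelizable), guards each replicate with an elapsed-time cap
(default 60 s; conditions that synthesize `Injury` by CART late in a long
visit sequence are known to be pathologically slow on data with many-level
factors, and a timed-out replicate is recorded as a failure rather than
stalling the study), and writes replicate tables, a Mean (SD) summary, and a
log. `make_release_sheet()` emits the documentation that should accompany any
released synthetic panel — variables, methods, predictors with sources,
hyperparameters, scenario, utility summary, limitations — plus a
machine-readable YAML block that `read_release_sheet_plan()` round-trips into
the exact plan.

Desk-scale defaults (50 replicates; the analysis scripts and the acceptance
script use 34 × 120 panels, 50–100 replicates, and 200 players for the
recovery study) keep each analysis in the minutes range on one CPU; the
production scale of 500 replicates is one argument away.

## Numerical and degenerate-input choices

* Chronic-load windows and lags never cross player boundaries; windows are
  positional within each player's sorted weeks.
* `ACWR` at `CL = 0` or missing CL is missing, never infinite.
* A constant response yields a root-only tree, not an error; an 8-row node
  cannot split under `min_leaf = 5` by construction.
* Propensity fits that separate (probabilities numerically 0/1 or
  non-convergence) fall back to a weakly ridge-penalized logistic fit
  (`lambda = 0.01`, intercept unpenalized) and flag the report.
* GEE working-correlation estimates are clipped to the valid exchangeable
  range; variance weights are floored at 1e-12 to keep Pearson residuals
  finite under extreme fitted probabilities.
* `calibrate_baseline_risk()` uses common random numbers across bisection
  evaluations, so the simulated rate is monotone in the intercept and the
  search is well-posed; the no-effect no-frailty case returns the closed-form
  logit exactly.

## Limitations

* The fixture validates machinery, not real-data utility: its conditional
  structure is simple enough that CART captures it, so global-utility ratios
  sit below the ≈1 regime reported for real monitoring data, and the
  degradation of GEE replication as temporal predictors are added — driven on
  real data by lag splits diluting the load–injury association — is not
  reproduced at the fixture's effect sizes (its load-fidelity counterpart,
  lower observation-level MAE under lag conditioning, is).
* Only the sequential tree-based generation framework is implemented —
  no parametric methods, joint generative models, or disclosure-risk
  quantification.
* The ACWR itself is a ratio statistic with known conceptual problems; the
  package replicates the published analysis rather than endorsing the
  exposure definition.
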