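---
title: "Predicting prey-capture attempts from time-depth data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting prey-capture attempts from time-depth data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divebuzz)
```

## The problem

Echolocating odontocetes such as sperm whales emit *buzzes* — rapid click
trains during the terminal phase of prey pursuit — that are the standard
acoustic proxy for prey-capture attempts (PCAs). Buzzes can only be observed
with expensive multi-sensor acoustic tags. Time-depth recorders (TDRs), by
contrast, are cheap and ubiquitous but record nothing except depth at
(typically) 1 Hz. `divebuzz` implements a pipeline that learns, from a
deployment where both kinds of information are available, how buzz counts
relate to features of the 1 Hz depth trace alone, so that PCA rates can then
be estimated from plain TDR records.

The pipeline has five stages:

1. **Decimate** high-rate depth data (20–25 Hz) to 1 Hz
   (`downsample_depth()`), keeping the first sample per second — TDRs log
   instantaneous pressure, so decimation rather than block averaging is the
   faithful emulation.
2. **Detect dives and label phases** (`detect_dives()`, `label_phases()`).
   A candidate dive is a maximal run of samples deeper than 25 m; a
   *foraging* dive additionally contains at least one buzz. The first dive
   of every individual is excluded (tagging disturbance). Phases follow the
   sign of the 1 Hz depth rate: descent is the maximal initial run of
   positive rates, ascent the maximal final run of negative rates, the
   bottom phase whatever lies between.
3. **Segment** each dive into non-overlapping windows of 30, 60, 180 or
   300 s from the dive's first sample, discarding the trailing partial
   window (`segment_dives()`). A buzz belongs to the half-open window
   containing its start time; a segment's phase is the phase of its first
   second.
4. **Compute metrics and fit** (`segment_metrics()`, `buzz_glmm()`,
   `backward_select()`): a Poisson GLMM of buzz count per segment with a
   per-individual random intercept, reduced by backward AIC selection.
5. **Evaluate** by leave-individuals-out cross-validation
   (`make_splits()`, `sensitivity_analysis()`,
   `bottom_phase_comparison()`, `dive_level_accounting()`).

## The model

For segment $j$ of individual $i$, with buzz count $y_{ij}$ and standardized
segment metrics $x_{ij}$,

$$y_{ij} \sim \text{Poisson}(\lambda_{ij}), \qquad
  \log \lambda_{ij} = \beta_0 + b_i + \mathbf{x}_{ij}^\top \boldsymbol\beta,
  \qquad b_i \sim N(0, \sigma^2_\alpha).$$

Estimation uses the Laplace approximation (`lme4::glmer`); Wald $z$ and $p$
values are reported per coefficient. Predictors are z-scored with
training-set statistics before fitting. This matters for two reasons: the
metrics live on wildly different scales (metres, m²/s², counts), and
coefficients only become comparable across metrics — and across fits — on a
common scale. The standardization record is stored in the fitted object and
reapplied verbatim to any new data, so a test set shifted relative to
training retains its shift after transformation.

Two degenerate situations collapse to an ordinary Poisson regression with
$\sigma^2_\alpha = 0$: a single grouping level (the variance is
unidentifiable) and a constant response (the mixed likelihood has its
optimum on the boundary and the PIRLS inner loop cannot iterate). Both are
handled explicitly; the single-group fit is contractually required to match
an independent iteratively reweighted least squares Poisson fit to within
$10^{-3}$ relative, which the test suite enforces.

### Variance explained

Marginal and conditional $R^2$ follow the Nakagawa–Schielzeth
decomposition for a log-link Poisson model:
$R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_\alpha + \sigma^2_d)$ and
$R^2_c = (\sigma^2_f + \sigma^2_\alpha) / (\sigma^2_f + \sigma^2_\alpha +
\sigma^2_d)$, with $\sigma^2_f$ the variance of the fixed-effect linear
predictor. The observation-level variance uses the log-normal
approximation $\sigma^2_d = \ln(1 + 1/\bar\lambda)$ with $\bar\lambda =
\exp(\beta_0 + \sigma^2_\alpha/2)$ by default; the trigamma variant
$\psi_1(\bar\lambda)$ is available via `r_squared(m, method = "trigamma")`.
The log-normal form is the default because it is the variant most commonly
reported alongside mixed-model $R^2$ in the ecological literature.

### Model selection

`backward_select()` repeatedly removes the predictor whose removal lowers
AIC the most and stops when no removal lowers AIC — selection by lowest
AIC, nothing else. A property of this stopping rule worth knowing: a
predictor with no true effect survives whenever its deviance contribution
exceeds 2, which for a 1-df Wald/likelihood statistic happens with
probability $P(\chi^2_1 > 2) \approx 0.16$ regardless of sample size. So
pure-noise predictors are eliminated in roughly 84% of replicate data sets,
not almost always; our selection-consistency test measures exactly this
rate. Users wanting stricter parsimony can re-screen the selected set by
the reported $p$ values, as the sensitivity analysis's significance tally
does.

## The dive metrics

Sixteen segment-level metrics are computed per segment
(`compute_metrics()`; names via `metric_names()`): average, maximum and
variance of depth; absolute start-to-end depth difference; fraction of
time deeper than 60/70/80/90% of the parent dive's maximum depth; average
and variance of per-step vertical velocity; average and variance of
vertical acceleration; inflection, wiggle and steady-point counts; and
vertical sinuosity. Numerical conventions that had to be pinned down:

* **Vertical velocity** is the signed 1 Hz first difference; the sign
  carries descent/ascent information and the variance is sensitive to it.
  An absolute-value variant sits behind `velocity = "absolute"` for
  sensitivity checks. **Vertical acceleration** is the *absolute*
  difference of consecutive velocities.
* **Variances** use the sample (n−1) denominator throughout; with 30–300
  samples per segment the choice is immaterial, but the oracle tests need
  it fixed.
* **Steady points** compare consecutive depths after quantization to 0.1 m
  (typical TDR resolution); exact floating-point equality on simulated
  depths would be meaningless.
* **Wiggles** are inflections differing by more than 20 m in depth from the
  *immediately preceding* inflection within the same segment; the first
  inflection of a segment can never be a wiggle.
* **Sinuosity** is $|d_\text{end} - d_\text{start}| / \sum_t |\Delta d_t|$,
  defined as 1 for an all-constant segment (a degenerate straight path),
  keeping the ratio total on $[0, 1]$.
* **Phase reversals**: a contrary-rate episode of at most 10 s (the
  configurable `reversal_tolerance_s`) is absorbed into a descent or ascent
  only when the phase then *resumes for longer than the tolerance*. The
  second clause is what stops a jittery bottom phase — whose
  same-direction runs are themselves short — from being swallowed by the
  descent.

Collinearity screening (`screen_collinearity()`) drops, from every pair
with $|r| \ge 0.7$, the metric ranked lower in an explicit ecological
priority list (`default_metric_priority()`), processed greedily in priority
order so the retained set is deterministic.

## The synthetic-data generator

Real tag deployments of this kind are not publicly deposited, so the
package carries a first-class, seeded generator (`sim_config()`,
`simulate_deployment()`) whose defaults encode the study conditions the
pipeline is meant for: 12 individuals; Poisson-distributed dives per
individual with mean 9; bottom depths drawn uniformly on 500–900 m;
descent and ascent speeds drawn per dive from truncated normals
$1.35 \pm 0.21$ and $1.60 \pm 0.19$ m s⁻¹; bottom phases of 1200–2100 s
simulated as a reflected random walk (1 m per-second SD) within the
configured depth band; surface intervals of at least 60 s with ±0.5 m
jitter to exercise the 25 m threshold; and buzz durations of 5–10 s.

Buzz counts are generated at the model's own scale: each dive's
deeper-than-25 m samples are partitioned into complete 180 s windows (the
best-performing segment duration; the trailing partial window receives no
buzzes), the window's average depth, depth variance and vertical-velocity
variance are standardized with deployment-wide statistics computed before
any draw, and the count is drawn from the log-link Poisson model with true
coefficients $(\beta_0, \beta_{\bar d}, \beta_{s^2_d}, \beta_{s^2_v}) =
(-0.8, 0.955, -0.356, 0.187)$ and random-intercept SD 0.2. The slope
values are the field-reported magnitudes for the 180 s scale with their
characteristic signs (deeper segments buzz more, high depth variance marks
transit, high velocity variance marks pursuit); the intercept was
calibrated once, by simulation, to yield about 12 buzzes per dive — the
reported mean rate — and then frozen. Buzz events are placed uniformly and
non-overlapping within their window, so segment bookkeeping is exactly
conservative.

What the generator deliberately does not emulate: overdispersed
dive-per-individual counts (a Poisson draw understates the real
between-individual spread), any explicit within-dive phase prior on buzz
timing (bottom-phase concentration emerges only through the
depth-dependent covariates), depth sensor drift, and 3-D movement. Passing
tests on these simulations therefore demonstrate the statistical machinery
— detection, bookkeeping, estimation, selection, validation — under the
assumed generative model, not the ecological fidelity of any particular
coefficient for wild animals.

Because generation windows and processed segments share the same grid, the
parameter-recovery harness fits on *all* dives (`drop_first = FALSE`,
`foraging_only = FALSE`). Restricting to foraging dives conditions on the
response (a dive is "foraging" because it contains a buzz) and legitimately
inflates the intercept; that bias belongs to the analysis design, not the
estimator, so the recovery contract is evaluated without the filter.

## Cross-validated evaluation

Each of the (by default 100) runs draws 8 of 12 individuals for training
and evaluates on the 4 held out, pooled. Held-out individuals have no
estimated random intercept, so predictions use the population level
$b = 0$ — the honest prediction for an unseen animal. Segment-level
presence is scored as $p = 1 - e^{-\hat\lambda}$, the model-implied
probability of at least one buzz. AUC comes from the rank (Mann–Whitney)
identity with midrank ties, verified in the tests against both an
exhaustive pairwise loop and pROC. The paper-style single operating point
for sensitivity/specificity/precision requires a threshold rule the source
material does not name; the default is Youden's J maximized on the
*training* predictions (a fixed 0.5 probability threshold is available via
`rule = "fixed"`), and the threshold used is recorded per run. Runs whose
fit fails, or whose test labels are single-class (AUC undefined), are
excluded from the medians and counted.

Per-dive accounting (`dive_level_accounting()`) sums observed and rounded
predicted counts over each dive's complete segments; the percentage
difference uses the observed total as denominator and is reported missing
for dives with zero observed buzzes. Rounding is banker's rounding (R's
`round()`), fixed so that "exact prediction" tallies are reproducible.

The bottom-phase comparison refits the identical pipeline on
bottom-labelled segments only, under the *same* split plans, so the paired
reports are directly comparable run by run. When buzzes concentrate in the
bottom phase, restricting to it removes most true absences; single-class
test sets then become common and specificity collapses — the qualitative
behaviour the all-data/bottom-only contrast is designed to expose.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit integer seed, and the pipeline
(`run_pipeline()`) derives all stage seeds from one master seed; reruns are
byte-identical, which the test suite asserts on the report files. The test
suite exercises the full study scale where a property demands it (40
replicate deployments of 12 individuals for coefficient recovery; 100
cross-validation runs for the null AUC calibration) and smaller seeded
deployments (5–8 individuals, shorter bottom phases) where only the
bookkeeping or plumbing is at stake.

## Known limitations

* AIC-stopped backward selection retains spurious predictors at the
  $\approx 16\%$ χ²-tail rate discussed above; it reproduces the reference
  procedure, not an oracle selector.
* The Poisson model carries no overdispersion, zero-inflation or random
  slopes — deliberately, matching the reference analysis; real buzz counts
  may need them.
* Phase labelling is rule-based on 1 Hz rates; dives with pathological
  profiles (e.g. flat-topped with long mid-dive plateaus at the tolerance
  boundary) can shift phase boundaries by up to the tolerance.
* `buzz_glmm` standardizes with training statistics; applying a model to a
  population diving at systematically different depths extrapolates on the
  standardized scale and should be done with care.
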