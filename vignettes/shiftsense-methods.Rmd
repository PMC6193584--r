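---
title: "Sensor-based nursing workload: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensor-based nursing workload: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

shiftsense analyses how the *work processes* of critical-care nurses —
where they are, how they move, how and where they speak, how noisy and warm
their surroundings are — relate to how mentally and physically exerting they
perceive their work to be. The measurement setting is a surgical intensive
care unit instrumented with stationary sensor badges in patient rooms,
nursing stations and service areas, with each nurse wearing a badge that
resolves zone-level location, speech features and accelerometry. Perceived
mental exertion (ME) and physical exertion (PE) are self-rated on the Borg
6–20 scale once per four-hour shift segment, and shift-level *task demands*
(patient counts, sitters, assistant presence, counts of patients needing
specific interventions such as an insulin drip) are recorded per shift.

The package implements the full analysis chain as reusable, tested
components:

1. a **synthetic study generator** with known ground truth,
2. **feature extraction** from raw event streams,
3. **elastic-net screening** of features and pairwise interactions,
4. a **staged two-level mixed-model sequence** with its diagnostics, and
5. a **pipeline orchestrator** with file-based ingest and reporting.

## The data model

A *segment* is a four-hour block of one 12-hour day shift; segments are
nested in shifts, and shifts are the grouping level for all multilevel
modelling. The analysis table has one row per rated segment: identifier
columns (`shift_id`, `segment_index`), the sensor features (Level 1),
the shift's task demands (Level 2, constant within shift), and the two Borg
ratings `me` and `pe`.

## Work-process features

`extract_all()` computes the feature catalogue defined in
`feature_registry()` — around thirty features across seven categories
(location, accelerometer, environmental noise, speaking, posture, walking,
temperature). The registry is data-driven: each feature carries an internal
name, a report label, and a category, so the catalogue can be extended
without touching extraction code. Two features deserve their definitions
spelled out.

**Burstiness.** For an ordered set of event times with inter-event gaps
having mean $\mu$ and sample standard deviation $\sigma$ (the $n-1$
denominator, fixed for reproducibility),

$$B = \frac{\sigma - \mu}{\sigma + \mu} \in [-1, 1].$$

$B = -1$ for perfectly periodic events, $B \approx 0$ for Poisson-like
events, and $B \to 1$ for extremely clumped activity. Burstiness of
*speaking* uses speech-episode start times (episodes are maximal runs of
speaking frames); burstiness of *transitions* uses the times of
distinct-zone location changes. With fewer than three events (two gaps) the
statistic is undefined and propagates as a missing value.

**Transition entropy.** The sequence of occupied zones is first merged over
consecutive repeats (fragmentation artefacts), then consecutive pairs
$a \to b$ are tabulated and

$$H = -\sum_{a \to b} p(a \to b)\, \log_2 p(a \to b)$$

in bits; $H = 0$ when the segment has no transition, and $H$ is bounded by
$\log_2$ of the number of distinct observed pairs. "Time series of physical
locations" admits several readings; the pair-distribution entropy is the
standard movement-predictability reading and the one implemented here.

Other conventions: *main work areas* are patient rooms, nursing stations
and service areas; "outside main work areas" is their complement (halls,
break and locker rooms), which carries no stationary sensors. Ambient
features condition on both the sensor's zone class and the nurse's presence
in that class. Time features are fractions of the segment, except walking
times, which are seconds; after grand-mean centring and scaling the unit
choice does not affect the model fits. The walking classifier is a
configurable accelerometer band (defaults 0.15–0.60 g, minimum run 2 s) —
no validated gait classifier is claimed, so the band is explicit and
overridable in `feature_params()`. Missing-feature policy: undefined
burstiness and empty conditioned means stay missing, and segments missing a
modelled feature are dropped listwise at modelling with logged counts.

## Feature screening

`screen_interactions()` runs the two-phase screen that precedes modelling.
The elastic net minimises

$$\frac{1}{2n}\lVert y - X\beta \rVert_2^2 +
  \lambda\left(\alpha \lVert\beta\rVert_1 +
  \frac{1-\alpha}{2}\lVert\beta\rVert_2^2\right)$$

by cyclic coordinate descent with warm starts down a 100-point log-spaced
$\lambda$ grid (implemented in C++ with covariance updates and an active
set; the test suite cross-checks it against an independent solver and
against the closed forms for orthonormal, ridge and unpenalised designs).
Defaults are $\alpha = 0.9$ — weighting the lasso heavily while keeping
enough ridge to tolerate correlated features — and 10-fold cross-validation
with a seeded fold assignment.

Stage one fits the main-effects elastic net and keeps everything non-zero
at a *lenient* penalty: the smallest $\lambda$ whose cross-validation error
is within one standard error of the minimum — the least-shrinkage end of
the near-optimal plateau — bounded so the surviving support is at most
about twice the size of the CV-optimal model. Leniency is deliberate:
screening ignores the clustering of segments within shifts, so it should
err towards keeping predictors and let the clustered models prune. The
support bound exists because a flat CV curve (as under a pure-noise
response) would otherwise place the whole pool inside the one-SE band;
bounding leniency *relative to the optimum* keeps "lenient" meaningful. Stage two adds all pairwise
products among the survivors and selects at `lambda_min`; because products
are only formed between survivors and retained products pull their parents
forward, the candidate set satisfies strong hierarchy by construction. A
grouped-hierarchy interaction learner would be an alternative here; the
two-stage product screen was chosen because it is transparent, testable
against planted-interaction simulations, and its excess retentions are
pruned by the downstream backward elimination anyway.

## The staged multilevel model sequence

`run_model_sequence()` fits, per response, the five-stage sequence of
two-level linear mixed models with shift random intercepts, estimated by
maximum likelihood (ML rather than REML because stages differing in fixed
effects are compared by likelihood-ratio tests; REML is available for
single-model use but refused in `lr_test()`):

* **M0** — intercept only, against a pooled no-grouping OLS null
  (likelihood ratio, 1 df). The intraclass correlation
  $\mathrm{ICC} = \sigma^2_{u0} / (\sigma^2_{u0} + \sigma^2_e)$ and the
  group-mean reliability
  $\frac{1}{G}\sum_j \sigma^2_{u0} / (\sigma^2_{u0} + \sigma^2_e / n_j)$
  are computed here.
* **M1** — all Level-1 candidates enter and are backward-eliminated: the
  single least-significant droppable term with $p \ge 0.05$ is removed and
  the model refitted, repeatedly. A main effect is not droppable while a
  retained product contains it (strong hierarchy) or while it carries a
  random slope; ties break to the larger p, then lexicographically.
* **M2** — Level-2 task demands enter and are eliminated among themselves.
* **M3** — random slopes are tried one candidate at a time over *all*
  Level-1 candidates (not just fixed-effect survivors — a feature whose
  average effect is null can still vary by shift); a slope is accepted when
  its likelihood-ratio test passes 0.05. The test uses the naive
  $\chi^2$ with df equal to the parameters added (slope variance +
  intercept–slope covariance, +1 if the feature's fixed effect is newly
  added); a boundary-corrected halved p-value is available but off by
  default. After slope acceptance, fixed terms that have lost significance
  are re-eliminated (Level-2 terms and slope carriers retained).
* **M4** — cross-level products between task demands and the retained
  random-slope features are screened one at a time at 0.05, and the
  survivors enter jointly with their Level-2 parents and are
  backward-eliminated. A cross-level interaction explains slope
  *variation*, so without a retained slope M4 equals M3.

Stages M1 and M2 are additionally *gated* on their deviance reduction: the
added terms are kept only when the stage's likelihood-ratio test passes
0.05, otherwise the stage reverts. Deviance comparison is the acceptance
criterion for each stage. The gate tempers — but does not control — the
family-wise error of the sequence under a null response; see Limitations.

Fixed-effect inference uses containment degrees of freedom: Level-1 and
cross-level terms (and the intercept) get $N - G - p_1$ with $p_1$ the
Level-1 + cross-level term count; Level-2 terms get $G - p_2 - 1$. Variance
explained is reported as the proportional reduction of each variance
component relative to M0 (slope variation relative to M3), with negative
values reported as computed — a component can rise when the model changes.
A rank-deficient design is an error naming the collinear terms; inside the
automated sequence, candidate sets are first capped (by marginal
correlation rank) so containment df stay positive, and inseparable columns
are dropped products-first so hierarchy cannot break.

Two labelling conventions are worth noting for readers comparing with
staged-results tables of this kind elsewhere. The variance components are labelled
by what they are — between-shift (intercept) variance, within-shift
residual variance — rather than by any symbol convention, since printed
symbol-to-label pairings vary. And the random-slope likelihood-ratio test
is reported at the moment of slope acceptance (before the post-slope
re-elimination), which is why its df reflects only the parameters the slope
step itself added.

## The synthetic study generator

The generator is first-class, tested code, not a fixture. Its defaults
define the study conditions everything else is tested under: 35 day shifts
of three four-hour segments (14 400 s), with per-segment rating dropout of
16/105 so the expected number of rated segments is 89 (the reference totals
give segments per shift only in aggregate; three segments with calibrated
dropout reproduces both); 70%/30% weekday/weekend; a 16-room,
2-station, 3-service-area unit map with an uninstrumented off-main
pseudo-zone.

Raw streams per segment: a semi-Markov location process over zones
(class-level transition matrix, gamma dwell times, per-shift lognormal
dwell multipliers); a two-state speech renewal process whose inter-episode
gaps are exponential (Poisson-like speaking) or Pareto (bursty speaking;
tail index 1.15, chosen so the downstream burstiness of speaking is
robustly positive across segments while keeping a finite mean gap);
accelerometer magnitudes around zone-class baselines with walking bouts at
each zone change plus occasional in-room activity bouts; and ambient
noise/temperature frames per instrumented zone with shift-level and
segment-level offsets. Shift-level effects are drawn once per shift in the
roster (columns prefixed `eff_`, part of the recorded ground truth, never
leaked into the analysis table), so segments of the same shift share
conditions — this is what produces between-shift clustering in the
features.

Exertion ratings come from a latent two-level linear model on the z-scored
features and task demands: configured fixed coefficients on the final-model
term structure (one Level-1 product and one cross-level product per
response), a shift random intercept, one random slope (burstiness of
speaking for ME; nursing-station speaking volume for PE), and residual
noise, mapped to Borg by `round(13 + 3y)` and clamped to [6, 20] — centred
on "somewhat hard" and order-preserving. Default variance components are
the final-model values (ME: 0.17 between, 0.36 residual, 0.02 slope; PE:
0.25, 0.20, 0.16). Fixed coefficients default to the reference final-model
values on the standardised scale, with one exception: the ME
time-outside × activity-outside product, whose reference value (2.24)
belongs to centred-but-unscaled fraction-scale features and would dominate
the latent variance on the standardised scale; the default is 0.60, chosen
once to preserve that term's share of explained between-shift variance.

Rounding to the Borg grid adds quantisation variance (1/12 on the Borg
scale) to the residual component and clamping mildly attenuates extreme
segments, so recovery testing of the *estimation machinery* fits the
recorded continuous latent outcome, while rating-based analyses accept
those known, small distortions as part of the measurement model.

**What the generator does and does not emulate.** It reproduces zone-level
time allocation, movement unpredictability, bursty speech, ambient
conditions and their shift-level clustering, and an exertion process with
exactly the model structure the analysis assumes. It does not emulate
radio-level localisation error, speaker isolation failures, posture beyond
a stillness ratio, cross-feature causal structure (the direct feature
simulator draws features independently), or any misspecification of the
exertion model. Passing tests therefore demonstrate that the pipeline
recovers what it assumes, at the study's scale and noise levels — not that
the assumed model is true of real nursing work.

**Calibration.** With the default stream parameters the emergent
feature-level intraclass correlations fall around 0.8 for ambient and
time-allocation features and 0.4–0.7 for dynamics features, and the
resulting outcome ICCs centre near 0.5 (ME) and 0.55 (PE) at the 35-shift
scale — the designed clustering regime of roughly 0.6, somewhat below for
ME because the interaction terms unavoidably contribute within-shift
variance on the standardised-feature scale. The direct feature simulator
(`simulate_features()`) used for Monte-Carlo work assigns ICC 0.85 to the
stable features and 0.45 to the dynamics features to mirror this.

## Problem sizes and numerical choices

Monte-Carlo validation runs at five times the study scale — 175 shifts,
100 replicates — for coefficient and variance-component recovery (within
two Monte-Carlo standard errors; 95% Wald intervals covering truth in at
least 90% of replicates), for recovery of a planted model structure by the
full staged sequence, and for false retention under a pure-noise response.
The structure-recovery study uses the physical-exertion generative
structure because each of its terms is either individually strong or
protected by hierarchy, making "recovered" unambiguous; the
mental-exertion structure is used for direct coefficient recovery, fitted
by REML because ML variance components carry a downward bias of order
(number of fixed effects)/(number of shifts) that a two-SE criterion at
100 replicates is sharp enough to detect. Two finite-sample facts of this
regime are worth recording. A slope variance as small as 0.02 (its
sampling standard deviation is about the same size) sits close to the
non-negativity boundary, and its estimator is right-skewed there: its
Monte-Carlo mean exceeds the generative value by slightly more than two
Monte-Carlo standard errors even though the estimation code is exact on
the balanced closed-form oracle. And a staged procedure that tests dozens
of candidate terms at per-term alpha = 0.05 — as this one, by design,
does — has a family-wise false-retention rate far above 0.05 under a
pure-noise response, roughly one minus 0.95 to the power of the number of
candidate tests. Controlling it would require Bonferroni-level per-term
thresholds that are not part of this procedure.

Numerical conventions collected in one place: sample (n−1) standard
deviation inside burstiness; entropy base 2 over merged distinct-zone
pairs; coordinate-descent convergence when the largest coefficient change
in a cycle falls below `tol` (default 1e-5; tests use 1e-10 against
closed forms); the $\lambda$ grid spans 4 decades below
$\lambda_{\max} = \max_j |x_j^\top y| / (n\alpha)$ when $n > p$ and 2 when
$p \ge n$; variance parameters are constrained non-negative with boundary
fits allowed (a boundary intercept variance yields ICC 0); ties in
backward elimination break to the larger p then lexicographic term name;
all randomness flows from explicit integer seeds, with sub-seeds derived
additively so every artifact is regenerable from configuration plus seed.

## Limitations

Screening ignores clustering by design and is only made safe by the
clustered modelling that follows; retained-set sizes at the screening stage
are therefore not meaningful endpoints. Containment df are a convention —
other df approximations (Satterthwaite, Kenward–Roger) would change
p-values slightly. The M3 slope search is greedy in likelihood-ratio
order; with several strong candidate slopes the accepted set can depend on
search order. The interaction-plot confidence bands use the normal
approximation on the fixed-effect covariance and ignore random-effect
uncertainty. The ingest path accepts an externally prepared segment-level
table through a column mapping, but any such table must already contain
the engineered features — raw-stream ingest expects this package's own CSV
dialect.
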