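# shiftsense

Sensor-based measurement and multilevel modelling of critical-care nursing
workload.

Intensive-care nurses wear badge sensors that resolve zone-level location,
speech features and body movement, while stationary badges record ambient
noise and temperature in patient rooms, nursing stations and service areas.
Every four hours the nurse rates perceived **mental exertion (ME)** and
**physical exertion (PE)** on the Borg 6–20 scale, and each shift records
its **task demands** (patient counts, sitters, assistant presence, counts of
patients needing specific interventions). `shiftsense` turns the raw sensor
streams into *work-process features* — e.g. the **burstiness** of speaking,

    B = (sigma - mu) / (sigma + mu)   over inter-event gaps,  B in [-1, 1],

and the **Shannon entropy of location transitions**
`H = -sum p(a->b) log2 p(a->b)` — screens the feature space with an
elastic net (alpha = 0.9, cross-validated lambda, two-stage hierarchical
interaction screen), and fits the staged two-level mixed-model sequence

    M0 (intercept + shift random intercept)
    M1 (+ Level-1 sensor features, backward-eliminated)
    M2 (+ Level-2 task demands)
    M3 (+ random coefficients)
    M4 (+ cross-level interactions)

by maximum likelihood, reporting fixed effects with containment-df t tests,
variance components, intraclass correlation, group-mean reliability,
level-specific pseudo-R², and likelihood-ratio model comparisons. A
synthetic-study generator with recorded ground truth (roster, raw streams,
Borg ratings) makes every stage testable without any data download.

## Worked example

```r
library(shiftsense)

# a complete synthetic study at the reference scale:
# 35 shifts x up to 3 rated four-hour segments (~89 rated segments)
report <- run_pipeline(run_config(mode = "simulate", seed = 1))
print(report)
```

```
Workload analysis report: 84 segments, 35 shifts (seed 1)

-- response: me --
Staged two-level model sequence for 'me' (84 obs, 35 shifts)
  ICC = 0.41, group-mean reliability = 0.61
  M0 Intercept only: 0 terms, deviance 226.55, LR chi2(1) = 10.83, p = 0.001
  M1 + Level 1 predictors: 12 terms, deviance 148.69, LR chi2(12) = 77.86, p = 1.06e-11
  M2 + Level 2 predictors (none retained): 12 terms, deviance 148.69
  ...
```

The ICC says ~41% of the variance in mental-exertion ratings lies between
shifts (nurses rate segments of the same shift alike); the M0 likelihood
ratio confirms the shift grouping is non-ignorable; the staged rows then
show how much between- and within-shift variance the sensor features and
task demands absorb. `sequence_table(report$sequences$me)` returns the
staged results as a tidy table (fixed components, random components,
variance modelled, model fit), and
`report$interaction_plots` holds moderator-at-bounds line data for every
retained product term (`plot_interaction()` draws them).

Individual stages are plain functions: `simulate_study()`,
`extract_all()`, `screen_interactions()`, `fit_lmm()`,
`run_model_sequence()`, `icc()`, `group_mean_reliability()`,
`pseudo_r2()`, `lr_test()`. A thin command-line wrapper lives at
`inst/scripts/shiftsense-cli.R`; externally prepared segment-level tables
ingest through `ingest_analysis_table()` with a column-mapping file.

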