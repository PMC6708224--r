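# pbsubtype

Physical-behavior subtyping from week-long accelerometer recordings, for
researchers studying activity patterns in severely fatigued people with
multiple sclerosis (and similar clinical cohorts). Wearable studies
routinely summarise a week of 60-second epoch counts into a single number
(e.g. minutes of MVPA); this package instead treats physical behavior as
multidimensional — amount and intensity, frequency and duration of bouts,
and within-day timing — and asks whether patients fall into distinct
behavioral subtypes.

## The method

Starting from epoch-level activity counts (`participant_id, timestamp,
counts[, worn]`), the pipeline:

1. **Validates wear time** — days count when wear ≥ 660 min; participants
   stay when they have ≥ 5 valid days.
2. **Classifies intensity** per epoch by counts-per-minute cut-points
   (defaults: sedentary < 100 cpm, MVPA ≥ 1952 cpm) and detects bouts:
   sedentary bouts are any uninterrupted sedentary run, prolonged MVPA
   bouts require ≥ 10 uninterrupted minutes.
3. **Computes 15 measures** per participant: %Active, %MVPA, %SB, CPD, CPM
   (amount/intensity); MVPA BL/NoB/tt and SB BL/NoB/tt
   (frequency/duration, weekly totals rescaled by 7/#valid-days); and four
   day-part change scores dMVPA1/2, dSB1/2 (afternoon − morning,
   evening − afternoon percentages).
4. **Reduces dimension**: z-scores, outlier-to-missing at |z| ≥ 4 (and
   removal of affected participants before clustering),
   Kaiser–Meyer–Olkin adequacy screening, correlation-matrix PCA retaining
   components with eigenvalue λ ≥ 1, direct oblimin (quartimin, δ = 0)
   rotation, and selection of one key measure per component with a
   sedentary-domain preference within a 0.05 loading margin. On the
   reference cohort this yields {%SB, dSB1, SB NoB, tt MVPA, dSB2}.
5. **Clusters** the key-measure z-scores in two steps: Ward agglomeration
   on squared Euclidean distances (k chosen from the largest relative jump
   in agglomeration coefficients), then k-means (Lloyd) refinement seeded
   with the hierarchical centroids. Stability is scored by double
   split-half cross-validation with Cramér's V,
   V = √(χ² / (n·(min(r,c) − 1))).
6. **Compares subtypes** on covariates and measures: ANOVA + Bonferroni
   post-hoc, Kruskal–Wallis + Mann–Whitney post-hoc, chi-square.

Because the original clinical data are not public, the package ships a
synthetic-cohort generator (`simulate_cohort()`): a day-part-modulated
three-state semi-Markov construction whose targets are the published
subtype profiles, so every stage is testable end to end.

## Worked example

```r
library(pbsubtype)

coh <- simulate_cohort(cohort_config(n_participants = 120, seed = 42))
mt  <- measures_table(coh$epochs)           # wear validation + 15 measures
fit <- pb_subtype(mt$measures, keys = pb_key_measures(), k = 3, seed = 42)
fit
#> Physical-behavior subtype model
#>   participants clustered: 119 (removed as outliers: 0)
#>   key measures: pct_sb, d_sb1, sb_nob, tt_mvpa, d_sb2
#>   k = 3 subtypes (sizes 29/38/52); split-half Cramer's V = 0.62

round(coef(fit, "raw"), 1)
#>      pct_sb d_sb1 sb_nob tt_mvpa d_sb2
#> [1,]   67.5  -8.8  731.9   107.7  20.3
#> [2,]   55.8  -1.7  758.7   173.5  11.4
#> [3,]   71.2   1.7  747.7    91.9   5.8
```

One participant of 120 fell below the 5-valid-day wear rule and was
excluded, so 119 enter clustering. The three centroids read as
behavioral phenotypes: row 2 is the *active* subtype (lowest %SB, highest
weekly prolonged-MVPA minutes), row 3 the *most sedentary* one (highest
%SB, flat day pattern), and row 1 an *afternoon-active* subtype — its
negative dSB1 means it sits ~9 percentage points less in the afternoon
than in the morning, and its large dSB2 that sitting rebounds in the
evening. A split-half Cramér's V of 0.62 indicates moderate stability at
this small n; at the reference scale (n ≈ 212) it is typically ≥ 0.7.

`plot(fit, "profile")` draws the per-subtype z-score signatures,
`plot(fit, "dayparts")` the day-part %SB curves, `plot(fit, "elbow")` the
k-selection diagnostics. `predict(fit, newdata)` assigns new participants
to the nearest centroid, and `compare_groups(data, cluster_labels(fit))`
produces the covariate comparison table. `run_pipeline(run_config(...))`
chains every stage and writes per-stage CSV/JSON outputs plus a manifest.

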