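---
title: "Physical-behavior subtyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physical-behavior subtyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbsubtype)
```

This vignette is the package's account of its science: what is modelled,
which parameters matter, what the synthetic cohort does and does not
emulate, and where the design was genuinely open.

## The analysis in one paragraph

Week-long 60-s-epoch accelerometer counts are validated for wear time
(days with ≥ 660 worn minutes; participants with ≥ 5 such days),
classified into sedentary / light / MVPA by counts-per-minute cut-points,
and summarised into fifteen physical-behavior measures spanning three
categories (amount and intensity; frequency and duration of bouts; day
patterns) and two domains (physical activity; sedentary behavior). The
fifteen z-scored measures are reduced by correlation-matrix PCA with
direct oblimin rotation to five components, each represented by one key
measure. Two-step clustering — Ward agglomeration for the cluster count,
k-means for refinement — on the key-measure z-scores yields behavioral
subtypes, whose stability is scored by double split-half cross-validation
with Cramér's V and whose clinical correlates are tested with an
ANOVA / Kruskal–Wallis / chi-square battery.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_wear_min` | 660 | min/day | wear-validity threshold, inclusive ("at least") |
| `min_valid_days` | 5 | days | participant inclusion, inclusive |
| `sedentary_max` | 100 | counts/min (exclusive) | standard adult vertical-axis cut-point; the source calibration did not print its values, so this is a declared convention, fully configurable |
| `mvpa_min` | 1952 | counts/min (inclusive) | same |
| SB bout minimum | 1 | min | any uninterrupted sedentary run counts; weekly sedentary-bout numbers of ~700–800 are only consistent with a 1-epoch minimum, not a 10-min one |
| MVPA bout minimum | 10 | min | "prolonged" MVPA |
| interruption allowance | 0 | min | bouts are strictly uninterrupted by default; a per-interruption allowance is available |
| non-wear rule | 60 | min of zeros | used only when no `worn` flag is supplied |
| day parts | 06–12, 12–18, 18–24 | clock h | conventional tertiles of the waking day; boundaries are configurable because no canonical definition exists |
| outlier threshold | 4.0 | SD, inclusive | single measurements beyond it become missing; participants with any flagged key measure are removed before clustering |
| `sb_preference_margin` | 0.05 | loading units | see key-measure selection |
| k-means | tol 1e-6, 300 iters | — | deterministic Lloyd from hierarchical centroids; empty clusters reseeded with the farthest point |
| `k_max` | 10 | clusters | search range for the elbow rule |

## Measure operationalization

The per-measure formulas are a reconstruction: the measure list and its
category/domain structure are fixed, but no published formula sheet was
available, so the package documents its own operationalization.
Percentage measures are wear-time-normalized over all valid days pooled
(`%SB` = sedentary minutes / worn minutes). Weekly totals (tt MVPA,
tt SB, bout counts) are sums over valid days rescaled by 7/#valid-days —
a participant with five identical valid days gets the same weekly totals
as with seven; the identity `tt MVPA = MVPA BL × MVPA NoB` holds exactly
under this convention. Day-part percentages are computed within each
window over the wear time in that window, averaged across valid days,
then differenced (afternoon − morning, evening − afternoon); averaging
before differencing is a choice, the per-day alternative is a
documented variant. A participant with no wear in some day part on every
valid day has undefined change scores and is flagged and excluded from
the multivariate stages rather than imputed. The two bout families use
different minima (1 min for SB, 10 for MVPA), and bout runs never join
across non-wear or across gaps in the recording.

## Dimension reduction

Z-scores use the sample mean and SD per measure. `%Active = 100 − %SB`
holds by construction, so the 15-measure correlation matrix is exactly
singular; the KMO statistic therefore uses a Moore–Penrose pseudoinverse
for its anti-image partial correlations (with a warning), which reduces
to the ordinary inverse on full-rank data. Components with eigenvalue
≥ 1 are retained — for a correlation matrix the leading eigenvalue is
always ≥ 1, so retention is never empty.

"Orthogonal direct oblimin" is a contradiction in terms (oblimin is
oblique); the package resolves it as oblique direct oblimin with δ = 0
(quartimin), because correlated components are expected when measures
share wear-time denominators. The rotation is a gradient-projection
implementation with Kaiser row normalization, written in-package;
varimax is available as an orthogonal alternative. Loadings are reported
from the pattern matrix (the structure matrix and component correlations
are also returned); each component's sign is fixed so its dominant
loading is positive.

Key-measure selection takes, per component in descending variance order,
the measure with the largest absolute pattern loading — unless a
sedentary-domain measure loads within `sb_preference_margin = 0.05` of
that maximum, in which case the sedentary measure wins. The margin is
reverse-engineered so that the rule reproduces the reference cohort's
published choices (%SB over %Active at 0.92 vs 0.97; dSB1 over dMVPA1 at
0.91 vs −0.94); it is a named parameter, not a claim about the original
authors' reasoning. A measure can represent only one component; a taken
measure yields to the next candidate.

## Clustering and validation

Hierarchical agglomeration uses Ward linkage over squared Euclidean
distances; Ward is the standard companion of that metric (the linkage
itself was not specified in the reference analysis; single, complete and
average are provided). The agglomeration schedule reports, per merge,
the merge criterion value (for Ward, twice the within-SS increase) and
the cumulative within-cluster SS. The cluster count maximizes the
relative coefficient change (c(k−1) − c(k))/c(k) over k ∈ [2, k_max]
using the per-merge criterion values: on data with genuine k-cluster
structure the merge that first fuses two true clusters is an order of
magnitude costlier than the last within-cluster merge, which makes the
ratio peak at the true k. (Using cumulative coefficients instead makes
the rule a knife-edge biased toward k = 2, because the final merge is
intrinsically the largest; both columns are returned so either analysis
can be reproduced.) The automated rule replaces the visual dendrogram
reading that cannot be automated; the tree is exported in Newick form
for human inspection.

Split-half validation: the sample is halved at random (floor/ceil, no
stratification), each half gets its own two-step solution, k-means is
rerun on each half seeded with the *other* half's centers, and agreement
between own and cross-seeded labels is Cramér's V per half. The summary
V is the mean of the two — the combination rule of the single published
V = 0.7 is unstated, so the package names its choice and reports both
halves.

## The synthetic cohort

The generator emulates the study conditions: ~212 participants, 7
recording days, 60-s epochs, a ~07:00–23:00 wear window with ±20 min
daily jitter, a 0.1 probability per day of truncated wear below 660 min,
and three latent subtypes with the published key-measure means/SDs and
covariate distributions as generative parameters (proportions
46/114/48 over the 208 clustered patients).

Per participant, targets for the five key measures are drawn as
independent truncated normals (percentages to [0,100], times and counts
to ≥ 0, and the three day-part sedentary occupancies implied by
(%SB, dSB1, dSB2) each to [0,100]; infeasible specifications error after
bounded rejection). A day-part-modulated three-state semi-Markov
construction then realizes them: per day part, the sedentary occupancy
fixes the sedentary minutes, the weekly bout-number target fixes the
number of sedentary runs (redistributed across parts when a part's light
time cannot host its quota), run lengths are random compositions, and
prolonged MVPA is scheduled as explicit 10–25-min bouts. Weekly
quantities are provisioned on valid days at 1/7 of the weekly target per
day, so the downstream 7/#valid-days rescaling recovers the target.
Counts are uniform within the state's cut-point band — only their
ordering across cut-points matters downstream.

Documented round-trip tolerances (epoch simulation → measure extraction):
%SB and the day-part change scores within ±3 percentage points, tt MVPA
within ±15 min/week, SB NoB within ±25 bouts/week; in practice the
errors are an order of magnitude smaller.

What the generator does **not** emulate: between-measure correlations
within a subtype (targets are drawn independently; correlations among
the fifteen measures arise only mechanically from the state process),
day-to-day behavioral autocorrelation, seasonal or weekday/weekend
structure, device artefacts, and any fatigue dynamics. Passing recovery
tests therefore show that the pipeline recovers structure of this
independent-normal form at the published effect sizes — not that the
clinical clusters themselves are this well separated, nor that real
measure correlations would not change the PCA. Indeed, under these
independence conditions the published between-subtype separations put a
ceiling on recoverability: the Bayes-optimal classifier with the true
generative parameters reaches an adjusted Rand index of only ~0.64, so
near-perfect recovery at published SDs is impossible by construction;
with SDs halved the pipeline recovers subtypes almost perfectly
(ARI ≈ 0.95–0.98) and selects k = 3 essentially always. The
measure-level "fast mode" emits the drawn key-measure targets directly
(the ten non-key measures exist only in epoch mode) and yields the same
recovery behavior as the epoch route under matched seeds.

The exact discrete EDSS distribution of the cohort is unknown; the
generator uses a normal on the published median with SD = IQR/1.349,
rounded to 0.5 steps and clipped to [0, 5.5], and documents this rather
than claiming fidelity. Disease duration is log-normal matched to the
published median and IQR; CIS20r fatigue is clipped to [35, 56]
(severe-fatigue inclusion); age to [18, 70].

## Comparison battery

Normal continuous variables: classic equal-variance one-way ANOVA
(Welch-free, matching the era's default) with pooled-SD pairwise t tests,
Bonferroni-adjusted (for 3 clusters, adjusted p = min(1, 3·raw)). Skewed
variables: Kruskal–Wallis with pairwise Mann–Whitney post-hoc, unadjusted
by default because no adjustment was stated for them (a Bonferroni switch
exists). Categorical: chi-square without continuity correction, with a
warning attached when expected counts fall below 1; the "other/unknown"
MS type stays its own category. All-tied Kruskal–Wallis data are
reported as p = 1 with a note. Post-hoc grids are only produced when the
omnibus p is below α = 0.05.

## Numerical choices and degenerate inputs

Problem sizes in the test-suite simulations are chosen to keep the whole
suite in a few minutes: recovery runs use 25 seeds at n = 212
(measure-level), oracle-equivalence checks use 100 random small
instances per primitive, and the type-I-error simulation uses 1000
replicates of three 100-participant groups. Assignment ties in k-means
go to the lowest cluster index; zero-distance merges are legal in the
hierarchical step (duplicate participants merge first at coefficient 0,
and a zero denominator in the elbow ratio is treated as an infinite
jump, i.e. perfect clusters). A degenerate schedule with all
coefficients equal (e.g. a single repeated point) errors as
"cluster count undetermined". Determinism: every stochastic stage takes
an explicit seed; a global pipeline seed fans out to stage seeds through
a fixed affine map modulo 2³¹ − 1, and the caller's RNG state is always
restored.

## Known limitations

The cut-point values, day-part boundaries and the measure formula sheet
are declared reconstructions, not recovered constants; analyses
sensitive to them should vary them. The elbow rule automates what was
originally a part-visual judgement. The pseudoinverse-based KMO on
rank-deficient data is a well-defined extension but not a standard
statistic. The synthetic cohort's independence assumptions bound what
recovery tests can certify about real data (see above).
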