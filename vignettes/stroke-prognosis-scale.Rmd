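---
title: "An early prognostic scale for ischemic stroke recovery: model, construction pipeline, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An early prognostic scale for ischemic stroke recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokescale)
```

## The problem

Most prognostic tools for ischemic stroke use only baseline severity or
imaging. This package implements a bedside alternative: an 8-item
weighted-point scale that predicts the 90-day outcome (good recovery,
defined as a day-90 Barthel Index of 90 or more) from observations that are
all available by day 3 of admission — age, diabetes history, the NIHSS on
day 1, two symptoms from the traditional Chinese medicine (TCM) examination
on day 1 (anxiety, irritability), and the *changes* between day 1 and day 3
of the NIHSS and of two further symptoms (circumrotating, i.e. vertigo, and
tinnitus). The change of a symptom is coded ternary: *disappear*
(present day 1, absent day 3), *appear* (absent day 1, present day 3), and
*keep* (no change).

The package contains both the finished instrument
(`default_scale()`, `score_cohort()`, `validate_scale()`) and the complete
procedure by which such an instrument is constructed from a cohort
(`run_develop()`), so the methodology itself is testable.

## The scale

Each item maps a patient to a category and assigns points
(`points = weight × category index`); the total is the sum over items and a
total **strictly greater than the cutoff 9.5** predicts poor recovery.

| Item | Categories → points |
|---|---|
| Age | ≤ 56.44 → 0; > 56.44 → 1 |
| History of diabetes | no → 0; yes → 1 |
| Anxiety, day 1 | no → 0; yes → 1 |
| NIHSS, day 1 | ≤ 2 → 0; 3–6 → 1; ≥ 7 → 2 |
| Irritability, day 1 | no → 0; yes → 1.5 |
| NIHSS change (day 3 − day 1) | ≤ −1 → 0; > −1 → 1 |
| Circumrotating change | disappear → 0; keep → 2; appear → 4 |
| Tinnitus change | disappear → 0; keep → 2.5; appear → 5 |

The maximum total is 16.5 (verified in the tests by brute-force enumeration
of all 864 category combinations). Two boundary conventions deserve
mention, because the printed instrument leaves them ambiguous:

* **NIHSS day 1 = 7.** The published category listing skips 7 ("≤ 2",
  "3–6", "> 7" in one rendering, "> 6" in another). We code 7 into the top
  category so the three categories partition the integers; this matches the
  "> 6" rendering.
* **Symptoms absent on both days.** A literal reading of "no change
  (keep)" gives such patients the keep points (so an entirely symptom-free
  patient starts at 2 + 2.5 = 4.5 points). This literal policy is the
  default; `absent_pair_policy = "zero"` scores absent-absent pairs 0
  instead. The published 0–16.5 range is attainable under either policy.
* **Classification at the cutoff.** The rule is strict (`total > cutoff`
  ⇒ poor), observable at a total of exactly 9.5, which is an achievable
  half-point score.

```{r}
sc <- default_scale()
sc
score_patient(sc, list(age = 60, hx_dm = 0, sym_anxiety_d1 = 0,
                       nihss_d1 = 4L, nihss_d3 = 2L,
                       sym_irritability_d1 = 0,
                       sym_circumrotating_d1 = 1, sym_circumrotating_d3 = 0,
                       sym_tinnitus_d1 = 0, sym_tinnitus_d3 = 0))$total
```

## The construction pipeline

`run_develop()` re-runs the published construction procedure on any cohort:

1. **Univariate screening** (`screen_candidates()`). Symptoms with a day-1
   appearance rate below 5 % are dropped (boundary inclusive; the filter
   precedes change analysis). Binary factors are compared between good and
   poor recoveries by Pearson chi-square without continuity correction;
   continuous factors by a caller-chosen method, defaulting to the
   Mann–Whitney U test (continuity-corrected normal approximation with tie
   correction); symptom changes by chi-square on the
   3 × 2 status-by-outcome table with empty rows dropped. Significance is
   `p < 0.05`. For the symptom–severity association,
   `rank_correlation()` offers Spearman (default, on midranks, p from the
   large-sample t approximation) and Pearson, since the source analysis
   described both.
2. **Cutpoint discretization** (`grow_thresholds()`). Continuous
   predictors are binned by a CART-style exhaustive search: candidate
   thresholds at midpoints between consecutive distinct values, Gini
   impurity decrease as the criterion, ties broken toward the smallest
   threshold, `min_leaf = 20` by default to avoid sliver bins at cohort
   sizes of a few hundred. Age and the NIHSS change use depth 1 (two
   categories); day-1 NIHSS uses depth 2 pruned to the two largest-gain
   thresholds (three categories). The procedure is deterministic. The
   published thresholds (56.44 years; 2 and 6 NIHSS points; −1 change) are
   data artifacts of the original cohort and are shipped as constants of
   the instrument (`published_discretizations()`); re-derivation reports
   thresholds at full precision.
3. **Multivariable logistic regression** (`fit_logistic()`,
   `select_factors()`). Maximum likelihood via iteratively reweighted
   least squares, outcome coded 1 = poor so positive coefficients are risk
   factors. Change variables enter as the single ordinal code
   disappear/keep/appear = 0/1/2, matching a one-coefficient-per-change
   model. The original report does not state its selection algorithm;
   we adopt backward elimination at Wald `p ≥ 0.05` (dropping the largest
   p first, refitting each time) and record every elimination in an audit
   trail; `strategy = "none"` keeps the full model. Confidence intervals
   are `exp(β ± 1.96·SE)`; perfect separation and collinearity abort with
   diagnostic errors rather than silently returning unstable estimates.
4. **Weight assignment.** The published mapping from coefficients to
   point weights was "a simple weighting scheme" with no stated algorithm,
   so by default the pipeline carries the published weights as constants.
   Rounding each fitted coefficient to the nearest half point
   (`use_published_weights = FALSE`) reproduces all eight published weights
   from the published coefficients and is offered as an explicitly
   experimental alternative.
5. **Cutoff selection** (`roc_curve()`, `youden_cutoff()`). The scale is
   applied to the development cohort and the decision cutoff is the
   achievable score value maximizing Youden's index
   (sensitivity + specificity − 1), ties broken toward the smallest cutoff.
   Candidate cutoffs sit at observed score values (not midpoints) because
   the published cutoff 9.5 is itself an achievable score under the
   half-point scheme.

Validation (`validate_scale()`) reports the confusion counts in the
good/poor convention — TG/FP/FG/TP with sensitivity = TG/(TG+FP) the
*detection rate of good recovery*, specificity = TP/(TP+FG), accuracy =
(TG+TP)/n — plus the full ROC table and trapezoidal AUC.

## The synthetic cohort generator

No patient records are distributed with (or available to) this package, so
every stage is exercised on synthetic cohorts (`generate_cohort()`,
`default_params()`) that reproduce the development cohort's published
marginal structure:

* n = 413; age ~ Normal(66.4, 10.8) truncated to 25–95 years, reported to
  0.1 year; 61.5 % male; history prevalences 0.608 (hypertension), 0.327
  (prior stroke), 0.245 (CHD), 0.199 (diabetes), 0.058 (AF);
  onset-to-admission ~ Normal(10.0, 7.17) truncated to 0–24 h.
* Day-1 symptom prevalences are the pooled good/poor counts of the
  development tables (15-symptom default panel). One symptom
  (difficult-to-cough-sputum) has tabulated change counts but no tabulated
  day-1 prevalence; we assume 0.10 once and derive its transition rates
  from that. Symptoms with no tabulated transitions use resolve = 0.30,
  appear = 0.02, typical of the tabulated ones.
* Day-1 NIHSS is a rounded lognormal with arithmetic mean 6.3 and SD 4.6,
  clipped to 0–42; the day-1→3 change is a discretized normal with mean
  −0.5 and SD 2.25 (between the two reported group SDs), and day-3 NIHSS
  is day 1 + change clipped to range.
* The outcome is drawn from a logistic model on the 8 scale category
  codes with the published coefficients (1.20, 0.79, 1.15, 1.12, 1.53,
  0.91, 2.05, 2.58); the intercept is not published and is calibrated by
  bisection (`calibrate_intercept()`, on a fixed 50 000-draw covariate
  sample with its own RNG substream) so the expected poor fraction is
  181/413. The day-90 Barthel Index is then back-filled merely to be
  consistent with the drawn label (poor: uniform on {0, 5, …, 85}; good:
  uniform on {90, 95, 100}) — it is explicitly synthetic, since only the
  dichotomy is modelled.
* Predictors are mutually independent: the source tables report only
  marginals, so no dependence structure is assumed.

**What passing tests on this generator do and do not show.** They show the
pipeline's statistics are correct (everything is cross-checked against
brute-force oracles: exact permutation enumeration for Mann–Whitney,
direct Σ(O−E)²/E for chi-square, naive double-loop Gini scans for splits,
one-pass tallies for confusion counts) and that the estimation stages
recover planted truth — logistic coefficient recovery is tested at
n = 5000 over 50 seeds with mean relative bias under 5 %, planted
cutpoints over 20 seeds, and the type-I rate of the full screen approaches
the nominal 0.05 under a null generator (500 replicates at n = 2000).
They do *not* show that real stroke cohorts behave like the generator. In
particular, real risk factors are correlated (older patients have more
comorbidity and higher NIHSS), which widens and shifts the score
distribution. Because the generator reproduces only marginals and draws
the outcome from a linear predictor closely aligned with the score itself,
the Youden-optimal cutoff on synthetic cohorts concentrates near the mean
synthetic score plus a prior-odds offset; the published cutoff instead
reflects the original cohort's joint distribution, which marginal tables
alone cannot reconstruct. Cutoff re-derivation on synthetic data is
therefore a mechanism check, not a reproduction of the published 9.5.

## Reproducible end-to-end check

```{r, eval = FALSE}
res <- run_end_to_end_check(seed = 1)
res$checks
```

simulates a development cohort (n = 2000) and an independent held-out
cohort (n = 1000), re-runs the whole pipeline, applies the resulting scale
to the held-out data and asserts the structural invariants (score range
and half-point granularity, confusion-count consistency, metric bounds).
These problem sizes, and those quoted above for the recovery tests, were
chosen so the full suite runs in about a minute while keeping Monte Carlo
error well inside the asserted tolerances.

## Known limitations

* Patients who died before day 90 (no Barthel Index) are outside the
  model, as in the source study; cohort validation rejects incomplete
  records rather than imputing.
* The published instrument's external validity is not addressed here: the
  package validates arithmetic and methodology, not clinical performance.
* Only days 1 and 3 enter the scale; day-2/7/14/28 observations, although
  collected in the original study, are unused.
* The scale emits a dichotomous prediction, not a calibrated probability;
  no logit-based risk output is provided because the published instrument
  is a point score.
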