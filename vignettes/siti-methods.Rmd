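---
title: "The SITI scale: scoring rules, evaluation methods, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SITI scale: scoring rules, evaluation methods, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitiscale)
```

## The scoring model

The Surgical Intervention for Traumatic Injury (SITI) scale summarizes a
TBI patient's admission findings into a single 0–11 integer intended to
communicate how likely a neurosurgeon is to judge that the patient needs
surgical decompression (craniotomy or craniectomy within 24 hours of
arrival). It is purely additive over five components, each observable at
presentation:

* **GCS total** (3–15): 0 points above 12, 1 point for 9–12, 2 points
  below 9. For intubated patients the verbal component is graded 1T and
  counted as 1 inside the total; the intubation flag itself is metadata
  and never alters points.
* **Pupil exam**: 2 points for a *unilateral* enlarged pupil. Bilateral
  enlarged and/or unreactive pupils score 0 — they signal a different
  (often unsalvageable) clinical situation, and the population the scale
  was evaluated on excluded such patients at entry. We model them as an
  explicit category rather than as missing data so the scale stays total
  on real-world inputs. A unilaterally unreactive but *not* enlarged
  pupil is not a level of the scale; it should be coded `normal`.
* **Midline shift** of the septum pellucidum at the foramen of Monro, in
  millimeters: 0 below 5 mm, 2 for 5–10 mm, 4 above 10 mm.
* **Temporal pathology** (hemorrhage or edema in the middle cranial
  fossa): 1 point, reflecting herniation risk.
* **Epidural hematoma**: 2 points at a width of 10 mm or more.

A total of **3 or more** is classified positive. The additive structure
makes the scale monotone: worsening any one component can never lower
the total, a property the test suite verifies by exhaustive enumeration
of all 108 component-level combinations.

### Boundary and tie-break choices

Three boundaries of the published rule card are ambiguous at the printed
precision, and we fixed them as follows:

* **Midline shift at exactly 10.0 mm** scores 2, not 4: the bands are
  printed as "<5", "5–10", ">10", and taking the middle band closed on
  both sides is the only reading under which the three bands partition
  the measurement axis while honoring both strict inequalities.
* **Epidural hematoma at exactly 10.0 mm** scores 2: the prose rule is
  "≥ 10 mm" while the rule-card label reads ">10 mm"; we follow the
  prose as the more precise statement and expose `edh_strict_gt = TRUE`
  for the strict variant.
* **Positivity at exactly 3**: the threshold is "3 or above". The
  published contingency-table row labels ("> 3" / "< 3") cannot be meant
  literally, since the accompanying counts and predictive values are
  only consistent with a ≥ 3 split.

Out-of-range inputs (GCS outside 3–15, negative widths, midline shift
≥ 50 mm) are rejected with the offending value named, never clamped:
silent repair would hide upstream data errors. A missing component makes
the record's total undefined (`NA`); evaluation excludes such records
listwise and reports the count.

## Evaluation methods

`confusion_at_threshold()` crosses test positivity (score ≥ t) with the
operative label. `diagnostic_metrics()` returns sensitivity,
specificity, PPV and NPV as exact ratios; a metric with an empty
denominator is `NA` and flagged, not fabricated. Reported tables round
to two decimals half-away-from-zero at the reporting layer only — raw
ratios are always retained.

`roc_curve()` sweeps the integer thresholds 12 down to 0. Thirteen
thresholds are the natural resolution of a 12-level integer score; the
curve necessarily starts at (0,0) and ends at (1,1).
`auc_trapezoid()` integrates it with the trapezoid rule, which on a
threshold-swept curve is algebraically the Mann–Whitney statistic
P(S_op > S_nonop) + ½ P(S_op = S_nonop); ties therefore contribute
half-credit by construction. The test suite checks this identity against
a brute-force O(n²) pair enumeration on a thousand random cohorts, to
1e-12, and cross-checks one cohort against the independent pROC
implementation.

`compare_groups()` uses Welch's t-test for means by default (a
pooled-variance option exists) and the Pearson chi-squared test without
continuity correction for proportions. The source analysis says only
"t-tests" and "chi-squared tests"; Welch is the safer default under
unequal group variances (the groups differ in size by a factor of four),
and the uncorrected chi-squared makes small fixtures exactly
hand-checkable. Two groups of identical constant values are reported as
t = 0, p = 1 rather than an error.

`fit_logistic()` estimates surgery odds on any subset of the five
component point variables by maximum likelihood via iteratively
reweighted least squares (deviance tolerance 1e-8, at most 100
iterations), as implemented in `stats::glm`. Complete or quasi-complete
separation — where the MLE diverges — is detected from fitted
probabilities numerically at 0/1 together with exploding coefficients;
such fits are flagged nonconverged and report no coefficients. Each
converged model reports the rank-based AUC of its fitted probabilities.

### A published inconsistency

The published threshold-3 contingency table prints 327 above-threshold
nonoperative patients, but 327 + 470 does not equal the nonoperative
group total of 707, and the printed PPV of 0.39 is only consistent with
152/(152+237). The package therefore treats (tp 152, fp 237, fn 12,
tn 470) as the self-consistent matrix; `reproduce_table3()` refuses
inconsistent totals and names the violated identity, so user data is
never silently "corrected". Relatedly, the published NPV of 0.97 cannot
be obtained from that matrix by any consistent rounding rule:
470/482 = 0.9751, which rounds to 0.98 (truncation would give 0.97 but
would also turn sensitivity 0.9268 into 0.92, contradicting the printed
0.93). The package reports 0.98 and documents the 0.01 discrepancy
rather than reproducing it.

## The synthetic cohort generator

No individual-level data from the source trial is public, so
`generate_cohort()` emulates its assessed population: 871 patients,
operative fraction 164/871, entry GCS 4–12, no bilateral fixed-dilated
pupils. Each record draws its group label first, then each component
independently from group-specific marginals taken from the published
characteristics table:

* midline-shift bands (688, 19, 0)/707 nonoperative vs
  (61, 68, 35)/164 operative, with the continuous measurement uniform
  within the selected band (10–15 mm for the open top band);
* temporal pathology 245/707 vs 143/164;
* unilateral enlarged pupil 94/707 vs 34/164;
* epidural hematoma 56/707 vs 49/164. The published hematoma row is
  read as counting hematomas that meet the 10 mm scoring cutoff (the
  rule card labels the row with the width criterion), so by default
  every generated hematoma scores (`edh_ge10_frac = 1`, widths uniform
  10–20 mm); lowering the fraction mixes in sub-threshold hematomas
  (widths uniform 3–10 mm).
* GCS bin probabilities are not published. With totals uniform within
  the 4–8 and 9–12 bins, the bin means are 6 and 10.5, so we set
  P(9–12) = (m − 6)/4.5 per group to match the published group mean GCS
  (7.6 nonoperative, 8.1 operative), giving 0.356 and 0.467.

Optional fields (age, transport time, mechanism, intubation) are drawn
from simple distributions matched to the published group summaries; they
exist so the group-comparison machinery has realistic material, and
carry no information about the label beyond their group means.
Continuous values are recorded to 0.1 mm / 0.1 unit — the precision of
the underlying clinical measurements — which also makes cohorts
round-trip exactly through the CSV schema.

Generation is driven by a single seed in the spec and restores the
caller's RNG state, so identical specs give byte-identical cohorts.

### What the generator does and does not emulate

Only *marginals* are published, so components are sampled independently
within each group. Real TBI presentations are correlated (large shifts
co-occur with low GCS and hematomas), and correlation among informative
components typically *reduces* a score's AUC relative to independent
sampling. The pipeline-level check is therefore deliberately soft: over
200 seeded cohorts of n = 871 the mean AUC must fall in [0.80, 0.95], a
sanity corridor around the published high-0.8s value, not a point
reproduction. Passing it shows the calibration and pipeline are
mutually coherent at the published operating point; it does not validate
the scale on real patients. Under the default calibration the mean
synthetic group scores come out near the published 2.5 (nonoperative)
and 5.1 (operative).

`fixture_table3_cohort()` is different in kind: it is *constructed*, not
sampled — 871 records whose totals are forced to 2 or 3 so that the
threshold-3 confusion matrix is exactly (152, 237, 12, 470). It
reproduces the published screening metrics exactly but compresses the
score distribution to two levels, so its ROC is a single bend and its
AUC (≈ 0.80) understates what a full-range cohort shows.

## Problem sizes used in the checks

The test suite works at desk scale by design: the Mann–Whitney
equivalence uses 1000 random cohorts of up to 20 records (the identity
is exact, so small n loses nothing); marginal recovery uses one cohort
of 50,000 with 3-sigma binomial bands; logistic parameter recovery uses
100 replicates of n = 5000 requiring each coefficient inside 3 standard
errors at least 95 times; and the AUC corridor uses 200 cohorts of 871,
the assessed size of the source population.

## Known limitations

* The scale covers closed head injury only — no skull fracture,
  penetrating-injury, or posterior-fossa scoring — and the package makes
  no treatment recommendation beyond the positivity flag: the score
  suggests a clinical response, it does not dictate one.
* Confidence intervals for sensitivity/specificity/AUC are out of scope,
  as is any modelling of clinical outcome beyond the operative label.
* The synthetic cohorts cannot stand in for prospective validation; see
  the corridor discussion above.
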