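---
title: "Methods: the five-feature CT score for diffuse thyroid disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the five-feature CT score for diffuse thyroid disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyroCT)
```

## The score and its assumptions

Diffuse thyroid disease (DTD) — Hashimoto thyroiditis, non-Hashimoto
lymphocytic thyroiditis, diffuse hyperplasia — alters the whole gland rather
than forming nodules. On neck CT this manifests as lower parenchymal
attenuation (lymphocytic infiltration and follicular loss reduce the iodine
content that gives normal thyroid its high HU), textural inhomogeneity,
glandular enlargement, marginal lobulation and inhomogeneous enhancement.
The score simply counts these five binary findings and calls a gland
DTD-positive when at least `k` of them are present.

Assumptions worth making explicit:

* **The reference standard is histopathology** of surgical specimens; the
  DTD label of every record is *derived* from the histopathology class
  (`histopath_class != "normal"`), never stored separately, so label and
  class can never disagree.
* **The five-feature list is literal.** Heterogeneous patterns (focal
  deviations, e.g. from adjacent nodular disease) and decreased size are
  recorded but are *not* abnormal under the counting rule; only the five
  listed categories raise flags. Whether a radiologist would count
  heterogeneous attenuation as abnormal is genuinely open; we follow the
  literal list and preserve the category in all reports.
* **Enhancement degree carries no flag.** The enhanced-minus-nonenhanced HU
  difference is similar in normal (≈ 88 HU) and DTD (≈ 93 HU) glands; it is
  computed (`enhancementDegree()`) and reported only.

## Tunable parameters

All thresholds live in `classifierConfig()`:

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `lowHuCutoff` | 100 | HU | attenuation degree is *low* iff HU < cutoff |
| `highHuCutoff` | 180 | HU | *high* iff HU > cutoff; 100–180 inclusive is *iso* |
| `sizeBand` | [1, 2] | cm | mean AP diameter band called *normal* (inclusive) |
| `k` | 3 | features | positivity threshold of the counting rule |
| `comparison` | `less_or_equal` | — | convention for HU cut-off *sweeps* |

Boundary semantics deserve a note. The *feature* rule is strict
(`HU < 100` is low; a measurement of exactly 100 is iso), while published
cut-off sweeps label rows "100 or less". Both conventions are supported via
`comparison`; on continuous HU data they differ only on exact ties. The
reference cohort contains exactly one subject at 100.0 HU — the two
conventions differ by exactly that one record, which is why both appear in
the published counts (27 vs 28 normals below cut-off).

Display rounding is half-up to one decimal for percentages and four decimals
for AUCs (`roundHalfUp()`), matching the reference tables; R's default
round-half-even would print some cells differently.

## The synthetic cohort generator

`sampleCohort()` emulates the study population: class sizes 157/17/34/1
(normal / Hashimoto / non-Hashimoto LT / diffuse hyperplasia), per-class
Gaussian HU (normal 114.3 ± 21.2 nonenhanced, 202.5 ± 29.3 enhanced; DTD
94.5 ± 21.3, 187.6 ± 29.9 — all three DTD classes share these, as only
normal-vs-DTD marginals are published) and per-class categorical frequencies
from the published frequency table. HU values are sampled untruncated:
±5 SD excursions are harmless, and truncation would bias the means the
generator is calibrated to.

Two design choices:

* **Attenuation degree is never sampled.** It is derived from the sampled
  HU by the banding rule, so the profile invariant (degree consistent with
  HU) holds by construction. Its implied marginal — Φ((100 − μ)/σ), about
  60% low for DTD — is close to, but not exactly, the published 65.4%; the
  published degree frequencies and the published HU moments are not exactly
  compatible under a Gaussian model, and we treat the HU moments as primary
  for sampled cohorts (the fixtures, below, hit the categorical counts
  exactly instead).
* **Features are independent by default**, because only marginals are
  published. The observed distribution of abnormal counts implies positive
  inter-feature correlation, so a single-parameter latent-threshold coupling
  is exposed (`correlation` in `cohortParams()`): one standard-normal latent
  per patient, Gaussian-copula-linked to every categorical feature (abnormal
  categories in the upper tail) and to the nonenhanced HU with negative
  loading (low HU is the abnormal direction). Marginals are preserved
  exactly for any correlation strength.

What passing tests on generated cohorts do **not** show about real data:
real HU distributions are not exactly Gaussian, real feature dependence is
not exchangeable single-factor, and reader variability is absent entirely.
The generator validates the *machinery*, not the clinical claim.

## The 209-patient fixtures

Two published summaries of the same cohort disagree slightly: the
per-threshold confusion table reports 46/40/29 DTD and 84/27/7 normals at
≥ 1/2/3 abnormal features, while the results narrative reports totals
98/50/31/15/5 with per-class breakdowns (implying 44/37/26 DTD and 54/13/5
normals). The discrepancy is unexplained in the source. Rather than choose,
`reconstructFixtureCohort()` ships both as modes — `"table4"` (the
confusion-table version, which matches the headline abstract numbers and is
the acceptance anchor) and `"section3"` (the narrative version, which is
nearly consistent with the feature-frequency marginals).

Reconstruction proceeds in three deterministic steps:

1. **Level counts.** The ≥ k chains are differenced into exact per-count
   levels per class. Cells the mode does not pin down are filled from the
   other summary (table4 mode takes k ≥ 4 levels from the narrative) or by
   largest-remainder allocation (the narrative never splits the five
   all-feature cases by class; 3:2 Hashimoto:non-Hashimoto follows their
   7:6 membership at ≥ 4).
2. **Greedy feature assignment.** Patients in descending count order take
   their `c` features from the largest remaining per-group quotas (the
   published abnormal-feature totals), ties broken in the feature order of
   the frequency table. This is a classic max-remaining construction for
   degree-constrained 0/1 matrices; where the constraint set is infeasible
   the quotas go negative and the achieved L1 distance to the published
   marginals is attached to the cohort (`fixtureResidual()`), never hidden.
   In section3 mode the instance totals are 73 vs 72 (normals) and 126 vs
   125 (DTD), so the achieved residual of 1 per group is the provable floor;
   in table4 mode the conflict is larger (119 vs 72, 134 vs 125) and the
   residual is reported accordingly.
3. **HU assignment.** Low-attenuation patients receive HU values in the
   bands the published cut-off sweep implies (≤ 80 / 80–90 / 90–100); one
   iso normal sits at exactly 100 HU; remaining iso patients sit mid-band.
   Enhanced HU adds the per-class mean enhancement degree.

The sum-of-thresholds identity — Σ_k #{count ≥ k} equals the total number of
abnormal feature instances — is audited by brute force
(`abnormalInstanceAudit()`) and holds for every cohort by construction of
the flag matrix.

Known inconsistencies in the printed source, found while encoding the
tables, are documented in the test helpers rather than reproduced: the
90-HU row's specificity/PPV cells disagree with the confusion counts its
sensitivity, NPV and accuracy cells jointly pin down (87.9/56.8 computed vs
88.5/58.1 printed), one feature-table specificity prints 14.7 for 23/157 =
14.6, and one frequency prints 65.6 for 34/52 = 65.4.

## Operating-point selection

Each rule in this system is a single binary classifier, so its ROC curve has
one interior point and the trapezoidal area is (Se + Sp)/2 — balanced
accuracy (`twoPointAuc()`). This reproduces three of the six published AUCs
exactly (0.6091, 0.7378, 0.7566); the other three (0.6831, 0.6238, 0.5421)
do not equal (Se + Sp)/2 of their own rows under any convention we could
identify and are not reproduced.

Selection uses two different criteria deliberately:

* **best HU cut-off: maximal two-point AUC** (ties toward the larger
  cut-off, the higher-sensitivity point). All three published cut-offs tie
  on accuracy at 78.0%, so only an ROC criterion can order them; it selects
  100 HU.
* **best count threshold: maximal accuracy** (ties toward larger k, the
  more specific rule). Two-point AUC would rank k = 2 (0.799) above k = 3
  (0.757), contradicting the source's own conclusion, whereas accuracy peaks
  unambiguously at k = 3 (85.6%).

AUC confidence intervals use the Hanley–McNeil standard error, clipped to
[0, 1]. On the table4 fixture the HM SE (0.042) is conservative relative to
a nonparametric patient-resampling bootstrap of the two-point AUC (0.035);
the test suite asserts concordance within 0.01 absolute. The published 95%
CIs match neither form and are reported by the package's own method, not
asserted against the source.

Chi-square comparisons use the Pearson statistic without continuity
correction after dropping unobserved categories (df = retained rows − 1);
the logistic cut-off analysis is a maximum-likelihood univariate fit by
iteratively reweighted least squares (≤ 25 iterations, tolerance 1e-8), with
complete separation reported via a flag rather than an error. The published
size-comparison P = 0.0749 cannot be reproduced by Pearson chi-square on any
printed arrangement of the size table and is not a target.

## The phantom model

`generatePhantom()` builds a two-phase HU raster: two elliptical-cylinder
lobes (left–right semi-axis 7 mm by default; AP semi-axis set by the ground
truth diameter) flanking an 8 mm air trachea on a 60 HU soft-tissue
background, voxel spacing 0.5 × 0.5 × 3 mm (3 mm slices). The axial-plane
convention is: first axis left–right, second axis anteroposterior; AP
diameters are measured along the second axis on the mid-lobe slice.

* **Margin.** Lobulation perturbs the boundary radius by
  1 + A·cos(mθ). The extraction statistic is the convexity deficiency
  1 − area(mask)/area(hull) with the hull over pixel centres, clamped at 0,
  so digitised convex shapes score exactly 0. The default decision threshold
  is 0.02. Calibration on generated shapes: the continuous deficiency at
  A = 0.15 is 0.0078 (m = 3), 0.047 (m = 4), 0.089 (m = 5) — three
  undulations at that amplitude are barely concave and undetectable at any
  sensible threshold, so the calibrated claim is separation for m ≥ 4, and
  the profile-to-phantom mapping uses A = 0.2 with m = 5. A threshold of
  1.0 degenerates to "always smooth".
* **Texture and the pattern rule.** Parenchymal inhomogeneity is a smooth
  Gaussian random field (white knots trilinearly interpolated at the
  configured scale), normalised to the requested SD inside the lobes, with a
  per-phase amplitude. The pattern rule calls a lobe *heterogeneous* if a
  connected region ≥ 10% of the mid-slice lobe area deviates ≥ 50 HU from
  the lobe median, else *inhomogeneous* if the within-lobe SD — after
  subtracting the configured sensor-noise SD in quadrature — exceeds 15 HU.
  The two sub-rules interact: a smooth field of SD 40 HU almost always
  contains a ≥ 50 HU blob of ≥ 10% area in a lobe this size (23/30 seeds),
  so high-amplitude texture is indistinguishable from focality. The
  profile-to-phantom mapping therefore uses 20 HU at 4 mm scale (0/200
  spurious focal calls; SD comfortably above the 15 HU boundary), and focal
  ground truth is generated with explicit lesions (−80 HU spheres sized to
  ~14% of the mid slice).
* **ROI measurements and mean preservation.** The default ROI is a round
  disc at the lobe centroid with radius 40% of the smaller semi-axis, and
  any ROI must clear the mask boundary by one voxel (partial-volume edge
  voxels never enter the mean). The texture field is re-centred to zero mean
  over each lobe's default ROI disc, so the ground-truth mean attenuation —
  defined as the centroid-ROI measurement — is preserved at any texture
  amplitude. Focal lesions are parked laterally in a widened lobe so they
  never overlap the ROI. These two choices make the imaging path and the
  tabular path *exactly* equivalent in the noiseless case, which the test
  suite exploits: the tabular evaluation of a cohort is the oracle for the
  evaluation of phantoms generated from the same profiles, down to identical
  confusion counts at 400 patients.

The phantom emulates the measurement setting, not CT physics: no beam
hardening, no contrast kinetics, no partial-volume blur beyond
voxelisation, and the margin/pattern thresholds stand in for a radiologist's
visual judgement — no claim is made that they match the human reader.

## Problem sizes and numerical conventions

Generator convergence tests use n = 10,000 with 3-standard-error
tolerances; the copula test uses n = 4,000 per arm; logistic recovery uses
n = 5,000 within 3 SE; the chi-square closed-form equivalence runs 1,000
random 2×2 tables; the imaging-vs-tabular equivalence runs 400 phantoms
(200 normal, 200 DTD). Phantom grids are sized automatically from the
geometry (typically ~120 × 50 × 9 voxels). All stochastic operations take an
explicit integer seed and restore the caller's RNG state; identical seeds
give byte-identical outputs, which the suite asserts.

## Known limitations

* The published cohort cannot be fully reconciled with itself (narrative vs
  confusion table vs frequency marginals); both fixture modes are exact for
  their own anchor and carry explicit residuals against the rest.
* Three published AUCs and all published AUC confidence intervals follow an
  unidentified computation and are not reproduced.
* The generator's independence default understates real feature co-occurrence;
  the correlation knob is a modelling convenience, not a fitted quantity.
* Phantom-derived margin/pattern thresholds are calibrated to the phantom
  family itself; applying them to real CT would require re-calibration
  against reader judgements.
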