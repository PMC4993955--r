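---
title: "Bone shape vectors and matched case-control inference: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone shape vectors and matched case-control inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tkrshape)
```

This vignette is the package's account of the science it implements: the
shape model and scoring rule, the matched case-control machinery around it,
what the synthetic data generator does and does not emulate, and the design
choices made where the methodology left the design genuinely open.

## 1. The shape model and the OA vector

The input to the shape module is a set of corresponded 3D bone point clouds:
every sample of a given bone has the same number of points, and point *i*
marks the same anatomical location on every bone (the output format of an
active appearance model search; the segmentation step itself is out of
scope). Model building proceeds in three steps.

**Rigid generalized Procrustes alignment** (`gpaAlign()`). Each shape is
centred and rotated to a running mean that is re-estimated until it moves
less than `tol = 1e-7` mm per point on average (at most 100 iterations).
Scaling is deliberately *not* removed: osteophytic ridge growth and overall
bone-area expansion are disease signal the score must retain, so only
translation and rotation are quotiented out. The iteration is initialized at
the coordinate-wise mean of the centred input so that alignment is
idempotent — re-aligning an aligned set is a no-op rather than an arbitrary
global rotation. (If the initial mean is nearly degenerate, which can happen
when poses cancel, the first shape is used as the starting reference
instead.)

**Principal components** (`fitShapeModel()`). The aligned coordinate matrix
(samples × 3N) is centred and decomposed by SVD. The basis is truncated at
the smallest number of components explaining at least `varFrac` of total
variance. The default is 0.98: high enough that the group-mean geometry
survives truncation essentially intact, low enough to drop the pure-noise
tail; the original methodology does not state a truncation, so this is a
package decision exposed as a parameter. Component signs are fixed
(largest-magnitude loading positive) so fits are reproducible across
platforms. Training shapes without a KL grade are excluded — group
membership requires a label — and a fit is refused when either KL group is
empty or the two group means coincide.

**The OA vector and the score** (`scoreShapes()`). With `m_nonOA` and `m_OA`
the PC-score vectors of the two group mean shapes, a new shape with scores
`p` receives

$$ b \;=\; \frac{2\,(p - m_{nonOA})\cdot u}{\lVert m_{OA}-m_{nonOA}\rVert} - 1,
\qquad u = \frac{m_{OA}-m_{nonOA}}{\lVert m_{OA}-m_{nonOA}\rVert}. $$

The projection is orthogonal, so any component of `p` perpendicular to the
line does not move `b`; the affine map puts the training non-OA mean at −1
and the OA mean at +1 exactly (tested to 1e-8). The vector lives in
truncated PC-score space, not raw coordinate space, matching the definition
of the group means as principal-component representations. Scoring rigidly
aligns the input to the model mean first (`align = TRUE`); because every
training shape is optimally aligned to the Procrustes mean at convergence,
the group-mean shapes are stationary under this alignment and the
normalization identity survives it.

**Reliability metrics.** `pointToSurfaceError()` is the segmentation
accuracy metric (mean minimum distance from points to a triangulated
reference surface, exact point-to-triangle distances via the Voronoi-region
algorithm); `smallestDetectableDifference()` is the test-retest noise floor,
`1.96 × sd(test − retest)`, i.e. the 95% Bland–Altman limit in normalized
score units.

## 2. The matched case-control machinery

**Eligibility and selection** (`selectCohort()`). Cases are knees with a
confirmed replacement and an OA indication; a recorded rheumatoid-arthritis
indication excludes the knee. Where the indication is unrecorded, "OA highly
likely" is operationalized as baseline KL ≥ 2 *and* pain NRS ≥ 1 — the
source criterion is verbal, so the thresholds are a package decision.
Participants contribute their first-replaced knee; same-day ties are broken
uniformly at random under the run seed so results stay reproducible. Both
arms require complete baseline records (age, gender, pain, weight, KL) and
usable shape data; every exclusion is logged with exactly one reason. Among
a participant's surviving knees the control knee is the one with higher
pain, the right knee on ties; the surviving knee of a case participant may
serve as a control (contralateral controls are legitimate in this design).

**Propensity model and matching** (`fitPs()`, `matchPairs()`). The
stratification score is a maximum-likelihood logistic regression of case
status on age band (5-year bands, 75+ top), gender, merged WHO weight
category (normal/underweight, overweight, obese), continuous pain NRS and
knee side. KL grade is excluded by design. Aliased columns are an error
naming the columns; suspected separation is a warning carried in the model
object. Matching is greedy nearest-neighbour without replacement on the
probability scale: cases in descending score order (ties by knee id), each
taking the unused control with smallest absolute score difference (ties by
knee id, detected with a 1e-12 tolerance so float noise cannot hide them).
Greedy-descending was chosen because the original ordering is unstated and
determinism is required for testing; no caliper is imposed — instead the
number of exact matches at two decimals and the maximum matched difference
are reported as outcomes. Balance is assessed with standardized differences
on the *raw* continuous covariates (age, BMI, pain; threshold 10%) and on
dichotomous prevalence (gender, side; threshold 0.1).

**Matched inference** (`pairedT()`, `fitClr()`, `compareAic()`,
`assignTertiles()`, `stratifiedClr()`). The paired t-test is computed from
the textbook formulas, returning a flagged degenerate result when the
difference SD is zero. Conditional logistic regression maximizes the exact
1:1 conditional likelihood by Newton–Raphson from β = 0 with step halving
(score tolerance 1e-8, 50 iterations). Concordant pairs contribute the
constant log(1/2) and are counted separately. Divergence handling is
explicit because conditional likelihoods are monotone on sign-concordant
discordant pairs, *and* the score tends to zero along the divergent path —
so apparent gradient convergence at an extreme estimate (|β| > 15, or Wald
variance > 1e4) is reported as an error, never as an estimate. Wald
intervals mirror the OR (95% CI) presentation convention. The AIC comparator
(`AIC = 2k − 2ℓ`) refuses to rank fits on different pair samples; inside the
pipeline all compared models are refitted on the common complete-KL pair
set. The comparator enforces equal *pair* counts rather than equal
informative-pair counts: on an identical sample a KL-dummy model legitimately
has fewer discordant pairs than a continuous-score model, and the concordant
pairs it keeps contribute only a constant. Tertile cut points are the 1/3
and 2/3 empirical quantiles of the pooled matched baseline scores (the
quantile population is unstated in the source; pooling cases and controls is
the package decision), lower-open/upper-closed so cut-point ties fall
downward. Stratified analyses subset existing pairs by the case knee's
stratum (KL grade, or time-to-surgery band) rather than re-matching; strata
that are empty or divergent are logged and skipped, and strata with fewer
than 10 informative pairs are flagged wide-CI.

## 3. The synthetic cohort generator

`generateCohort()` draws an OAI-like cohort from explicit distributions
under one seed: 4,800 participants (two knees each), truncated-normal age
(61 ± 9 on [45, 80)), 58% female, log-normal BMI giving roughly 25% normal /
38% overweight / 37% obese, and a latent per-knee OA **severity** — the
single construct that drives everything downstream:

* severity = 0.04·(age − 61) + weight-category step (0.12 overweight, 0.25
  obese) + correlated Gaussian noise (SD 1.0; within-participant correlation
  0.6, since contralateral knees share anatomy and exposures);
* KL grade thresholds severity at (−0.45, 0.05, 0.75, 1.65) (≈ 33/17/25/18/7%
  across grades 0–4), with 5% missingness;
* pain NRS = round(3 + 1.1·severity + N(0, 1.8²)) clamped to 0–10;
* TKR log-odds = calibrated intercept + 0.55·severity + 0.25·(KL − 2)
  + 0.025·(age − 61) + 0.25·female + 0.08·(pain − 3) + weight-category step
  (0.30 overweight, 0.60 obese). The intercept is solved numerically so the
  marginal participant-level incidence hits the 7% target.

Two structural choices deserve explanation. First, weight acts on severity
and on the outcome through the WHO *category*, not per BMI unit. The
propensity model can only see the category; a strong within-category BMI
gradient would build in confounding that category matching cannot remove,
which contradicts the near-perfect post-match weight balance the design is
known to achieve. The per-unit coefficients remain in `simConfig()` for
sensitivity analyses, defaulting to zero. Second, the outcome model includes
a *direct* KL effect on top of severity, because the radiographic grade is
what the surgeon actually sees — the very reason KL is excluded from the
propensity model. This is also what makes KL adjustment genuinely attenuate
the shape-vector odds ratio rather than merely re-partitioning an identical
signal.

Shapes (`generateShape()`) are deterministic superellipsoid-like templates
per bone (femur/tibia/patella semi-axes ≈ 45/38/22 mm), sampled at 500
points on a Fibonacci lattice, deformed by a fixed "marginal ridge" field —
outward displacement concentrated in a band around the equatorial margin
plus a small uniform expansion, emulating osteophytic ridge growth — whose
amplitude is the knee's **shape severity**: latent severity plus independent
N(0, 0.25²) biological variation. The bio-noise term encodes that
radiographic grade and bone shape are correlated but distinct expressions of
disease; its SD is bounded above by the requirement that scores still track
latent severity with rank correlation > 0.95 (realized ≈ 0.96–0.97). On top
sit five smooth nuisance modes with a decaying amplitude spectrum
(0.8·0.7^(k−1) mm), per-coordinate Gaussian measurement noise (0.3 mm,
settable to 0 for noiseless-retest checks), and a random rigid pose that the
scoring alignment must undo. Training sets reproduce the 53 OA / 43 non-OA
split of 96 labelled shapes (the source's "equal numbers per KL grade"
cannot produce 53/43 of 96; the reported split wins), with severities drawn
uniformly within each grade's bin. Test-retest replicates share severity and
nuisance coefficients and differ only in measurement noise and pose.

**What the generator does not emulate:** real femoral anatomy (the ridge
field is a stylized margin, not an anatomical osteophyte atlas), MRI signal
or segmentation failure modes, longitudinal shape change, BMI drift before
surgery, and ethnicity structure. Passing tests therefore demonstrate that
the *pipeline machinery* — alignment, scoring, matching, conditional
inference — behaves correctly under a faithful statistical structure, not
that the synthetic effect sizes equal those of any real cohort.

## 4. Numerical choices, degenerate inputs, problem sizes

* Kabsch rotations via SVD with a determinant guard against reflections;
  all-coincident point sets are rejected.
* GPA tolerance 1e-7 mean displacement, max 100 iterations; PC sign
  convention fixed; model serialization writes full-precision JSON so a
  round trip moves scores by < 1e-10.
* Propensity matching ties resolved lexicographically at 1e-12 tolerance;
  the control pool running dry is an error reporting the shortfall.
* Zero pooled SDs in balance reports yield `NA` ("undefined"), not 0.
* Tertiles require ≥ 3 distinct values and non-coincident cut points.
* The test suite runs the study-scale cohort (4,800 participants) for the
  matching-balance and attenuation properties, 100 and 20 seeded replicates
  respectively; parameter-recovery uses 1,000 replicates of 300 pairs per
  effect size; shape-model unit tests run at reduced size (120 points, 24–48
  training shapes) where the property under test does not depend on scale.

Two boundary notes, so the test expectations are read correctly. The
balance property (all matched standardized differences below threshold in
≥ 95% of seeds) sits near its theoretical ceiling by construction: with
~290 pairs and a category-based propensity model, the irreducible
within-category BMI noise alone gives a standardized-difference SD of ~4%,
i.e. ~1% of seeds exceed 10% on BMI even under perfect category matching.
The realized rate over the canonical seed set is 95–98%. Second, the
attenuation property (KL-adjusted shape OR closer to 1 than unadjusted)
follows from the generator's structure — a direct KL effect plus imperfect
shape-severity coupling — and held in every development seed; it is tested
over 20 seeds at full scale.

## 5. Known limitations

The active appearance model itself (texture learning, automated MRI search)
is out of scope: the package consumes corresponded point clouds. Matching is
greedy, not optimal; the exhaustive-assignment comparison exists only as a
test oracle. Survival modelling of time to replacement is deliberately
absent — the nested case-control design with a rare outcome is the method
implemented. Missing KL grades are handled by complete-case restriction for
adjusted models (with the AIC comparator enforcing a common sample), not by
imputation. Pipeline leverage diagnostics are limited to explicit
divergence/failure logs per fitted model rather than per-pair influence
plots.
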