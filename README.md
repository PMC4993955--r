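# tkrshape

Quantitative 3D bone shape analysis for knee osteoarthritis (OA), and the
matched case-control machinery to relate it to total knee replacement (TKR).

## The problem

Radiographic OA severity is usually summarized by the ordinal
Kellgren–Lawrence (KL) grade, which is coarse and insensitive to early or
progressive structural change. Statistical shape modelling of MRI-segmented
bone surfaces offers a continuous alternative: across a KL-labelled training
set of corresponded bone point clouds, the mean OA (KL 2–4) and mean non-OA
(KL 0–1) shapes define a direction in principal-component shape space — an
"OA vector". Any knee's bone shape can be projected orthogonally onto that
line and expressed as a single scalar *b*, scaled so that the mean non-OA
training shape sits at −1 and the mean OA shape at +1:

```
p   = PC scores of the (rigidly aligned) shape
u   = (m_OA − m_nonOA) / ‖m_OA − m_nonOA‖
b   = 2 · (p − m_nonOA)·u / ‖m_OA − m_nonOA‖ − 1
```

The epidemiological question — is bone shape associated with the hard
endpoint of knee replacement? — is answered with a nested case-control
design: TKR case knees are matched 1:1 to surviving control knees on a
propensity (stratification) score estimated from age band, gender, WHO
weight category, pain NRS and knee side (KL grade deliberately omitted:
surgeons act on it directly, and it is correlated with the shape vector),
followed by paired t-tests, conditional logistic regression (CLR) fitted
from the 1:1 conditional likelihood, AIC model comparison, and tertile odds
ratios.

`tkrshape` implements the whole chain — shape space, scoring, reliability
metrics, eligibility rules, propensity matching with standardized-difference
balance diagnostics, and matched-pair inference — plus a seeded synthetic
cohort generator that emulates the structure of an OAI-like study (latent OA
severity driving shape, KL, pain and a confounded TKR outcome), so the full
workflow runs end-to-end with no external data.

## Worked example

```r
library(tkrshape)

res <- runPipeline(simConfig(), seed = 11, verbose = FALSE)

res$counts$n_pairs
#> [1] 284

res$paired_t[, c("bone", "control_mean", "case_mean", "mean_diff")]
#>      bone control_mean case_mean mean_diff
#> 1   femur       0.2533    1.0133    0.7600
#> 2   tibia       0.2014    0.9333    0.7319
#> 3 patella       0.1844    0.9078    0.7234
```

Case knees sit markedly closer to the mean OA shape (+1) than their matched
controls on every bone — the paired mean difference of ~0.8 normalized units
is the synthetic analogue of the case-control contrast the design is built
to detect. Conditional logistic regression expresses the same signal as an
odds ratio per normalized unit, before and after KL-grade adjustment:

```r
res$or_tables$femur_univariable[, c("term", "or", "or_low", "or_high")]
#>        term     or or_low or_high
#> femur femur 2.3741 1.8816  2.9956

res$or_tables$femur_adjusted[1, c("term", "or", "or_low", "or_high")]
#>        term     or or_low or_high
#> femur femur 1.7342  1.099  2.7366
```

Adjusting for KL attenuates the OR toward 1 (here 2.37 → 1.73): KL grade and
the shape vector are correlated expressions of the same underlying disease,
so the adjusted coefficient isolates only the shape information beyond the
radiographic grade. Balance diagnostics, the AIC model ranking, tertile odds
ratios and exploratory stratified fits are all in the returned bundle (see
`?runPipeline`), and `outputDir=` writes the CSV/JSON report files. A thin
command-line wrapper lives at `inst/scripts/run_pipeline.R`.

Individual stages are ordinary functions: `generateCohort()`,
`selectCohort()`, `fitPs()`/`matchPairs()`/`balanceReport()`,
`gpaAlign()`/`fitShapeModel()`/`scoreShapes()`,
`pairedT()`/`fitClr()`/`compareAic()`/`assignTertiles()`, and
`smallestDetectableDifference()` for test-retest reliability.

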