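# CPDscreen

Rule-based screening of haematological neoplasms from leukocyte cell
population data (CPD), the per-population VCS statistics
(volume, conductivity, multi-angle light scatter) that modern full
blood count analysers report on every routine differential.

## The scientific problem

Neoplastic marrow disorders change the morphology of circulating
leukocytes in ways the analyser's single-cell measurands capture
before a smear is ever made: neutrophil volume becomes heterogeneous
(SD-V-NE rises), granularity falls (MN-C-NE drops), lymphocyte
upper-median-angle scatter rises (MN-UMALS-LY), monocyte axial-loss
spread widens (SD-AL2-MO). `CPDscreen` implements a published
screening cascade built on these shifts:

1. a **composite neoplastic score**

   S = (SD-V-NE × MN-UMALS-LY × SD-AL2-MO) / MN-C-NE,  flag if S > 106.44

2. a **reactive discriminant** on MN-AL2-NE (cutoff 147.5) that rules
   out infective/inflammatory cases among stage-1 positives, and
3. advisory **subtype flags** (AML, APL, ALL, CLL) from seven
   single-parameter rules.

All comparisons are strict; a score exactly at a cutoff is negative.
Every decision leaves an audit row.

Alongside the published constants, the package ships the full
**calibration pipeline** that derives such discriminants from any
labelled CPD cohort (Welch-*t* screening → ROC with DeLong CIs → AUC
gate → Youden cutoff → composite construction), **diagnostic-accuracy
statistics** with continuity-corrected Wilson intervals, and a seeded
**synthetic cohort simulator** so the whole pipeline can be exercised
end-to-end without patient data.

## Worked example

```r
library(CPDscreen)

## simulate a study-sized labelled cohort (1348 samples x 56 parameters)
cohort <- generateCohort(paperLikeConfig(seed = 1))

## re-derive the screening discriminants from it
screen <- screenParameters(cohort, list(positive = "neoplastic",
                                        negative = "non-neoplastic"))
screen[screen$selected, c("parameter", "auc", "cutoff", "orientation")]
#> DataFrame with 4 rows and 4 columns
#>     parameter       auc    cutoff      orientation
#>   <character> <numeric> <numeric>      <character>
#> 1     SD-V-NE  0.974382   19.3302 high_is_positive
#> 2   SD-AL2-MO  0.956290   16.1999 high_is_positive
#> 3 MN-UMALS-LY  0.945248   59.7488 high_is_positive
#> 4     MN-C-NE  0.935771  147.9110  low_is_positive

buildComposite(cohort, list(positive = "neoplastic",
                            negative = "non-neoplastic"), screen)$rule
#> DiscriminantRule 'composite': (SD-V-NE x SD-AL2-MO x MN-UMALS-LY) / (MN-C-NE) > 122.1 -> 'neoplastic' (else 'non-neoplastic')

## classify one sample through the published cascade
rec <- CPDRecord(c(`SD-V-NE` = 25, `MN-UMALS-LY` = 70, `SD-AL2-MO` = 20,
                   `MN-C-NE` = 140, `MN-AL2-NE` = 140))
cascadeClassify(rec)
#> CascadeResult 'sample': composite score 250 -> stage1 neoplastic -> stage2 neoplastic
#>   subtype flags: ALL=not-evaluated, AML=not-evaluated, APL=not-evaluated, CLL=not-evaluated
#>   audit trail: 9 rule evaluations

## diagnostic accuracy with continuity-corrected Wilson CIs
accuracyStats(ConfusionCounts(tp = 262, fp = 2, fn = 4, tn = 16))
#> AccuracyStats (wilson-cc 95% CI)
#>   sensitivity   98.50%  (95% CI: 0.96, 1.00)
#>   specificity   88.89%  (95% CI: 0.64, 0.98)
#>   ppv           99.24%  (95% CI: 0.97, 1.00)
#>   npv           80.00%  (95% CI: 0.56, 0.93)
```

A command-line front end with `simulate`, `calibrate`, `classify` and
`validate` subcommands is installed at
`system.file("scripts", "cpdscreen.R", package = "CPDscreen")`.

## Documentation

The methods vignette (`vignettes/cpd-screening.Rmd`) describes the
model, the calibration pipeline, what the simulator does and does not
emulate, the numerical choices, and the provisional rule orientations.

## Limitations

The shipped cutoffs are instrument-specific constants requiring local
revalidation; subtype flags are advisory; this is a research tool, not
a medical device.
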