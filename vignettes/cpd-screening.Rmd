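---
title: "Screening haematological neoplasms from cell population data"
author: "CPDscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening haematological neoplasms from cell population data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CPDscreen)
```

## Background and model

Volume–conductivity–scatter (VCS) full blood count analysers report,
for each leukocyte population, the mean (`MN-`) and standard deviation
(`SD-`) of several single-cell measurands: cell volume (`V`),
conductivity (`C`), and light scatter at several angles (`MALS`,
`UMALS`, `LMALS`, `LALS`, `AL2`). These *cell population data* (CPD)
parameters are produced on every routine differential at no extra
cost, and shifts in them track the morphological changes a reviewer
would look for on a smear: neoplastic neutrophil populations become
heterogeneous in volume (`SD-V-NE` rises), hypogranular (`MN-C-NE`
falls), and so on.

A parameter is named `<statistic>-<channel>-<cellType>`, e.g.
`MN-UMALS-LY` is the mean upper-median-angle light scatter of the
lymphocyte population. `CPDscreen` canonicalises the common dialects:

```{r}
normalizeParameterName(c("mn_umals_ly", "MNV", "MNV-SD"))
```

All units are the analyser's internal channel units; the package
treats them as dimensionless positive reals and never rescales them.

## The decision cascade

The package implements a published three-stage screening cascade:

1. **Composite neoplastic score.** The product–quotient
   $$S = \frac{\text{SD-V-NE} \times \text{MN-UMALS-LY} \times
   \text{SD-AL2-MO}}{\text{MN-C-NE}}$$
   flags a sample as presumptively neoplastic when $S > 106.44$.
   Comparisons are strict: a score exactly at a cutoff is always the
   negative label.
2. **Reactive discriminant.** Stage-1 positives are tested on
   `MN-AL2-NE` against a cutoff of 147.5 to rule out reactive
   (infective/inflammatory) cases.
3. **Subtype flags.** Confirmed neoplastic samples receive advisory
   per-subtype flags (AML, APL, ALL, CLL) from seven single-parameter
   rules. These are advisory only and never alter the screening call.

```{r}
rec <- CPDRecord(c(`SD-V-NE` = 25, `MN-UMALS-LY` = 70, `SD-AL2-MO` = 20,
                   `MN-C-NE` = 140, `MN-AL2-NE` = 140, `SD-MALS-NE` = 20,
                   `SD-UMALS-NE` = 20, `MN-V-NE` = 165, `SD-V-MO` = 38,
                   `MN-MALS-NE` = 120, `MN-LMALS-NE` = 115, `SD-C-MO` = 9),
                 sampleId = "example")
res <- cascadeClassify(rec)
res
```

Every stage that runs leaves an audit row recording the rule, its
inputs, the score and the comparison performed; stages after a
negative stage-1 call are never evaluated (short-circuit), so their
absence from the audit trail is meaningful.

### Provisional orientations

The published work states cutoffs for the reactive discriminant and
the subtype rules but not, in every case, the direction of the
comparison. The shipped registry (`inst/extdata/published_rules.yaml`)
records these orientations explicitly and marks the inferred ones as
provisional in a `provisional_orientations` block. A rule whose
orientation is unset (`NA`) refuses to classify rather than guessing:

```{r, error = TRUE}
unset <- discriminantRule("demo", "MN-AL2-NE", cutoff = 147.5)
applyRule(CPDRecord(c(`MN-AL2-NE` = 140)), unset)
```

## The calibration pipeline

`screenParameters()` reproduces the derivation route on any labelled
cohort: each parameter is tested for a between-class difference
(Welch's *t* by default; two-sided, $\alpha = 0.05$), and survivors
are ranked by empirical ROC AUC, gated at AUC $> 0.9$. The AUC is the
Mann–Whitney tie-corrected estimate; `rocCurve()` delegates the sweep
to **pROC** but chooses the orientation so the AUC is at least one
half, and the package's tests verify the result against brute-force
pair counting. Confidence intervals are DeLong by default
(Hanley–McNeil by flag).

`selectCutoff()` picks the operating point by maximum Youden's $J$,
breaking ties first by minimum $|sens - spec|$ and then by the lower
threshold; a constrained policy (`sens` and `spec` both $\ge 0.8$)
errors with "infeasible" when no such point exists rather than
silently degrading. `buildComposite()` then forms the product–quotient
(high-is-positive parameters in the numerator, low-is-positive in the
denominator) and re-derives a cutoff, reported at two decimals.

For multi-group comparisons, `multiGroupScreen()` branches on
Levene's test (mean-centred): homogeneous variances go to one-way
ANOVA with Tukey HSD, heterogeneous ones to Welch's ANOVA with
Games–Howell post-hoc tests. With two groups the Games–Howell
statistic reduces exactly to Welch's *t*, which the tests assert.
`ksNormality()` (Lilliefors) requires at least 5 observations — the
smallest sample size the reference implementation supports.

Diagnostic accuracy uses the defining ratios with continuity-corrected
Wilson 95% intervals (`wilsonCCInterval()`, equivalent to
`stats::prop.test(correct = TRUE)`), clamped to $[0, 1]$; zero
denominators yield `NA`, never 0 or 1.

## The synthetic cohort simulator

Because CPD cohorts are patient data, the package ships a seeded
generator for end-to-end testing. `paperLikeConfig()` encodes the
study conditions: the exact group roster (1056 normal, 47 reactive,
62 AML, 30 APL, 54 ALL, 47 lymphoma, 28 CLL, 12 CML, 12 MDS; 1348
samples), truncated-normal marginals for `MN-` parameters and
lognormal marginals for `SD-` parameters (specified by natural-scale
mean and SD), healthy baselines per statistic/channel, and shifted
marginals for the discriminating parameters in the affected groups.
An optional single-factor term (`corFactor`) induces within-cell-type
correlation. `pureNoiseConfig()` draws both classes from identical
baselines, so any discriminant it "finds" is a false positive — the
tests use it to verify the screen's false-discovery behaviour at its
nominal level.

```{r}
cohort <- generateCohort(paperLikeConfig(seed = 1))
screen <- screenParameters(cohort, list(positive = "neoplastic",
                                        negative = "non-neoplastic"))
screen[screen$selected, c("parameter", "auc", "cutoff", "orientation")]
```

The generator emulates the *marginal* locations and scales that drive
the published discriminants; it does not attempt instrument noise
models, inter-parameter correlation structure beyond the optional
single factor, age/sex covariates, or the within-subtype heterogeneity
of real leukaemias. Recovered cutoffs therefore agree with the
published ones in rank and rough location, not to the decimal. Problem
sizes used in examples and tests (e.g. 50 samples per class for noise
cohorts, 10 replicate seeds) are the package's own choices, balancing
statistical resolution against test runtime.

## Numerical choices

* Rule scores are left-to-right double-precision products; `prod()`'s
  extended-precision accumulation is deliberately avoided so scores
  are bit-reproducible across platforms and match the documented
  arithmetic exactly.
* All cutoff comparisons are strict; equality is negative.
* Generation is seed-deterministic and restores the caller's RNG
  state.
* `writeCohort()` prints values with 17 significant digits so
  write/read round trips are bit-exact.

## Limitations

The shipped cutoffs are instrument- and calibration-specific
constants; they cannot be re-derived from this package and must be
revalidated before use on other analysers or populations. The subtype
flags are advisory screening aids, not diagnoses. The reactive
discriminant orientation and several subtype orientations are
provisional as described above. The package is a research tool and
not a medical device.

## Session info

```{r}
sessionInfo()
```
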