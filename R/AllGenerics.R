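#' @include AllClasses.R
NULL

#' Matrix of CPD values
#'
#' Accessor for the CPD measurement matrix of a [CPDCohort-class]
#' (parameters in rows, samples in columns; `NA` marks an absent
#' measurement).
#'
#' @param x a `CPDCohort`.
#' @return numeric matrix, parameters x samples.
#' @export
setGeneric("cpdValues", function(x) standardGeneric("cpdValues"))

#' Fine-grained diagnosis groups of a cohort
#'
#' @param x a `CPDCohort`.
#' @return character vector of group labels (possibly `NA`), one per
#'   sample.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' Coarse class (neoplastic / non-neoplastic) of each sample
#'
#' @param x a `CPDCohort`.
#' @return character vector, one per sample, obtained by mapping the fine
#'   groups through [labelScheme()].
#' @export
setGeneric("coarseClass", function(x) standardGeneric("coarseClass"))

#' Label scheme mapping fine groups to coarse classes
#'
#' @param x a `CPDCohort`.
#' @return named character vector (names = lower-case fine group labels,
#'   values = coarse classes).
#' @export
setGeneric("labelScheme", function(x) standardGeneric("labelScheme"))

#' Score a discriminant rule on CPD data
#'
#' Evaluates the score of a [DiscriminantRule-class] -- the product of
#' its numerator parameters divided by the product of its denominator
#' parameters -- on a single record or on every sample of a cohort.
#'
#' @param x a [CPDRecord-class] or [CPDCohort-class].
#' @param rule a `DiscriminantRule`.
#' @return For a record, a single number. For a cohort, a named numeric
#'   vector (one value per sample; `NA` where the sample is not scoreable
#'   for the rule or where a denominator is zero).
#' @export
setGeneric("ruleScore", function(x, rule) standardGeneric("ruleScore"))

#' Apply a discriminant rule
#'
#' Classifies by strict comparison of the rule score against the cutoff:
#' under `high_is_positive` the positive label is assigned iff
#' score > cutoff; under `low_is_positive` iff score < cutoff. A score
#' exactly equal to the cutoff always receives the negative label.
#'
#' @param x a [CPDRecord-class] or [CPDCohort-class].
#' @param rule a `DiscriminantRule` with an explicit orientation
#'   (an unset orientation is a configuration error, never guessed).
#' @return For a record, a list with elements `label` and `audit`
#'   (a one-row data frame). For a cohort, a character vector of labels
#'   (`NA` for unscoreable samples).
#' @export
setGeneric("applyRule", function(x, rule) standardGeneric("applyRule"))

#' Composite neoplastic score
#'
#' The published screening score
#' (SD-V-NE x MN-UMALS-LY x SD-AL2-MO) / MN-C-NE.
#'
#' @param x a [CPDRecord-class] or [CPDCohort-class].
#' @return For a record, a single number (errors if any of the four
#'   inputs is missing, or if MN-C-NE is zero -- the score is undefined
#'   there, never infinite). For a cohort, a named numeric vector with
#'   `NA` for unscoreable samples.
#' @export
setGeneric("compositeScore", function(x) standardGeneric("compositeScore"))

#' Staged screening cascade
#'
#' Stage 1 separates neoplastic from non-neoplastic samples with the
#' composite score; stage 2 excludes reactive cases among stage-1
#' positives with the MN-AL2-NE discriminant; stage-2 positives are then
#' annotated with advisory leukaemia-subtype flags. Later stages are
#' never evaluated for samples ruled out earlier.
#'
#' @param x a [CPDRecord-class] or [CPDCohort-class].
#' @param registry a rule registry as returned by [publishedRules()] or
#'   [readRules()].
#' @return For a record, a [CascadeResult-class]. For a cohort, a
#'   `DataFrame` with one row per sample (columns `compositeScore`,
#'   `stage1`, `stage2`, `finalCall` and one logical column per subtype)
#'   whose `metadata()$audit` holds the per-sample audit trails.
#' @export
setGeneric("cascadeClassify", function(x, registry = publishedRules())
  standardGeneric("cascadeClassify"))

#' Generate a synthetic CPD cohort
#'
#' @param config a [SimulationConfig-class].
#' @param seed integer seed overriding the seed stored in `config`.
#' @return a [CPDCohort-class]; deterministic for a fixed (config, seed).
#' @export
setGeneric("generateCohort", function(config, seed = NULL)
  standardGeneric("generateCohort"))
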