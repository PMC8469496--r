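# Class definitions. Validity functions may call helpers defined in the
# grammar / rules files; those are resolved at run time, not load time.

#' CPDParameter: identity of one cell population data parameter
#'
#' A CPD parameter is the mean (`MN`) or standard deviation (`SD`) of one
#' measurement channel -- volume (`V`), conductivity (`C`), one of the
#' light-scatter angles (`MALS`, `UMALS`, `LMALS`, `LALS`) or axial light
#' loss (`AL2`) -- over one gated leukocyte population (`NE` neutrophils,
#' `LY` lymphocytes, `MO` monocytes, `EO` eosinophils; further cell types
#' can be registered with [registerCPDCellType()]). Its canonical string
#' form is `{statistic}-{channel}-{cellType}`, e.g. `"SD-V-NE"`.
#'
#' @slot statistic `"MN"` or `"SD"`.
#' @slot channel one of `"V"`, `"C"`, `"MALS"`, `"UMALS"`, `"LMALS"`,
#'   `"LALS"`, `"AL2"`.
#' @slot cellType a registered cell-type code.
#' @seealso [parseParameter()], [formatParameter()]
#' @export
setClass("CPDParameter",
  representation(statistic = "character", channel = "character",
                 cellType = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@statistic) != 1L ||
        !object@statistic %in% cpdStatistics())
      msg <- c(msg, sprintf("unknown statistic '%s'", object@statistic[1]))
    if (length(object@channel) != 1L || !object@channel %in% cpdChannels())
      msg <- c(msg, sprintf("unknown channel '%s'", object@channel[1]))
    if (length(object@cellType) != 1L ||
        !object@cellType %in% cpdCellTypes())
      msg <- c(msg, sprintf("unknown cell type '%s'", object@cellType[1]))
    if (length(msg)) msg else TRUE
  })

#' CPDRecord: one sample's CPD measurements
#'
#' @slot sampleId sample identifier.
#' @slot values named non-negative numeric vector; names are canonical
#'   parameter names. A parameter the instrument did not report is simply
#'   absent from the vector (never stored as zero).
#' @slot group fine diagnosis group label, or `NA`.
#' @slot metadata free-form list.
#' @seealso [CPDRecord()], [getRecord()]
#' @export
setClass("CPDRecord",
  representation(sampleId = "character", values = "numeric",
                 group = "character", metadata = "list"),
  prototype(group = NA_character_, metadata = list()),
  validity = function(object) {
    msg <- character(0)
    if (length(object@sampleId) != 1L)
      msg <- c(msg, "sampleId must be a single string")
    v <- object@values
    if (length(v)) {
      if (is.null(names(v)) || any(!nzchar(names(v))))
        msg <- c(msg, "all values must be named by a CPD parameter")
      if (any(!is.finite(v)) || any(v < 0))
        msg <- c(msg, "values must be finite and >= 0")
      bad <- names(v)[!isCanonicalParameter(names(v))]
      if (length(bad))
        msg <- c(msg, sprintf("not canonical parameter names: %s",
                              paste(bad, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
  })

#' CPDCohort: a cohort of CPD samples
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a single
#' assay `"cpd"` (parameters in rows, samples in columns; `NA` = absent
#' measurement). `rowData` carries the parsed parameter identity
#' (`statistic`, `channel`, `cellType`); `colData` carries `group`,
#' `coarseClass` and any further sample metadata. The label scheme that
#' maps fine groups onto coarse classes is stored in
#' `metadata(x)$labelScheme` and must cover every group present.
#'
#' @seealso [CPDCohort()], [readCohort()], [writeCohort()]
#' @export
setClass("CPDCohort", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character(0)
    if (!"cpd" %in% SummarizedExperiment::assayNames(object))
      return("assay 'cpd' is required")
    v <- SummarizedExperiment::assay(object, "cpd")
    if (any(!is.na(v) & (!is.finite(v) | v < 0)))
      msg <- c(msg, "CPD values must be finite and >= 0")
    bad <- rownames(object)[!isCanonicalParameter(rownames(object))]
    if (length(bad))
      msg <- c(msg, sprintf("not canonical parameter names: %s",
                            paste(bad, collapse = ", ")))
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicate sample ids")
    grp <- object$group
    if (!is.null(grp)) {
      scheme <- S4Vectors::metadata(object)$labelScheme
      present <- unique(tolower(grp[!is.na(grp)]))
      unmapped <- setdiff(present, names(scheme))
      if (length(unmapped))
        msg <- c(msg, sprintf(
          "label scheme does not cover group(s): %s",
          paste(unmapped, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
  })

#' DiscriminantRule: a scored classification rule
#'
#' A rule scores a sample as the product of its numerator parameters
#' divided by the product of its denominator parameters (a single
#' parameter is a numerator of length one), then compares the score
#' strictly against the cutoff in the direction given by the orientation.
#'
#' @slot name rule identifier.
#' @slot numerator,denominator canonical parameter names (denominator
#'   may be empty).
#' @slot cutoff finite decision threshold.
#' @slot orientation `"high_is_positive"`, `"low_is_positive"`, or `NA`
#'   when the direction is not yet configured (the rule then refuses to
#'   classify).
#' @slot positiveLabel,negativeLabel labels assigned on either side of
#'   the cutoff.
#' @slot subtype optional subtype this rule flags (e.g. `"AML"`).
#' @seealso [discriminantRule()], [applyRule()], [publishedRules()]
#' @export
setClass("DiscriminantRule",
  representation(name = "character", numerator = "character",
                 denominator = "character", cutoff = "numeric",
                 orientation = "character", positiveLabel = "character",
                 negativeLabel = "character", subtype = "character"),
  prototype(denominator = character(0), orientation = NA_character_,
            subtype = NA_character_),
  validity = function(object) {
    msg <- character(0)
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "name must be a non-empty string")
    if (length(object@numerator) < 1L)
      msg <- c(msg, "at least one numerator parameter is required")
    bad <- c(object@numerator, object@denominator)
    bad <- bad[!isCanonicalParameter(bad)]
    if (length(bad))
      msg <- c(msg, sprintf("not canonical parameter names: %s",
                            paste(bad, collapse = ", ")))
    if (length(object@cutoff) != 1L || !is.finite(object@cutoff))
      msg <- c(msg, "cutoff must be a single finite number")
    if (length(object@orientation) != 1L ||
        (!is.na(object@orientation) &&
         !object@orientation %in% c("high_is_positive", "low_is_positive")))
      msg <- c(msg, "orientation must be 'high_is_positive', 'low_is_positive' or NA")
    if (length(msg)) msg else TRUE
  })

#' CascadeResult: outcome of the staged screening cascade for one sample
#'
#' @slot sampleId sample identifier.
#' @slot compositeScore stage-1 composite score.
#' @slot stage1 `"neoplastic"` or `"non-neoplastic"`.
#' @slot stage2 `"neoplastic"`, `"reactive"`, or `NA` when stage 1 was
#'   negative (later stages are short-circuited).
#' @slot flags named logical, one per subtype rule evaluated
#'   (`NA` = not evaluated, e.g. a required parameter was absent).
#' @slot subtypeCalls named logical, any-rule-positive summary per
#'   subtype.
#' @slot audit data frame of rule evaluations in execution order
#'   (columns `rule`, `inputs`, `score`, `comparison`, `outcome`).
#' @export
setClass("CascadeResult",
  representation(sampleId = "character", compositeScore = "numeric",
                 stage1 = "character", stage2 = "character",
                 flags = "logical", subtypeCalls = "logical",
                 audit = "data.frame"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@audit) < 1L)
      msg <- c(msg, "audit trail must be non-empty")
    if (identical(object@stage1, "non-neoplastic") &&
        (!is.na(object@stage2) || length(object@flags)))
      msg <- c(msg, "stage 2 / subtype flags must be absent when stage 1 is negative")
    if (length(msg)) msg else TRUE
  })

#' ROCResult: an empirical ROC analysis
#'
#' Thresholds are the midpoints between adjacent distinct observed
#' values (plus -Inf/Inf end points); sensitivity and specificity are
#' given at each threshold under the recorded orientation. The AUC is
#' the Mann--Whitney probability estimate (ties count one half) with a
#' DeLong 95% confidence interval.
#'
#' @slot thresholds,sensitivities,specificities the threshold sweep.
#' @slot auc area under the curve, in `[0, 1]`.
#' @slot aucCI length-2 numeric, 95% CI for the AUC.
#' @slot orientation `"high_is_positive"` or `"low_is_positive"`, chosen
#'   so that the AUC is >= 0.5 and recorded explicitly.
#' @slot cutoff,cutoffSensitivity,cutoffSpecificity the selected
#'   operating point (see [selectCutoff()]), or `NA` if none selected.
#' @slot policy cutoff-selection policy used.
#' @slot nPositive,nNegative class sizes.
#' @seealso [rocCurve()], [selectCutoff()]
#' @export
setClass("ROCResult",
  representation(thresholds = "numeric", sensitivities = "numeric",
                 specificities = "numeric", auc = "numeric",
                 aucCI = "numeric", orientation = "character",
                 cutoff = "numeric", cutoffSensitivity = "numeric",
                 cutoffSpecificity = "numeric", policy = "character",
                 nPositive = "integer", nNegative = "integer"),
  prototype(cutoff = NA_real_, cutoffSensitivity = NA_real_,
            cutoffSpecificity = NA_real_, policy = NA_character_),
  validity = function(object) {
    msg <- character(0)
    if (object@auc < 0 || object@auc > 1)
      msg <- c(msg, "auc must lie in [0, 1]")
    if (length(object@aucCI) != 2L ||
        object@aucCI[1] > object@auc + 1e-12 ||
        object@aucCI[2] < object@auc - 1e-12)
      msg <- c(msg, "aucCI must bracket the AUC")
    n <- length(object@thresholds)
    if (length(object@sensitivities) != n ||
        length(object@specificities) != n)
      msg <- c(msg, "threshold sweep vectors must have equal length")
    if (length(msg)) msg else TRUE
  })

#' ConfusionCounts: a 2x2 confusion table
#'
#' @slot tp,fp,fn,tn non-negative integer counts.
#' @seealso [confusionCounts()], [accuracyStats()]
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 tn = "integer"),
  validity = function(object) {
    k <- c(object@tp, object@fp, object@fn, object@tn)
    if (length(k) != 4L || any(is.na(k)) || any(k < 0))
      return("tp, fp, fn, tn must be single non-negative integers")
    if (sum(k) < 1L) return("at least one count must be positive")
    TRUE
  })

#' AccuracyStats: diagnostic accuracy statistics with confidence intervals
#'
#' @slot counts the underlying [ConfusionCounts-class].
#' @slot estimates named numeric (`sensitivity`, `specificity`, `ppv`,
#'   `npv`) as proportions; `NA` marks a statistic whose denominator is
#'   zero (undefined, never reported as 0 or 1).
#' @slot ci 4x2 matrix of 95% confidence bounds, rows matching
#'   `estimates`.
#' @slot ciMethod the interval method used.
#' @seealso [accuracyStats()], [wilsonCCInterval()]
#' @export
setClass("AccuracyStats",
  representation(counts = "ConfusionCounts", estimates = "numeric",
                 ci = "matrix", ciMethod = "character"),
  validity = function(object) {
    msg <- character(0)
    e <- object@estimates
    if (!all(c("sensitivity", "specificity", "ppv", "npv") %in% names(e)))
      msg <- c(msg, "estimates must contain sensitivity, specificity, ppv, npv")
    ok <- !is.na(e)
    if (any(e[ok] < 0 | e[ok] > 1))
      msg <- c(msg, "estimates must lie in [0, 1]")
    ci <- object@ci
    if (!all(dim(ci) == c(4L, 2L)))
      msg <- c(msg, "ci must be a 4x2 matrix")
    else {
      bad <- ok & (ci[, 1] > e + 1e-12 | ci[, 2] < e - 1e-12)
      if (any(bad, na.rm = TRUE))
        msg <- c(msg, "confidence intervals must contain the point estimates")
      if (any(ci[!is.na(ci)] < 0 | ci[!is.na(ci)] > 1))
        msg <- c(msg, "confidence bounds must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  })

#' GroupSpec: distributional specification of one simulated group
#'
#' @slot label group label (e.g. `"normal"`, `"AML"`).
#' @slot n number of samples to draw.
#' @slot params data frame with columns `parameter`, `family`
#'   (`"normal"` or `"lognormal"`), `mean`, `sd` -- the target marginal
#'   mean and standard deviation on the natural scale. Normal draws are
#'   truncated at zero.
#' @slot corFactor single-factor correlation (in `[0, 1)`) shared by the
#'   parameters of each cell type on the latent Gaussian scale;
#'   0 = independence.
#' @seealso [groupSpec()], [generateCohort()]
#' @export
setClass("GroupSpec",
  representation(label = "character", n = "integer",
                 params = "data.frame", corFactor = "numeric"),
  prototype(corFactor = 0),
  validity = function(object) {
    msg <- character(0)
    if (length(object@label) != 1L || !nzchar(object@label))
      msg <- c(msg, "label must be a non-empty string")
    if (length(object@n) != 1L || is.na(object@n) || object@n < 0L)
      msg <- c(msg, "n must be a single non-negative integer")
    p <- object@params
    need <- c("parameter", "family", "mean", "sd")
    if (!all(need %in% names(p)))
      msg <- c(msg, "params needs columns parameter, family, mean, sd")
    else {
      if (!all(p$family %in% c("normal", "lognormal")))
        msg <- c(msg, "family must be 'normal' or 'lognormal'")
      if (any(!is.finite(p$mean)) || any(!is.finite(p$sd)) || any(p$sd <= 0))
        msg <- c(msg, "means must be finite and sds finite and > 0")
      if (anyDuplicated(p$parameter))
        msg <- c(msg, "duplicate parameter in params")
    }
    if (length(object@corFactor) != 1L || object@corFactor < 0 ||
        object@corFactor >= 1)
      msg <- c(msg, "corFactor must lie in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' SimulationConfig: full specification of a synthetic cohort
#'
#' @slot groups list of [GroupSpec-class] with unique labels.
#' @slot seed mandatory integer seed.
#' @slot parameters parameter roster (defaults to the 56 canonical
#'   names).
#' @slot labelScheme named character mapping fine groups to coarse
#'   classes, stored into the generated cohort.
#' @seealso [simulationConfig()], [paperLikeConfig()], [pureNoiseConfig()]
#' @export
setClass("SimulationConfig",
  representation(groups = "list", seed = "integer",
                 parameters = "character", labelScheme = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!length(object@groups) ||
        !all(vapply(object@groups, is, logical(1), "GroupSpec")))
      msg <- c(msg, "groups must be a non-empty list of GroupSpec")
    else {
      labs <- vapply(object@groups, function(g) g@label, character(1))
      if (anyDuplicated(labs)) msg <- c(msg, "group labels must be unique")
    }
    if (length(object@seed) != 1L || is.na(object@seed))
      msg <- c(msg, "seed is mandatory")
    if (length(msg)) msg else TRUE
  })
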