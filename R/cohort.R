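#' Default label scheme
#'
#' Maps fine diagnosis groups onto the coarse screening classes:
#' non-neoplastic = normal + reactive; neoplastic = AML, APL (also
#' accepted as "APML"), ALL, lymphoma, CLL, CML, MDS. Group labels are
#' matched case-insensitively.
#'
#' @return named character vector (names = lower-case fine groups).
#' @export
defaultLabelScheme <- function() {
  c(normal = "non-neoplastic", reactive = "non-neoplastic",
    aml = "neoplastic", apl = "neoplastic", apml = "neoplastic",
    all = "neoplastic", lymphoma = "neoplastic", cll = "neoplastic",
    cml = "neoplastic", mds = "neoplastic")
}

#' Construct a CPDCohort
#'
#' @param values numeric matrix or data frame of CPD measurements,
#'   samples in rows and parameters in columns (column names in any
#'   accepted dialect; normalised to canonical form). `NA` marks an
#'   absent measurement.
#' @param group optional character vector of fine diagnosis groups, one
#'   per sample.
#' @param sampleId sample identifiers; defaults to the row names of
#'   `values` or `S1..Sn`. Must be unique.
#' @param labelScheme named character vector mapping (lower-case) fine
#'   groups to coarse classes; must cover every group present.
#' @param colData optional data frame of further per-sample metadata.
#' @return a [CPDCohort-class].
#' @examples
#' m <- cbind(`SD-V-NE` = c(25, 14), `MN-C-NE` = c(140, 152))
#' CPDCohort(m, group = c("AML", "normal"))
#' @export
CPDCohort <- function(values, group = NULL, sampleId = NULL,
                      labelScheme = defaultLabelScheme(),
                      colData = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    stop("'values' must have parameter column names")
  colnames(values) <- normalizeParameterName(colnames(values))
  bad <- colnames(values)[!isCanonicalParameter(colnames(values))]
  if (length(bad))
    stop(sprintf("not parsable as CPD parameters: %s",
                 paste(bad, collapse = ", ")))
  n <- nrow(values)
  if (is.null(sampleId))
    sampleId <- if (!is.null(rownames(values))) rownames(values)
                else sprintf("S%d", seq_len(n))
  sampleId <- as.character(sampleId)
  if (anyDuplicated(sampleId))
    stop("duplicate sample ids: ",
         paste(unique(sampleId[duplicated(sampleId)]), collapse = ", "))
  cd <- S4Vectors::DataFrame(row.names = sampleId)
  if (!is.null(group)) {
    group <- as.character(group)
    stopifnot(length(group) == n)
    cd$group <- group
    key <- tolower(group)
    cd$coarseClass <- unname(labelScheme[key])
  }
  if (!is.null(colData)) {
    extra <- S4Vectors::DataFrame(colData, row.names = sampleId)
    cd <- cbind(cd, extra[, setdiff(colnames(extra), colnames(cd)),
                          drop = FALSE])
  }
  parsed <- lapply(colnames(values), parseParameter)
  rd <- S4Vectors::DataFrame(
    statistic = vapply(parsed, slot, character(1), "statistic"),
    channel = vapply(parsed, slot, character(1), "channel"),
    cellType = vapply(parsed, slot, character(1), "cellType"),
    row.names = colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cpd = t(values)), rowData = rd, colData = cd,
    metadata = list(labelScheme = labelScheme))
  new("CPDCohort", se)
}

#' @rdname cpdValues
#' @export
setMethod("cpdValues", "CPDCohort", function(x)
  SummarizedExperiment::assay(x, "cpd"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "CPDCohort", function(x) {
  g <- x$group
  if (is.null(g)) rep(NA_character_, ncol(x)) else as.character(g)
})

#' @rdname coarseClass
#' @export
setMethod("coarseClass", "CPDCohort", function(x) {
  cc <- x$coarseClass
  if (is.null(cc)) rep(NA_character_, ncol(x)) else as.character(cc)
})

#' @rdname labelScheme
#' @export
setMethod("labelScheme", "CPDCohort", function(x)
  S4Vectors::metadata(x)$labelScheme)

#' Construct a single CPD record
#'
#' @param values named numeric vector of measurements (names in any
#'   accepted dialect). Absent parameters are simply not listed.
#' @param sampleId sample identifier.
#' @param group optional fine diagnosis group.
#' @param metadata free-form list.
#' @return a [CPDRecord-class].
#' @examples
#' CPDRecord(c(`SD-V-NE` = 25, `MN-UMALS-LY` = 70,
#'             `SD-AL2-MO` = 20, `MN-C-NE` = 140), sampleId = "case1")
#' @export
CPDRecord <- function(values, sampleId = "sample", group = NA_character_,
                      metadata = list()) {
  values <- values[!is.na(values)]
  if (length(values)) names(values) <- normalizeParameterName(names(values))
  new("CPDRecord", sampleId = as.character(sampleId),
      values = values, group = as.character(group), metadata = metadata)
}

#' Extract one sample from a cohort as a CPDRecord
#'
#' @param x a [CPDCohort-class].
#' @param i sample index or sample id.
#' @return a [CPDRecord-class]; absent (`NA`) measurements are dropped.
#' @export
getRecord <- function(x, i) {
  stopifnot(is(x, "CPDCohort"), length(i) == 1L)
  v <- cpdValues(x)[, i]
  CPDRecord(v[!is.na(v)], sampleId = colnames(x)[if (is.character(i))
    match(i, colnames(x)) else i], group = sampleGroups(x)[if (is.character(i))
    match(i, colnames(x)) else i])
}

#' Is a sample scoreable for a rule?
#'
#' A record (or cohort sample) is scoreable for a rule only if every
#' parameter the rule references is present.
#'
#' @param x a [CPDRecord-class] or [CPDCohort-class].
#' @param rule a [DiscriminantRule-class].
#' @return logical (one value per sample for a cohort).
#' @export
isScoreable <- function(x, rule) {
  pars <- c(rule@numerator, rule@denominator)
  if (is(x, "CPDRecord")) return(all(pars %in% names(x@values)))
  stopifnot(is(x, "CPDCohort"))
  present <- intersect(pars, rownames(x))
  if (length(present) < length(pars))
    return(setNames(rep(FALSE, ncol(x)), colnames(x)))
  colSums(is.na(cpdValues(x)[pars, , drop = FALSE])) == 0L
}

setMethod("show", "CPDCohort", function(object) {
  cat(sprintf("CPDCohort: %d samples x %d CPD parameters\n",
              ncol(object), nrow(object)))
  cc <- coarseClass(object)
  if (!all(is.na(cc))) {
    tab <- table(factor(cc), useNA = "ifany")
    cat("  coarse classes:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  g <- sampleGroups(object)
  if (!all(is.na(g))) {
    tab <- sort(table(g), decreasing = TRUE)
    cat("  groups:", paste(sprintf("%s=%d", names(tab), tab),
                           collapse = ", "), "\n")
  }
  cat(sprintf("  missing cells: %d\n", sum(is.na(cpdValues(object)))))
})

setMethod("show", "CPDRecord", function(object) {
  cat(sprintf("CPDRecord '%s' (%d parameters%s)\n", object@sampleId,
              length(object@values),
              if (is.na(object@group)) "" else paste0(", group ", object@group)))
  if (length(object@values)) {
    v <- utils::head(object@values, 6)
    cat(" ", paste(sprintf("%s=%.4g", names(v), v), collapse = ", "),
        if (length(object@values) > 6) "..." else "", "\n")
  }
})
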