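# Tabular I/O. One sample per row; parameter columns are recognised by
# the name grammar (any accepted dialect), everything else is routed to
# sample metadata. Comma and tab delimiters are sniffed from the header;
# files are written comma-separated at full decimal precision so that a
# read/write round trip is value-exact.

.sniffDelim <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty file: ", path)
  if (lengths(regmatches(header, gregexpr("\t", header))) >
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

#' Read a CPD cohort from a CSV/TSV file
#'
#' Expects a header row and one sample per row. Columns whose
#' (normalised) names parse as CPD parameters become measurements;
#' a column named `sample_id`/`sampleid`/`sample`/`id` (case-insensitive)
#' supplies sample identifiers, `group` the fine diagnosis group, and
#' any remaining columns become sample metadata. Empty cells become
#' absent values, never zeros.
#'
#' @param path file path.
#' @param labelScheme see [CPDCohort()].
#' @return a [CPDCohort-class].
#' @export
readCohort <- function(path, labelScheme = defaultLabelScheme()) {
  delim <- .sniffDelim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), quote = "\"",
                          comment.char = "")
  nms <- names(df)
  isPar <- isCanonicalParameter(normalizeParameterName(nms))
  if (!any(isPar))
    stop("no parsable CPD parameter column found in ", path)
  low <- tolower(nms)
  idCol <- which(!isPar & low %in% c("sample_id", "sampleid", "sample", "id"))[1]
  grpCol <- which(!isPar & low == "group")[1]
  metaCols <- setdiff(which(!isPar), c(idCol, grpCol))
  vals <- as.matrix(df[, isPar, drop = FALSE])
  storage.mode(vals) <- "double"
  sampleId <- if (!is.na(idCol)) as.character(df[[idCol]]) else NULL
  if (!is.null(sampleId) && anyDuplicated(sampleId))
    stop("duplicate sample_id in ", path, ": ",
         paste(unique(sampleId[duplicated(sampleId)]), collapse = ", "))
  CPDCohort(vals,
            group = if (!is.na(grpCol)) as.character(df[[grpCol]]) else NULL,
            sampleId = sampleId, labelScheme = labelScheme,
            colData = if (length(metaCols)) df[, metaCols, drop = FALSE]
                      else NULL)
}

#' Write a CPD cohort to a CSV file
#'
#' Values are written with 17 significant digits so that
#' `readCohort(writeCohort(x))` reproduces them bit-exactly; absent
#' measurements are written as empty cells and record order is
#' preserved.
#'
#' @param cohort a [CPDCohort-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "CPDCohort"))
  vals <- t(cpdValues(cohort))
  txt <- matrix("", nrow(vals), ncol(vals), dimnames = dimnames(vals))
  ok <- !is.na(vals)
  txt[ok] <- sprintf("%.17g", vals[ok])
  out <- data.frame(sample_id = colnames(cohort),
                    check.names = FALSE, stringsAsFactors = FALSE)
  g <- sampleGroups(cohort)
  if (!all(is.na(g))) out$group <- g
  cd <- SummarizedExperiment::colData(cohort)
  meta <- setdiff(colnames(cd), c("group", "coarseClass"))
  for (m in meta) out[[m]] <- cd[[m]]
  out <- cbind(out, as.data.frame(txt, stringsAsFactors = FALSE,
                                  check.names = FALSE))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = TRUE, na = "")
  invisible(path)
}

#' Read a discriminant-rule registry from YAML (or JSON)
#'
#' The registry format is a top-level `rules:` list whose entries have
#' fields `name`, `numerator`, optional `denominator`, `cutoff`,
#' optional `orientation` (left unset, the rule refuses to classify
#' until configured), `positive_label`, `negative_label` and optional
#' `subtype`.
#'
#' @param path YAML file path.
#' @return named [S4Vectors::SimpleList] of [DiscriminantRule-class],
#'   with any registry-level metadata kept in `metadata()`.
#' @seealso [publishedRules()], [writeRules()]
#' @export
readRules <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$rules)) stop("registry has no 'rules' entry: ", path)
  rules <- lapply(doc$rules, function(r) {
    discriminantRule(
      name = r$name,
      numerator = normalizeParameterName(unlist(r$numerator)),
      denominator = normalizeParameterName(unlist(r$denominator %||%
                                                    character(0))),
      cutoff = as.numeric(r$cutoff),
      orientation = r$orientation %||% NA_character_,
      positiveLabel = r$positive_label %||% "positive",
      negativeLabel = r$negative_label %||% "negative",
      subtype = r$subtype %||% NA_character_)
  })
  names(rules) <- vapply(rules, function(r) r@name, character(1))
  out <- S4Vectors::SimpleList(rules)
  S4Vectors::metadata(out) <- doc[setdiff(names(doc), "rules")]
  out
}

#' Write a rule registry to YAML
#'
#' @param registry a list / `SimpleList` of [DiscriminantRule-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRules <- function(registry, path) {
  rules <- lapply(registry, function(r) {
    out <- list(name = r@name, numerator = as.list(r@numerator))
    if (length(r@denominator)) out$denominator <- as.list(r@denominator)
    out$cutoff <- r@cutoff
    if (!is.na(r@orientation)) out$orientation <- r@orientation
    out$positive_label <- r@positiveLabel
    out$negative_label <- r@negativeLabel
    if (!is.na(r@subtype)) out$subtype <- r@subtype
    out
  })
  doc <- c(if (is(registry, "SimpleList")) S4Vectors::metadata(registry),
           list(rules = unname(rules)))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' The published rule registry
#'
#' The shipped registry of published CPD discriminants for the Beckman
#' Coulter DxH 800 platform: the composite neoplastic score and its four
#' constituent single-parameter rules, the MN-AL2-NE reactive
#' discriminant, and the seven advisory leukaemia-subtype rules. The
#' orientations of the reactive and subtype rules were not part of the
#' published cutoff tables; the shipped defaults are provisional
#' configuration (see the registry file's comments) and can be relearned
#' from data with the calibration functions.
#'
#' @return named [S4Vectors::SimpleList] of [DiscriminantRule-class].
#' @examples
#' publishedRules()[["neoplastic_composite"]]
#' @export
publishedRules <- function() {
  readRules(system.file("extdata", "published_rules.yaml",
                        package = "CPDscreen", mustWork = TRUE))
}
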