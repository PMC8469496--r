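#' Construct a discriminant rule
#'
#' @param name rule identifier.
#' @param numerator canonical parameter name(s) multiplied in the score
#'   numerator (a single-parameter rule has a length-1 numerator).
#' @param denominator parameter name(s) divided out (may be empty).
#' @param cutoff finite decision threshold.
#' @param orientation `"high_is_positive"`, `"low_is_positive"`, or `NA`
#'   when the direction is not configured yet.
#' @param positiveLabel,negativeLabel labels assigned on the positive /
#'   negative side of the cutoff.
#' @param subtype optional subtype flagged by the rule.
#' @return a [DiscriminantRule-class].
#' @examples
#' discriminantRule("sd_v_ne", "SD-V-NE", cutoff = 18.95,
#'                  orientation = "high_is_positive",
#'                  positiveLabel = "neoplastic",
#'                  negativeLabel = "non-neoplastic")
#' @export
discriminantRule <- function(name, numerator, denominator = character(0),
                             cutoff, orientation = NA_character_,
                             positiveLabel = "positive",
                             negativeLabel = "negative",
                             subtype = NA_character_) {
  new("DiscriminantRule", name = name,
      numerator = normalizeParameterName(numerator),
      denominator = if (length(denominator))
        normalizeParameterName(denominator) else character(0),
      cutoff = as.numeric(cutoff), orientation = orientation,
      positiveLabel = positiveLabel, negativeLabel = negativeLabel,
      subtype = as.character(subtype))
}

.ruleScoreRecord <- function(record, rule) {
  pars <- c(rule@numerator, rule@denominator)
  missing <- setdiff(pars, names(record@values))
  if (length(missing))
    stop(sprintf("record '%s' is missing parameter(s) %s required by rule '%s'",
                 record@sampleId, paste(missing, collapse = ", "),
                 rule@name))
  # left-to-right double-precision products (prod() accumulates in
  # extended precision, which would make scores platform-dependent)
  num <- Reduce(`*`, as.list(record@values[rule@numerator]), 1)
  den <- if (length(rule@denominator))
    Reduce(`*`, as.list(record@values[rule@denominator]), 1) else 1
  if (den == 0)
    stop(sprintf("rule '%s' is undefined for record '%s': denominator parameter is zero",
                 rule@name, record@sampleId))
  num / den
}

#' @rdname ruleScore
#' @export
setMethod("ruleScore", signature("CPDRecord", "DiscriminantRule"),
          function(x, rule) .ruleScoreRecord(x, rule))

#' @rdname ruleScore
#' @export
setMethod("ruleScore", signature("CPDCohort", "DiscriminantRule"),
  function(x, rule) {
    pars <- c(rule@numerator, rule@denominator)
    v <- cpdValues(x)
    out <- setNames(rep(NA_real_, ncol(x)), colnames(x))
    if (!all(pars %in% rownames(v))) return(out)
    ok <- isScoreable(x, rule)
    if (!any(ok)) return(out)
    # left-to-right double-precision row products, matching the
    # single-record path bit for bit
    rowProd <- function(m) Reduce(`*`, asplit(m, 1), rep(1, ncol(m)))
    num <- rowProd(v[rule@numerator, ok, drop = FALSE])
    den <- if (length(rule@denominator))
      rowProd(v[rule@denominator, ok, drop = FALSE]) else 1
    s <- num / den
    s[is.infinite(s) | is.nan(s)] <- NA_real_  # zero denominator: undefined
    out[ok] <- s
    out
  })

.compareToCutoff <- function(score, rule) {
  if (is.na(rule@orientation))
    stop(sprintf("orientation of rule '%s' is not configured; refusing to guess",
                 rule@name))
  # strict comparisons; a score exactly at the cutoff is negative
  if (rule@orientation == "high_is_positive") score > rule@cutoff
  else score < rule@cutoff
}

#' @rdname applyRule
#' @export
setMethod("applyRule", signature("CPDRecord", "DiscriminantRule"),
  function(x, rule) {
    score <- ruleScore(x, rule)
    pos <- .compareToCutoff(score, rule)
    label <- if (pos) rule@positiveLabel else rule@negativeLabel
    pars <- c(rule@numerator, rule@denominator)
    cmp <- if (rule@orientation == "high_is_positive") ">" else "<"
    audit <- data.frame(
      rule = rule@name,
      inputs = paste(sprintf("%s=%.10g", pars, x@values[pars]),
                     collapse = ";"),
      score = score,
      comparison = sprintf("%.10g %s %.10g", score, cmp, rule@cutoff),
      outcome = label, stringsAsFactors = FALSE)
    list(label = label, audit = audit)
  })

#' @rdname applyRule
#' @export
setMethod("applyRule", signature("CPDCohort", "DiscriminantRule"),
  function(x, rule) {
    score <- ruleScore(x, rule)
    pos <- .compareToCutoff(score, rule)
    out <- ifelse(is.na(pos), NA_character_,
                  ifelse(pos, rule@positiveLabel, rule@negativeLabel))
    setNames(out, colnames(x))
  })

setMethod("show", "DiscriminantRule", function(object) {
  score <- paste(object@numerator, collapse = " x ")
  if (length(object@denominator))
    score <- sprintf("(%s) / (%s)", score,
                     paste(object@denominator, collapse = " x "))
  cmp <- switch(object@orientation, high_is_positive = ">",
                low_is_positive = "<", "?")
  cat(sprintf("DiscriminantRule '%s': %s %s %.4g -> '%s' (else '%s')%s\n",
              object@name, score, cmp, object@cutoff,
              object@positiveLabel, object@negativeLabel,
              if (is.na(object@subtype)) ""
              else sprintf(" [subtype %s]", object@subtype)))
  if (is.na(object@orientation))
    cat("  (orientation not configured)\n")
})
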