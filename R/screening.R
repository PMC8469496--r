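# The published screening discriminants and the staged decision cascade.

.compositeParams <- list(numerator = c("SD-V-NE", "MN-UMALS-LY", "SD-AL2-MO"),
                         denominator = "MN-C-NE")

.compositeRule <- function(cutoff = 106.44)
  discriminantRule("neoplastic_composite",
                   numerator = .compositeParams$numerator,
                   denominator = .compositeParams$denominator,
                   cutoff = cutoff, orientation = "high_is_positive",
                   positiveLabel = "neoplastic",
                   negativeLabel = "non-neoplastic")

#' @rdname compositeScore
#' @export
setMethod("compositeScore", "CPDRecord", function(x)
  ruleScore(x, .compositeRule()))

#' @rdname compositeScore
#' @export
setMethod("compositeScore", "CPDCohort", function(x)
  ruleScore(x, .compositeRule()))

#' Reactive-case discriminant
#'
#' Applies the single-parameter MN-AL2-NE rule that separates reactive
#' (infection-driven) cases from genuinely neoplastic ones among
#' stage-1-positive samples. The published cutoff is 147.5; the side of
#' the cutoff that is neoplastic was not published, so the rule's
#' orientation must be configured explicitly (the shipped registry
#' defaults, provisionally, to neoplastic-low).
#'
#' @param x a [CPDRecord-class] or [CPDCohort-class].
#' @param rule the MN-AL2-NE [DiscriminantRule-class]; defaults to the
#'   shipped registry entry.
#' @return as [applyRule()].
#' @export
reactiveDiscriminant <- function(x,
                                 rule = publishedRules()[["reactive_mn_al2_ne"]]) {
  stopifnot(is(rule, "DiscriminantRule"))
  if (is.na(rule@orientation))
    stop(sprintf("orientation of rule '%s' is not configured; refusing to guess",
                 rule@name))
  applyRule(x, rule)
}

.subtypeRules <- function(registry)
  registry[!vapply(registry, function(r) is.na(r@subtype), logical(1))]

#' Advisory leukaemia-subtype flags
#'
#' Evaluates the subtype rules of a registry (by default the seven
#' published ones: AML via SD-MALS-NE and SD-UMALS-NE, APL via MN-V-NE
#' and SD-V-MO, ALL via MN-MALS-NE and MN-LMALS-NE, CLL via SD-C-MO) on
#' one record. Rules are advisory and independent: no mutual exclusion
#' is enforced. A rule whose input parameter is absent yields `NA`
#' ("not evaluated"), never `FALSE`.
#'
#' @param record a [CPDRecord-class].
#' @param registry a rule registry; only rules with a `subtype` are used.
#' @return list with elements `flags` (named logical per rule),
#'   `subtype` (named logical any-rule-positive summary per subtype;
#'   `NA` when no rule fired but some were not evaluated) and `audit`
#'   (data frame of evaluations).
#' @export
subtypeFlags <- function(record, registry = publishedRules()) {
  stopifnot(is(record, "CPDRecord"))
  rules <- .subtypeRules(registry)
  if (!length(rules)) stop("registry contains no subtype rules")
  flags <- setNames(rep(NA, length(rules)),
                    vapply(rules, function(r) r@name, character(1)))
  audit <- list()
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (!isScoreable(record, r)) {
      audit[[i]] <- data.frame(rule = r@name, inputs = NA_character_,
                               score = NA_real_, comparison = NA_character_,
                               outcome = "not evaluated",
                               stringsAsFactors = FALSE)
      next
    }
    res <- applyRule(record, r)
    flags[i] <- identical(res$label, r@positiveLabel)
    audit[[i]] <- res$audit
  }
  subtype <- vapply(split(flags, vapply(rules, function(r) r@subtype,
                                        character(1))),
                    function(f) {
                      if (any(f %in% TRUE)) TRUE
                      else if (anyNA(f)) NA
                      else FALSE
                    }, logical(1))
  list(flags = flags, subtype = subtype,
       audit = do.call(rbind, audit))
}

#' @rdname cascadeClassify
#' @export
setMethod("cascadeClassify", "CPDRecord", function(x, registry) {
  if (!"neoplastic_composite" %in% names(registry))
    stop("registry has no 'neoplastic_composite' rule")
  comp <- registry[["neoplastic_composite"]]
  s1 <- applyRule(x, comp)
  audit <- s1$audit
  score <- s1$audit$score
  if (identical(s1$label, comp@negativeLabel))
    return(new("CascadeResult", sampleId = x@sampleId,
               compositeScore = score, stage1 = s1$label,
               stage2 = NA_character_, flags = logical(0),
               subtypeCalls = logical(0), audit = audit))
  if (!"reactive_mn_al2_ne" %in% names(registry))
    stop("registry has no 'reactive_mn_al2_ne' rule")
  react <- registry[["reactive_mn_al2_ne"]]
  s2 <- reactiveDiscriminant(x, react)
  audit <- rbind(audit, s2$audit)
  if (identical(s2$label, react@negativeLabel))
    return(new("CascadeResult", sampleId = x@sampleId,
               compositeScore = score, stage1 = s1$label,
               stage2 = s2$label, flags = logical(0),
               subtypeCalls = logical(0), audit = audit))
  s3 <- subtypeFlags(x, registry)
  new("CascadeResult", sampleId = x@sampleId, compositeScore = score,
      stage1 = s1$label, stage2 = s2$label, flags = s3$flags,
      subtypeCalls = s3$subtype, audit = rbind(audit, s3$audit))
})

#' @rdname cascadeClassify
#' @export
setMethod("cascadeClassify", "CPDCohort", function(x, registry) {
  results <- lapply(seq_len(ncol(x)), function(i)
    cascadeClassify(getRecord(x, i), registry))
  subtypes <- sort(unique(stats::na.omit(vapply(.subtypeRules(registry),
    function(r) r@subtype, character(1)))))
  pick <- function(res, st) {
    if (!length(res@subtypeCalls) || !st %in% names(res@subtypeCalls))
      NA else res@subtypeCalls[[st]]
  }
  out <- S4Vectors::DataFrame(
    compositeScore = vapply(results, function(r) r@compositeScore,
                            numeric(1)),
    stage1 = vapply(results, function(r) r@stage1, character(1)),
    stage2 = vapply(results, function(r) r@stage2, character(1)),
    row.names = colnames(x))
  for (st in subtypes)
    out[[st]] <- vapply(results, pick, logical(1), st = st)
  out$finalCall <- ifelse(out$stage1 == "non-neoplastic", "non-neoplastic",
                          ifelse(is.na(out$stage2), NA_character_,
                                 out$stage2))
  S4Vectors::metadata(out)$audit <- setNames(
    lapply(results, function(r) r@audit), colnames(x))
  out
})

setMethod("show", "CascadeResult", function(object) {
  cat(sprintf("CascadeResult '%s': composite score %.4g -> stage1 %s",
              object@sampleId, object@compositeScore, object@stage1))
  if (!is.na(object@stage2)) cat(" -> stage2", object@stage2)
  cat("\n")
  if (length(object@subtypeCalls)) {
    f <- object@subtypeCalls
    cat("  subtype flags:",
        paste(sprintf("%s=%s", names(f), ifelse(is.na(f), "not-evaluated",
                                                f)), collapse = ", "), "\n")
  }
  cat(sprintf("  audit trail: %d rule evaluations\n", nrow(object@audit)))
})
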