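# Calibration pipeline: candidate screening by hypothesis tests, ROC
# analysis with DeLong confidence intervals, AUC-gated selection and
# Youden cutoff determination; re-derives discriminant rules from any
# labelled cohort.

#' Lilliefors-corrected Kolmogorov--Smirnov normality test
#'
#' Tests a sample against a normal distribution with estimated mean and
#' SD (the Lilliefors correction accounts for the estimation). Recorded
#' during calibration but not used to gate the pipeline.
#'
#' @param values numeric vector, n >= 5 with positive variance.
#' @return an object of class `htest` (see `[nortest::lillie.test]`).
#' @export
ksNormality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5L)
    stop("normality test requires at least 5 observations")
  if (stats::sd(values) == 0)
    stop("degenerate input: zero variance")
  nortest::lillie.test(values)
}

#' Two-group difference test for one parameter
#'
#' Two-sided t-test between two groups of parameter values; the Welch
#' (unequal-variance) form is the default, the Student form is available
#' by flag.
#'
#' @param a,b numeric vectors, each with n >= 2; at least one with
#'   positive variance.
#' @param varEqual use the Student (pooled-variance) form.
#' @param alpha candidate-selection level.
#' @return list with elements `test` (`"welch_t"` or `"student_t"`),
#'   `statistic`, `df`, `p.value` and `selected` (`p.value < alpha`).
#' @export
groupDifferenceTest <- function(a, b, varEqual = FALSE, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("degenerate input: zero variance in both groups")
  tt <- stats::t.test(a, b, var.equal = varEqual,
                      alternative = "two.sided")
  list(test = if (varEqual) "student_t" else "welch_t",
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, selected = tt$p.value < alpha)
}

# Games-Howell pairwise comparisons: Welch-type standard errors and
# degrees of freedom with studentized-range reference distribution.
# No installed package provides this post hoc test.
.gamesHowell <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  m <- tapply(values, g, mean)
  v <- tapply(values, g, stats::var)
  n <- tapply(values, g, length)
  pairs <- utils::combn(levels(g), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    diff = NA_real_, df = NA_real_, p.value = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se2 <- v[a] / n[a] + v[b] / n[b]
    t <- abs(m[a] - m[b]) / sqrt(se2)
    df <- se2^2 / ((v[a] / n[a])^2 / (n[a] - 1) +
                   (v[b] / n[b])^2 / (n[b] - 1))
    out$diff[i] <- unname(m[a] - m[b])
    out$df[i] <- unname(df)
    out$p.value[i] <- stats::ptukey(t * sqrt(2), nmeans = k, df = df,
                                    lower.tail = FALSE)
  }
  out
}

#' Multi-group screen: ANOVA with homogeneity-of-variance branching
#'
#' Levene's test (mean-centred) decides the branch: with homogeneous
#' variances a one-way ANOVA with Tukey HSD pairwise comparisons is run;
#' otherwise a Welch ANOVA with Games--Howell pairwise comparisons. The
#' omnibus p-value gates candidate selection; pairwise results are
#' reported alongside.
#'
#' @param values numeric vector of parameter values.
#' @param groups group labels (>= 3 levels, each with n >= 2 and
#'   positive variance).
#' @param alpha selection level for the omnibus test.
#' @param homogeneityAlpha level of the Levene pre-test.
#' @return list with elements `branch` (`"anova_tukey"` or
#'   `"welch_games_howell"`), `levene.p`, `p.value` (omnibus),
#'   `pairwise` (data frame `group1`, `group2`, `diff`, `p.value`) and
#'   `selected`.
#' @export
multiGroupScreen <- function(values, groups, alpha = 0.05,
                             homogeneityAlpha = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  g <- droplevels(factor(groups[keep]))
  if (nlevels(g) < 3L) stop("need at least 3 groups")
  n <- tapply(values, g, length)
  if (any(n < 2L))
    stop("group(s) with fewer than 2 observations: ",
         paste(names(n)[n < 2L], collapse = ", "))
  v <- tapply(values, g, stats::var)
  if (any(v == 0))
    stop("degenerate group(s) with zero variance: ",
         paste(names(v)[v == 0], collapse = ", "))
  lev <- car::leveneTest(values ~ g, center = mean)
  levP <- lev[["Pr(>F)"]][1]
  if (levP >= homogeneityAlpha) {
    fit <- stats::aov(values ~ g)
    omnibus <- summary(fit)[[1]][["Pr(>F)"]][1]
    tuk <- stats::TukeyHSD(fit)$g
    # TukeyHSD orders comparisons like combn(levels, 2) with the pair
    # reversed ("l2-l1"); reconstruct labels from the levels rather than
    # parsing row names (labels may themselves contain '-')
    pairs <- utils::combn(levels(g), 2)
    pw <- data.frame(
      group1 = pairs[2, ], group2 = pairs[1, ],
      diff = tuk[, "diff"], p.value = tuk[, "p adj"],
      row.names = NULL, stringsAsFactors = FALSE)
    branch <- "anova_tukey"
  } else {
    omnibus <- stats::oneway.test(values ~ g, var.equal = FALSE)$p.value
    pw <- .gamesHowell(values, g)[, c("group1", "group2", "diff",
                                      "p.value")]
    branch <- "welch_games_howell"
  }
  list(branch = branch, levene.p = levP, p.value = omnibus,
       pairwise = pw, selected = omnibus < alpha)
}

#' Empirical ROC analysis
#'
#' Builds the empirical ROC over all midpoint thresholds via `pROC`,
#' with the AUC equal to the Mann--Whitney probability estimate (ties
#' count one half) and a DeLong 95% confidence interval
#' (Hanley--McNeil available by flag). The orientation is chosen so
#' that the AUC is at least 0.5 unless forced, and is always recorded
#' explicitly. By default a Youden operating point is also selected
#' (see [selectCutoff()]).
#'
#' @param values numeric scores.
#' @param labels class labels (same length).
#' @param positive the positive-class label.
#' @param orientation `"auto"` (default), `"high_is_positive"` or
#'   `"low_is_positive"`.
#' @param ciMethod `"delong"` (default) or `"hanley"` (Hanley--McNeil,
#'   via the bootstrap-free binormal variance as implemented here).
#' @param select select a Youden cutoff into the result.
#' @return an [ROCResult-class].
#' @examples
#' r <- rocCurve(c(3, 5, 1, 4), c("pos", "pos", "neg", "neg"), "pos")
#' auc(r)  # 0.75
#' @export
rocCurve <- function(values, labels, positive,
                     orientation = c("auto", "high_is_positive",
                                     "low_is_positive"),
                     ciMethod = c("delong", "hanley"), select = TRUE) {
  orientation <- match.arg(orientation)
  ciMethod <- match.arg(ciMethod)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  isPos <- labels == positive
  nPos <- sum(isPos); nNeg <- sum(!isPos)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present (positives: ", nPos,
         ", negatives: ", nNeg, ")")
  resp <- factor(ifelse(isPos, "pos", "neg"), levels = c("neg", "pos"))
  fit <- function(dir) pROC::roc(response = resp, predictor = values,
                                 direction = dir, quiet = TRUE,
                                 levels = c("neg", "pos"))
  if (orientation == "auto") {
    # choose the direction whose AUC is at least one half (pROC's own
    # "auto" compares class medians, which does not guarantee this)
    r <- fit("<")
    if (as.numeric(r$auc) < 0.5) r <- fit(">")
  } else {
    r <- fit(switch(orientation, high_is_positive = "<",
                    low_is_positive = ">"))
  }
  auc <- as.numeric(r$auc)
  ci <- if (ciMethod == "delong") {
    # pROC warns that a degenerate (AUC = 1) DeLong interval is
    # uninformative; the interval is still well defined, so keep it
    as.numeric(suppressWarnings(pROC::ci.auc(r, method = "delong")))[c(1, 3)]
  } else .hanleyMcNeilCI(auc, nPos, nNeg)
  ci <- pmin(pmax(ci, 0), 1)
  ci <- c(min(ci[1], auc), max(ci[2], auc))
  res <- new("ROCResult", thresholds = r$thresholds,
             sensitivities = r$sensitivities,
             specificities = r$specificities, auc = auc, aucCI = ci,
             orientation = if (r$direction == "<") "high_is_positive"
                           else "low_is_positive",
             nPositive = nPos, nNegative = nNeg)
  if (select) {
    sel <- tryCatch(selectCutoff(res), error = function(e) NULL)
    if (!is.null(sel)) {
      res@cutoff <- sel$cutoff
      res@cutoffSensitivity <- sel$sensitivity
      res@cutoffSpecificity <- sel$specificity
      res@policy <- sel$policy
    }
  }
  res
}

# Hanley & McNeil (1982) standard error of the empirical AUC.
.hanleyMcNeilCI <- function(auc, nPos, nNeg, level = 0.95) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (nPos - 1) * (q1 - auc^2) +
              (nNeg - 1) * (q2 - auc^2)) / (nPos * nNeg))
  z <- stats::qnorm(1 - (1 - level) / 2)
  auc + c(-1, 1) * z * se
}

#' AUC and operating-point accessors
#'
#' @param x an [ROCResult-class].
#' @return `auc()`: the AUC; `aucCI()`: its 95% CI; `chosenCutoff()`:
#'   the selected cutoff with its sensitivity and specificity.
#' @export
auc <- function(x) { stopifnot(is(x, "ROCResult")); x@auc }

#' @rdname auc
#' @export
aucCI <- function(x) { stopifnot(is(x, "ROCResult")); x@aucCI }

#' @rdname auc
#' @export
chosenCutoff <- function(x) {
  stopifnot(is(x, "ROCResult"))
  c(cutoff = x@cutoff, sensitivity = x@cutoffSensitivity,
    specificity = x@cutoffSpecificity)
}

#' Select an operating cutoff on a ROC curve
#'
#' The default policy maximises Youden's J (sensitivity + specificity
#' - 1); ties are broken by minimising |sensitivity - specificity| and
#' then by the lower threshold. The `"constrained"` policy maximises J
#' among thresholds with sensitivity >= `minSens` and specificity >=
#' `minSpec` and fails explicitly when no threshold qualifies. Reported
#' cutoffs are midpoints between adjacent distinct observed values, so
#' classifying with a strict inequality at the cutoff is unambiguous.
#'
#' @param roc an [ROCResult-class].
#' @param policy `"youden"` or `"constrained"`.
#' @param minSens,minSpec constraints for the `"constrained"` policy.
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youdenJ`,
#'   `policy`.
#' @export
selectCutoff <- function(roc, policy = c("youden", "constrained"),
                         minSens = 0.80, minSpec = 0.80) {
  stopifnot(is(roc, "ROCResult"))
  policy <- match.arg(policy)
  ok <- is.finite(roc@thresholds)
  if (!any(ok)) stop("no finite thresholds: scores are constant")
  th <- roc@thresholds[ok]
  se <- roc@sensitivities[ok]
  sp <- roc@specificities[ok]
  if (policy == "constrained") {
    feas <- se >= minSens & sp >= minSpec
    if (!any(feas))
      stop(sprintf(
        "constrained cutoff selection infeasible: no threshold with sensitivity >= %.2f and specificity >= %.2f",
        minSens, minSpec))
    th <- th[feas]; se <- se[feas]; sp <- sp[feas]
  }
  j <- se + sp - 1
  cand <- which(j >= max(j) - 1e-12)
  if (length(cand) > 1L) {
    bal <- abs(se[cand] - sp[cand])
    cand <- cand[bal <= min(bal) + 1e-12]
  }
  best <- cand[which.min(th[cand])]
  list(cutoff = th[best], sensitivity = se[best], specificity = sp[best],
       youdenJ = j[best], policy = policy)
}

.resolveContrastMask <- function(cohort, labels) {
  labels <- tolower(labels)
  tolower(coarseClass(cohort)) %in% labels |
    tolower(sampleGroups(cohort)) %in% labels
}

#' Screen every parameter of a cohort against a contrast
#'
#' For each CPD parameter: a two-sided t-test between the contrast
#' classes gates candidates at `alpha`; candidates get a full ROC
#' analysis and are retained when the AUC exceeds `aucMin`; results are
#' ranked by AUC, descending.
#'
#' @param cohort a labelled [CPDCohort-class].
#' @param contrast list with elements `positive` and `negative`, each a
#'   vector of coarse classes and/or fine groups (matched
#'   case-insensitively) defining the two classes.
#' @param aucMin AUC retention threshold (0.9 for screening-strength
#'   discriminants; 0.7 for subtype-level utility).
#' @param alpha t-test gate level.
#' @param varEqual use Student rather than Welch t-tests.
#' @return `DataFrame` of the parameters that passed the p-value gate,
#'   ranked by AUC descending, with columns `parameter`, `p.value`,
#'   `auc`, `aucLo`, `aucHi`, `orientation`, `cutoff`, `sensitivity`,
#'   `specificity` and `selected` (`auc > aucMin`). `metadata()` records
#'   `nTested`, `nGated`, `alpha` and `aucMin`; `metadata()$roc` keeps
#'   the [ROCResult-class] objects of the selected parameters.
#' @export
screenParameters <- function(cohort, contrast, aucMin = 0.9,
                             alpha = 0.05, varEqual = FALSE) {
  stopifnot(is(cohort, "CPDCohort"), is.list(contrast))
  pos <- .resolveContrastMask(cohort, contrast$positive)
  neg <- .resolveContrastMask(cohort, contrast$negative)
  if (!any(pos)) stop("contrast positive class matches no samples")
  if (!any(neg)) stop("contrast negative class matches no samples")
  v <- cpdValues(cohort)
  rows <- list()
  rocs <- list()
  nTested <- 0L
  for (p in rownames(v)) {
    a <- v[p, pos]; b <- v[p, neg]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) next
    if (stats::sd(a) == 0 && stats::sd(b) == 0) next
    nTested <- nTested + 1L
    tt <- groupDifferenceTest(a, b, varEqual = varEqual, alpha = alpha)
    if (!tt$selected) next
    r <- rocCurve(c(a, b), rep(c("pos", "neg"), c(length(a), length(b))),
                  positive = "pos")
    rows[[p]] <- data.frame(
      parameter = p, p.value = tt$p.value, auc = r@auc,
      aucLo = r@aucCI[1], aucHi = r@aucCI[2],
      orientation = r@orientation, cutoff = r@cutoff,
      sensitivity = r@cutoffSensitivity,
      specificity = r@cutoffSpecificity,
      selected = r@auc > aucMin, stringsAsFactors = FALSE)
    if (r@auc > aucMin) rocs[[p]] <- r
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parameter = character(0), p.value = numeric(0),
               auc = numeric(0), aucLo = numeric(0), aucHi = numeric(0),
               orientation = character(0), cutoff = numeric(0),
               sensitivity = numeric(0), specificity = numeric(0),
               selected = logical(0))
  out <- out[order(-out$auc), , drop = FALSE]
  res <- S4Vectors::DataFrame(out, row.names = NULL)
  S4Vectors::metadata(res) <- list(nTested = nTested,
                                   nGated = nrow(out), alpha = alpha,
                                   aucMin = aucMin, roc = rocs)
  res
}

#' Build a composite rule from screened parameters
#'
#' Combines selected single parameters into the product/quotient form:
#' positively-oriented parameters multiply in the numerator,
#' negatively-oriented ones in the denominator. The composite's cutoff
#' is re-derived by ROC analysis of the composite scores and cutoff
#' selection on the contrast, and reported to 2 decimals.
#'
#' @param cohort a labelled [CPDCohort-class].
#' @param contrast as in [screenParameters()].
#' @param screen the `DataFrame` from [screenParameters()] (its
#'   `selected` rows are used), or a data frame with columns `parameter`
#'   and `orientation`.
#' @param name rule name.
#' @param policy,minSens,minSpec passed to [selectCutoff()].
#' @return list with `rule` (the composite [DiscriminantRule-class]) and
#'   `roc` (the [ROCResult-class] of the composite score).
#' @export
buildComposite <- function(cohort, contrast, screen,
                           name = "composite", policy = "youden",
                           minSens = 0.80, minSpec = 0.80) {
  screen <- as.data.frame(screen)
  if ("selected" %in% names(screen))
    screen <- screen[screen$selected, , drop = FALSE]
  if (!nrow(screen)) stop("no selected parameters to combine")
  if (anyNA(screen$orientation) || is.null(screen$orientation))
    stop("parameter(s) with undefined orientation: ",
         paste(screen$parameter[is.na(screen$orientation)],
               collapse = ", "))
  num <- screen$parameter[screen$orientation == "high_is_positive"]
  den <- screen$parameter[screen$orientation == "low_is_positive"]
  proto <- discriminantRule(name, numerator = num, denominator = den,
                            cutoff = 0, orientation = "high_is_positive")
  scores <- ruleScore(cohort, proto)
  pos <- .resolveContrastMask(cohort, contrast$positive)
  neg <- .resolveContrastMask(cohort, contrast$negative)
  keep <- (pos | neg) & !is.na(scores)
  r <- rocCurve(scores[keep], ifelse(pos[keep], "pos", "neg"),
                positive = "pos", orientation = "high_is_positive",
                select = FALSE)
  sel <- selectCutoff(r, policy = policy, minSens = minSens,
                      minSpec = minSpec)
  r@cutoff <- sel$cutoff; r@cutoffSensitivity <- sel$sensitivity
  r@cutoffSpecificity <- sel$specificity; r@policy <- sel$policy
  rule <- discriminantRule(name, numerator = num, denominator = den,
                           cutoff = round(sel$cutoff, 2),
                           orientation = "high_is_positive",
                           positiveLabel = paste(contrast$positive,
                                                 collapse = "+"),
                           negativeLabel = paste(contrast$negative,
                                                 collapse = "+"))
  list(rule = rule, roc = r)
}

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: AUC %.3f (95%% CI %.3f-%.3f), %d positives vs %d negatives, %s\n",
              object@auc, object@aucCI[1], object@aucCI[2],
              object@nPositive, object@nNegative, object@orientation))
  if (!is.na(object@cutoff))
    cat(sprintf("  cutoff %.4g (%s): sensitivity %.1f%%, specificity %.1f%%\n",
                object@cutoff, object@policy,
                100 * object@cutoffSensitivity,
                100 * object@cutoffSpecificity))
})
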