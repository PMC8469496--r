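# Clinical diagnostic-accuracy statistics with confidence intervals.

#' Construct a 2x2 confusion table
#'
#' Either from four counts, or from paired truth/prediction label
#' vectors via [confusionCounts()].
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return a [ConfusionCounts-class].
#' @examples
#' ConfusionCounts(262, 2, 4, 16)
#' @export
ConfusionCounts <- function(tp, fp, fn, tn) {
  k <- c(tp, fp, fn, tn)
  if (any(k != round(k))) stop("counts must be whole numbers")
  new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn))
}

#' Cross-tabulate truth against prediction
#'
#' @param truth,predicted equal-length label vectors, each drawn from
#'   `positive` plus exactly one other label.
#' @param positive the positive-class label.
#' @return a [ConfusionCounts-class] whose counts partition the cohort.
#' @examples
#' confusionCounts(c("P", "P", "N", "N"), c("P", "N", "P", "N"), "P")
#' @export
confusionCounts <- function(truth, predicted, positive) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  labs <- unique(c(truth, predicted))
  if (!positive %in% labs)
    stop(sprintf("positive class '%s' not found among labels", positive))
  if (length(setdiff(labs, positive)) > 1L)
    stop("labels must be drawn from the positive class plus one other label; found: ",
         paste(labs, collapse = ", "))
  if (anyNA(truth) || anyNA(predicted)) stop("unknown (NA) label")
  t1 <- truth == positive; p1 <- predicted == positive
  ConfusionCounts(tp = sum(t1 & p1), fp = sum(!t1 & p1),
                  fn = sum(t1 & !p1), tn = sum(!t1 & !p1))
}

#' Binomial proportion confidence intervals
#'
#' `wilsonCCInterval()` is the Newcombe continuity-corrected Wilson
#' score interval (the method behind the VassarStats clinical
#' calculator), computed through `stats::prop.test(correct = TRUE)` and
#' clamped to `[0, 1]`. Plain Wilson and Clopper--Pearson variants are
#' available through `ciMethod` of [accuracyStats()].
#'
#' @param successes,n counts with `0 <= successes <= n`, `n >= 1`.
#' @param level confidence level.
#' @return length-2 numeric `(lower, upper)`.
#' @examples
#' round(wilsonCCInterval(16, 20), 2)   # 0.56 0.93
#' round(wilsonCCInterval(141, 141), 2) # 0.97 1.00
#' @export
wilsonCCInterval <- function(successes, n, level = 0.95) {
  .propCI(successes, n, level, "wilson-cc")
}

.propCI <- function(successes, n, level, method) {
  if (length(successes) != 1L || length(n) != 1L || is.na(successes) ||
      is.na(n) || n < 1 || successes < 0 || successes > n)
    stop("invalid counts: need 0 <= successes <= n, n >= 1")
  ci <- switch(method,
    "wilson-cc" = suppressWarnings(
      stats::prop.test(successes, n, conf.level = level,
                       correct = TRUE)$conf.int),
    "wilson" = suppressWarnings(
      stats::prop.test(successes, n, conf.level = level,
                       correct = FALSE)$conf.int),
    "clopper-pearson" =
      stats::binom.test(successes, n, conf.level = level)$conf.int,
    stop("unknown CI method: ", method))
  pmin(pmax(as.numeric(ci), 0), 1)
}

#' Diagnostic accuracy statistics with 95% confidence intervals
#'
#' Point estimates are the exact defining ratios: sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP), NPV =
#' TN/(TN+FN). A statistic whose denominator is zero is reported as
#' undefined (`NA`), never as 0 or 1. Intervals default to the
#' continuity-corrected Wilson method (see [wilsonCCInterval()]).
#'
#' @param counts a [ConfusionCounts-class].
#' @param ciMethod `"wilson-cc"` (default), `"wilson"` or
#'   `"clopper-pearson"`.
#' @param level confidence level.
#' @return an [AccuracyStats-class].
#' @examples
#' accuracyStats(ConfusionCounts(262, 2, 4, 16))
#' @export
accuracyStats <- function(counts, ciMethod = c("wilson-cc", "wilson",
                                               "clopper-pearson"),
                          level = 0.95) {
  stopifnot(is(counts, "ConfusionCounts"))
  ciMethod <- match.arg(ciMethod)
  num <- c(sensitivity = counts@tp, specificity = counts@tn,
           ppv = counts@tp, npv = counts@tn)
  den <- c(sensitivity = counts@tp + counts@fn,
           specificity = counts@tn + counts@fp,
           ppv = counts@tp + counts@fp,
           npv = counts@tn + counts@fn)
  est <- ifelse(den > 0, num / den, NA_real_)
  names(est) <- names(num)
  ci <- matrix(NA_real_, 4, 2,
               dimnames = list(names(num), c("lower", "upper")))
  for (s in names(num))
    if (den[[s]] > 0)
      ci[s, ] <- .propCI(num[[s]], den[[s]], level, ciMethod)
  new("AccuracyStats", counts = counts, estimates = est, ci = ci,
      ciMethod = ciMethod)
}

#' Extract accuracy estimates and confidence bounds
#'
#' @param x an [AccuracyStats-class].
#' @return `estimates()`: named numeric proportions (`NA` = undefined);
#'   `accuracyCI()`: the 4x2 matrix of 95% bounds (rows sensitivity,
#'   specificity, ppv, npv).
#' @export
estimates <- function(x) { stopifnot(is(x, "AccuracyStats")); x@estimates }

#' @rdname estimates
#' @export
accuracyCI <- function(x) { stopifnot(is(x, "AccuracyStats")); x@ci }

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts (2x2)\n")
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              dimnames = list(prediction = c("positive", "negative"),
                              truth = c("positive", "negative")))
  print(m)
})

setMethod("show", "AccuracyStats", function(object) {
  cat(sprintf("AccuracyStats (%s 95%% CI)\n", object@ciMethod))
  e <- object@estimates
  for (s in names(e)) {
    if (is.na(e[[s]])) {
      cat(sprintf("  %-12s undefined (zero denominator)\n", s))
    } else {
      cat(sprintf("  %-12s %6.2f%%  (95%% CI: %.2f, %.2f)\n", s,
                  100 * e[[s]], object@ci[s, 1], object@ci[s, 2]))
    }
  }
})
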