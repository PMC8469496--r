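test_that("normality test holds its level on normal data and rejects skewed data", {
  set.seed(21)
  rej <- vapply(1:100, function(i) ksNormality(rnorm(500))$p.value < 0.05,
                logical(1))
  expect_lt(mean(rej), 0.12)  # nominal 5% level, binomial tolerance
  set.seed(22)
  expect_lt(ksNormality(rexp(500))$p.value, 0.05)  # power at large n
  expect_error(ksNormality(rep(3, 50)), "zero variance")
  expect_error(ksNormality(rnorm(4)), "at least 5")
})

test_that("two-group test is two-sided, symmetric and agrees with a permutation oracle", {
  a <- c(1.2, 1.9, 2.4, 3.1, 2.2)
  res <- groupDifferenceTest(a, a)
  expect_equal(res$p.value, 1, tolerance = 1e-12)
  expect_identical(res$test, "welch_t")
  expect_false(res$selected)
  set.seed(31)
  x <- rnorm(50); y <- rnorm(50, 3)
  strong <- groupDifferenceTest(x, y)
  expect_lt(strong$p.value, 0.001)
  expect_lt(permutationP(x, y), 0.001)  # independent oracle concurs
  expect_identical(strong$p.value, groupDifferenceTest(y, x)$p.value)
  expect_identical(groupDifferenceTest(x, y, varEqual = TRUE)$test,
                   "student_t")
  expect_error(groupDifferenceTest(rep(1, 5), rep(1, 5)), "zero variance")
  expect_error(groupDifferenceTest(1, c(1, 2)), "at least 2")
})

test_that("multi-group screen branches on variance homogeneity", {
  set.seed(41)
  vals <- c(rnorm(30), rnorm(30), rnorm(30))
  g <- rep(c("a", "b", "c"), each = 30)
  res <- multiGroupScreen(vals, g)
  expect_identical(res$branch, "anova_tukey")  # same scale -> Tukey
  set.seed(42)
  vals2 <- c(rnorm(40, sd = 0.5), rnorm(40, sd = 0.5), rnorm(40, sd = 6))
  res2 <- multiGroupScreen(vals2, g <- rep(c("a", "b", "c"), each = 40))
  expect_identical(res2$branch, "welch_games_howell")
  expect_error(multiGroupScreen(c(rnorm(5), rep(1, 5), rnorm(5)),
                                rep(c("a", "b", "c"), each = 5)),
               "zero variance: b")
  expect_error(multiGroupScreen(rnorm(10), rep(c("a", "b"), each = 5)),
               "at least 3 groups")
})

test_that("a single shifted group is flagged omnibus-wide and pairwise", {
  set.seed(43)
  vals <- c(rnorm(30), rnorm(30), rnorm(30, 5))
  g <- rep(c("g1", "g2", "g3"), each = 30)
  res <- multiGroupScreen(vals, g)
  expect_true(res$selected)
  expect_lt(res$p.value, 0.001)
  pw <- res$pairwise
  hit3 <- grepl("g3", pw$group1) | grepl("g3", pw$group2)
  expect_true(all(pw$p.value[hit3] < 0.01))
  expect_true(all(pw$p.value[!hit3] > 0.05))
  # oracle: pairwise Welch t-tests with Bonferroni reach the same verdict
  welch <- function(i, j) stats::t.test(vals[g == i], vals[g == j])$p.value
  bonf <- p.adjust(c(welch("g1", "g2"), welch("g1", "g3"),
                     welch("g2", "g3")), "bonferroni")
  expect_identical(unname(bonf < 0.05), c(FALSE, TRUE, TRUE))
})

test_that("under the null the omnibus screen selects at about its level", {
  set.seed(44)
  hits <- vapply(1:200, function(i) {
    vals <- rnorm(60)
    multiGroupScreen(vals, rep(c("a", "b", "c"), each = 20))$selected
  }, logical(1))
  expect_gt(mean(hits), 0.005)
  expect_lt(mean(hits), 0.11)  # ~5% with binomial tolerance at 200 reps
})

test_that("Games-Howell agrees with the Welch t-test on two groups up to the range correction", {
  set.seed(45)
  a <- rnorm(25, sd = 1); b <- rnorm(30, 1.5, sd = 3)
  gh <- CPDscreen:::.gamesHowell(c(a, b), rep(c("a", "b"), c(25, 30)))
  tt <- stats::t.test(a, b)
  # with k = 2 the studentized range with sqrt(2) scaling IS the t-test
  expect_equal(gh$p.value, tt$p.value, tolerance = 1e-9)
  expect_equal(gh$df, unname(tt$parameter), tolerance = 1e-9)
})

test_that("empirical ROC matches pair-counting and known examples", {
  r <- rocCurve(c(3, 5, 1, 4), rep(c("pos", "neg"), each = 2), "pos")
  expect_equal(auc(r), 0.75)
  expect_identical(r@orientation, "high_is_positive")
  sep <- rocCurve(c(10, 11, 12, 1, 2, 3),
                  rep(c("pos", "neg"), each = 3), "pos")
  expect_equal(auc(sep), 1)
  expect_error(rocCurve(1:4, rep("pos", 4), "pos"), "both classes")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(51)
  v <- rnorm(80); lab <- rep(c("pos", "neg"), 40)
  a1 <- auc(rocCurve(v, lab, "pos"))
  a2 <- auc(rocCurve(exp(v / 2) + v^3 / 50 + v, lab, "pos"))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("null-label AUC stays near one half", {
  set.seed(52)
  v <- rnorm(200)
  aucs <- vapply(1:100, function(i)
    auc(rocCurve(v, sample(rep(c("pos", "neg"), 100)), "pos")),
    numeric(1))
  # auto-orientation folds the null to >= 0.5; at n = 100 + 100 the
  # folded null SD is ~0.04, so the median sits near 0.53 and even the
  # extreme of 100 replicates stays well under 0.65
  expect_true(all(aucs >= 0.5))
  expect_lt(median(aucs), 0.56)
  expect_lt(max(aucs), 0.65)
})

test_that("cutoff selection follows Youden with the documented tie-breaks", {
  sep <- rocCurve(c(10, 11, 12, 1, 2, 3),
                  rep(c("pos", "neg"), each = 3), "pos", select = FALSE)
  sel <- selectCutoff(sep)
  expect_equal(sel$cutoff, 6.5)  # midpoint of the separating gap
  expect_equal(sel$sensitivity, 1)
  expect_equal(sel$specificity, 1)
  r <- rocCurve(c(3, 5, 1, 4), rep(c("pos", "neg"), each = 2), "pos",
                select = FALSE)
  sel2 <- selectCutoff(r)
  # J = 0.5 at thresholds 2.0 (sens 1, spec .5) and 4.5 (sens .5, spec 1);
  # |sens - spec| ties, the lower threshold wins
  expect_equal(sel2$cutoff, 2.0)
  expect_equal(sel2$sensitivity, 1)
  expect_equal(sel2$specificity, 0.5)
  expect_error(selectCutoff(r, policy = "constrained"), "infeasible")
  expect_equal(selectCutoff(sep, policy = "constrained")$cutoff, 6.5)
})

test_that("cutoff selection is reproducible and order-independent", {
  set.seed(53)
  v <- round(c(rnorm(60, 1), rnorm(60)), 1)
  lab <- rep(c("pos", "neg"), each = 60)
  ref <- selectCutoff(rocCurve(v, lab, "pos", select = FALSE))
  for (i in 1:5) {
    o <- sample(120)
    expect_identical(selectCutoff(rocCurve(v[o], lab[o], "pos",
                                           select = FALSE)), ref)
  }
})

test_that("parameter screening keeps p<0.05 candidates above the AUC gate, ranked", {
  co <- generateCohort(paperLikeConfig(seed = 2))
  contrast <- list(positive = "neoplastic", negative = "non-neoplastic")
  sc <- screenParameters(co, contrast)
  sel <- sc[sc$selected, ]
  expect_setequal(sel$parameter, screeningParams)
  expect_identical(sel$parameter[1], "SD-V-NE")  # strongest discriminant
  expect_true(all(diff(sc$auc) <= 1e-12))        # ranked by AUC desc
  expect_true(all(sc$p.value < 0.05))
  expect_identical(
    sel$orientation[match(c("SD-V-NE", "MN-C-NE"), sel$parameter)],
    c("high_is_positive", "low_is_positive"))
  # vacuous AUC threshold
  expect_identical(sum(screenParameters(co, contrast,
                                        aucMin = 1.1)$selected), 0L)
  expect_error(screenParameters(co, list(positive = "martian",
                                         negative = "normal")),
               "matches no samples")
})

test_that("composite building places orientations in numerator/denominator and re-derives a cutoff", {
  co <- generateCohort(paperLikeConfig(seed = 2))
  contrast <- list(positive = "neoplastic", negative = "non-neoplastic")
  sc <- screenParameters(co, contrast)
  bc <- buildComposite(co, contrast, sc)
  expect_setequal(bc$rule@numerator,
                  c("SD-V-NE", "MN-UMALS-LY", "SD-AL2-MO"))
  expect_identical(bc$rule@denominator, "MN-C-NE")
  expect_gte(auc(bc$roc), max(sc$auc))  # composite beats each single
  expect_true(is.finite(bc$rule@cutoff))
  expect_identical(bc$rule@cutoff, round(bc$rule@cutoff, 2))
  # all-positive orientations produce a pure product
  onlyPos <- data.frame(parameter = c("SD-V-NE", "SD-AL2-MO"),
                        orientation = "high_is_positive")
  bc2 <- buildComposite(co, contrast, onlyPos)
  expect_length(bc2$rule@denominator, 0L)
})
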