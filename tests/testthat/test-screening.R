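test_that("composite score equals the product/quotient of its four inputs", {
  rec1 <- CPDRecord(c(`SD-V-NE` = 1, `MN-UMALS-LY` = 1, `SD-AL2-MO` = 1,
                      `MN-C-NE` = 1))
  expect_identical(compositeScore(rec1), 1)
  rec <- CPDRecord(c(`SD-V-NE` = 25, `MN-UMALS-LY` = 70,
                     `SD-AL2-MO` = 20, `MN-C-NE` = 140))
  expect_identical(compositeScore(rec), 25 * 70 * 20 / 140)  # 250
  # a score of 250 is neoplastic at the published cutoff of 106.44
  comp <- publishedRules()[["neoplastic_composite"]]
  expect_identical(applyRule(rec, comp)$label, "neoplastic")
})

test_that("composite score refuses partial data and zero denominators", {
  rec <- CPDRecord(c(`SD-V-NE` = 25, `MN-UMALS-LY` = 70,
                     `SD-AL2-MO` = 20))
  expect_error(compositeScore(rec), "MN-C-NE")
  rec0 <- CPDRecord(c(`SD-V-NE` = 25, `MN-UMALS-LY` = 70,
                      `SD-AL2-MO` = 20, `MN-C-NE` = 0))
  expect_error(compositeScore(rec0), "denominator parameter is zero")
})

test_that("composite score is homogeneous in each input", {
  set.seed(5)
  for (i in 1:25) {
    x <- runif(4, 1, 200); k <- runif(1, 0.1, 10)
    base <- CPDRecord(setNames(x, screeningParams))
    s <- compositeScore(base)
    for (j in 1:3) {  # numerator terms scale the score by exactly k
      y <- x; y[j] <- k * y[j]
      expect_equal(compositeScore(CPDRecord(setNames(y, screeningParams))),
                   k * s, tolerance = 1e-12)
    }
    y <- x; y[4] <- k * y[4]  # denominator divides it
    expect_equal(compositeScore(CPDRecord(setNames(y, screeningParams))),
                 s / k, tolerance = 1e-12)
  }
})

test_that("rule application uses strict inequalities; equality is negative", {
  r <- publishedRules()
  sdv <- r[["sd_v_ne"]]; mnc <- r[["mn_c_ne"]]
  expect_identical(applyRule(CPDRecord(c(`SD-V-NE` = 20)), sdv)$label,
                   "neoplastic")
  expect_identical(applyRule(CPDRecord(c(`SD-V-NE` = 18.95)), sdv)$label,
                   "non-neoplastic")
  expect_identical(applyRule(CPDRecord(c(`MN-C-NE` = 150)), mnc)$label,
                   "non-neoplastic")
  expect_identical(applyRule(CPDRecord(c(`MN-C-NE` = 148.50)), mnc)$label,
                   "non-neoplastic")
  expect_identical(applyRule(CPDRecord(c(`MN-C-NE` = 140)), mnc)$label,
                   "neoplastic")
})

test_that("classification is invariant under monotone score/cutoff transforms", {
  set.seed(8)
  f <- function(x) log1p(x) * 3 + 1  # strictly increasing
  for (i in 1:50) {
    v <- runif(1, 0, 40); cut <- runif(1, 0, 40)
    raw <- discriminantRule("raw", "SD-V-NE", cutoff = cut,
                            orientation = "high_is_positive")
    trans <- discriminantRule("trans", "SD-V-NE", cutoff = f(cut),
                              orientation = "high_is_positive")
    expect_identical(
      applyRule(CPDRecord(c(`SD-V-NE` = v)), raw)$label,
      applyRule(CPDRecord(c(`SD-V-NE` = f(v))), trans)$label)
  }
})

test_that("reactive discriminant needs a configured orientation and is negative at the boundary", {
  unset <- discriminantRule("reactive_mn_al2_ne", "MN-AL2-NE",
                            cutoff = 147.5, positiveLabel = "neoplastic",
                            negativeLabel = "reactive")
  rec <- CPDRecord(c(`MN-AL2-NE` = 140))
  expect_error(reactiveDiscriminant(rec, unset), "refusing to guess")
  shipped <- publishedRules()[["reactive_mn_al2_ne"]]
  expect_identical(
    reactiveDiscriminant(CPDRecord(c(`MN-AL2-NE` = 147.5)), shipped)$label,
    "reactive")  # boundary -> negative label under either orientation
  expect_identical(
    reactiveDiscriminant(CPDRecord(c(`MN-AL2-NE` = 140)), shipped)$label,
    "neoplastic")
  expect_identical(
    reactiveDiscriminant(CPDRecord(c(`MN-AL2-NE` = 155)), shipped)$label,
    "reactive")
})

test_that("subtype flags are advisory, per rule, with NA for absent inputs", {
  reg <- publishedRules()
  rec <- fullRecord()
  sf <- subtypeFlags(rec, reg)
  expect_length(sf$flags, 7L)
  expect_equal(nrow(sf$audit), 7L)  # all seven evaluated and audited
  # missing SD-C-MO: CLL not evaluated, not FALSE
  rec2 <- fullRecord(); rec2@values <- rec2@values[names(rec2@values) !=
                                                     "SD-C-MO"]
  sf2 <- subtypeFlags(rec2, reg)
  expect_true(is.na(sf2$flags[["cll_sd_c_mo"]]))
  expect_true(is.na(sf2$subtype[["CLL"]]))
  # boundary: SD-MALS-NE exactly at 15.81 is negative for that rule
  sf3 <- subtypeFlags(fullRecord(`SD-MALS-NE` = 15.81), reg)
  expect_false(sf3$flags[["aml_sd_mals_ne"]])
  # any-rule-positive summary
  expect_true(sf3$flags[["aml_sd_umals_ne"]])
  expect_true(sf3$subtype[["AML"]])
})

test_that("cascade short-circuits and keeps an ordered audit trail", {
  reg <- publishedRules()
  # stage-1 negative: 14*50*12/155 = 54.2 < 106.44
  neg <- CPDRecord(c(`SD-V-NE` = 14, `MN-UMALS-LY` = 50,
                     `SD-AL2-MO` = 12, `MN-C-NE` = 155))
  res <- cascadeClassify(neg, reg)
  expect_identical(res@stage1, "non-neoplastic")
  expect_true(is.na(res@stage2))
  expect_length(res@flags, 0L)
  expect_identical(nrow(res@audit), 1L)  # stage 2/3 never evaluated
  # stage-1 positive, ruled out as reactive at stage 2
  reactive <- fullRecord(`MN-AL2-NE` = 155)
  res2 <- cascadeClassify(reactive, reg)
  expect_identical(res2@stage1, "neoplastic")
  expect_identical(res2@stage2, "reactive")
  expect_length(res2@flags, 0L)
  expect_identical(nrow(res2@audit), 2L)
  # full path with an AML-positive flag
  res3 <- cascadeClassify(fullRecord(`SD-MALS-NE` = 20), reg)
  expect_identical(res3@stage2, "neoplastic")
  expect_true(res3@subtypeCalls[["AML"]])
  expect_identical(res3@audit$rule[1:2],
                   c("neoplastic_composite", "reactive_mn_al2_ne"))
  expect_identical(nrow(res3@audit), 9L)
})

test_that("cascade is deterministic, record- and cohort-wise", {
  reg <- publishedRules()
  rec <- fullRecord()
  expect_identical(cascadeClassify(rec, reg), cascadeClassify(rec, reg))
  co <- generateCohort(paperLikeConfig(seed = 3))[, 1:40]
  r1 <- cascadeClassify(co, reg)
  r2 <- cascadeClassify(co, reg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(S4Vectors::metadata(r1)$audit,
                   S4Vectors::metadata(r2)$audit)
  # stage-1 negatives never appear in stage-2/3 audit rows
  auds <- S4Vectors::metadata(r1)$audit
  for (i in which(r1$stage1 == "non-neoplastic"))
    expect_identical(auds[[i]]$rule, "neoplastic_composite")
})

test_that("rule registry round-trips through YAML", {
  reg <- publishedRules()
  f <- withr::local_tempfile(fileext = ".yaml")
  writeRules(reg, f)
  back <- readRules(f)
  expect_identical(names(back), names(reg))
  for (nm in names(reg)) {
    expect_identical(back[[nm]]@cutoff, reg[[nm]]@cutoff)
    expect_identical(back[[nm]]@orientation, reg[[nm]]@orientation)
    expect_identical(back[[nm]]@numerator, reg[[nm]]@numerator)
    expect_identical(back[[nm]]@denominator, reg[[nm]]@denominator)
  }
})
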