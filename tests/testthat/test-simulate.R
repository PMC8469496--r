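test_that("generation is deterministic and leaves the caller's RNG alone", {
  cfg <- paperLikeConfig(seed = 9)
  set.seed(123); before <- runif(1)
  set.seed(123)
  c1 <- generateCohort(cfg)
  mid <- runif(1)
  expect_identical(mid, before)  # RNG state restored
  c2 <- generateCohort(cfg)
  expect_identical(cpdValues(c1), cpdValues(c2))  # bit-identical
  expect_identical(colnames(c1), colnames(c2))
  c3 <- generateCohort(cfg, seed = 10)
  expect_false(identical(cpdValues(c1), cpdValues(c3)))
})

test_that("group sizes and roster match the configured study conditions", {
  co <- generateCohort(paperLikeConfig(seed = 1))
  expect_identical(ncol(co), 1348L)
  expect_identical(nrow(co), 56L)
  tab <- table(sampleGroups(co))
  expect_identical(
    as.integer(tab[c("normal", "reactive", "AML", "APL", "ALL",
                     "lymphoma", "CLL", "CML", "MDS")]),
    c(1056L, 47L, 62L, 30L, 54L, 47L, 28L, 12L, 12L))
  expect_true(all(cpdValues(co) >= 0))
  expect_false(anyNA(cpdValues(co)))
})

test_that("sample moments converge to the specified marginals", {
  base <- CPDscreen:::.baselineParams(c("SD-V-NE", "MN-C-NE"))
  spec <- groupSpec("neoplastic", 10000,
                    data.frame(parameter = c("SD-V-NE", "MN-C-NE"),
                               family = c("normal", "normal"),
                               mean = c(25, 142), sd = c(3, 6)))
  cfg <- simulationConfig(list(spec), seed = 7,
                          labelScheme = c(neoplastic = "neoplastic"))
  co <- generateCohort(cfg)
  v <- cpdValues(co)
  expect_lt(abs(mean(v["SD-V-NE", ]) - 25), 0.1)   # CLT bound at n = 1e4
  expect_lt(abs(sd(v["SD-V-NE", ]) - 3), 0.1)
  expect_lt(abs(mean(v["MN-C-NE", ]) - 142), 0.2)
  # lognormal marginals hit their natural-scale moments too
  ln <- groupSpec("g", 20000,
                  data.frame(parameter = "SD-AL2-MO",
                             family = "lognormal", mean = 19.5, sd = 3))
  col <- generateCohort(simulationConfig(list(ln), seed = 8,
                                         labelScheme = c(g = "neoplastic")))
  expect_lt(abs(mean(cpdValues(col)) - 19.5), 0.1)
  expect_lt(abs(sd(cpdValues(col)) - 3), 0.1)
  expect_true(all(cpdValues(col) > 0))
})

test_that("zero-count groups contribute no records", {
  base <- CPDscreen:::.baselineParams()
  cfg <- simulationConfig(
    list(groupSpec("normal", 5, base), groupSpec("AML", 0, base)),
    seed = 3)
  co <- generateCohort(cfg)
  expect_identical(ncol(co), 5L)
  expect_false("AML" %in% sampleGroups(co))
})

test_that("single-factor correlation induces within-cell-type correlation", {
  base <- CPDscreen:::.baselineParams()
  rho <- 0.6
  co <- generateCohort(simulationConfig(
    list(groupSpec("normal", 4000, base, corFactor = rho)), seed = 5))
  v <- cpdValues(co)
  sameCell <- cor(v["MN-V-NE", ], v["MN-C-NE", ])
  crossCell <- cor(v["MN-V-NE", ], v["MN-C-LY", ])
  expect_gt(sameCell, 0.5)   # latent rho = 0.6
  expect_lt(abs(crossCell), 0.1)
  indep <- generateCohort(simulationConfig(
    list(groupSpec("normal", 4000, base)), seed = 5))
  vi <- cpdValues(indep)
  expect_lt(abs(cor(vi["MN-V-NE", ], vi["MN-C-NE", ])), 0.1)
})

test_that("simulation configs round-trip through YAML", {
  cfg <- pureNoiseConfig(nPerGroup = 4, seed = 17)
  f <- withr::local_tempfile(fileext = ".yaml")
  writeSimulationConfig(cfg, f)
  back <- readSimulationConfig(f)
  expect_identical(back@seed, cfg@seed)
  expect_identical(back@parameters, cfg@parameters)
  expect_identical(back@labelScheme, cfg@labelScheme)
  expect_equal(back@groups[[1]]@params, cfg@groups[[1]]@params)
  expect_identical(cpdValues(generateCohort(back)),
                   cpdValues(generateCohort(cfg)))
})

test_that("the generator writes the exact dialect the reader consumes", {
  co <- generateCohort(pureNoiseConfig(nPerGroup = 6, seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  writeCohort(co, f)
  back <- readCohort(f, labelScheme = labelScheme(co))
  expect_identical(cpdValues(back), cpdValues(co))
  expect_identical(coarseClass(back), coarseClass(co))
})

test_that("seeded end-to-end runs are reproducible", {
  run <- function() {
    co <- generateCohort(paperLikeConfig(seed = 6))
    sc <- screenParameters(co, list(positive = "neoplastic",
                                    negative = "non-neoplastic"))
    res <- cascadeClassify(co[, 1:30])
    list(as.data.frame(sc), as.data.frame(res))
  }
  expect_identical(run(), run())
})
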