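# Shared fixture builders; everything is generated in code.

screeningParams <- c("SD-V-NE", "MN-UMALS-LY", "SD-AL2-MO", "MN-C-NE")

# record scoreable for every published rule
fullRecord <- function(sampleId = "rec", ...) {
  vals <- c(`SD-V-NE` = 25, `MN-UMALS-LY` = 70, `SD-AL2-MO` = 20,
            `MN-C-NE` = 140, `MN-AL2-NE` = 140, `SD-MALS-NE` = 20,
            `SD-UMALS-NE` = 20, `MN-V-NE` = 165, `SD-V-MO` = 38,
            `MN-MALS-NE` = 120, `MN-LMALS-NE` = 115, `SD-C-MO` = 9)
  over <- c(...)
  vals[names(over)] <- over
  CPDRecord(vals, sampleId = sampleId)
}

tinyCohortMatrix <- function() {
  m <- rbind(c(25, 70, 20, 140),
             c(14, 50, 12, 155),
             c(30, 80, 25, 130))
  colnames(m) <- screeningParams
  rownames(m) <- c("s1", "s2", "s3")
  m
}

tinyCohort <- function(group = c("AML", "normal", "ALL")) {
  CPDCohort(tinyCohortMatrix(), group = group)
}

# independent Mann-Whitney AUC oracle: brute-force pair counting,
# ties count one half
pairCountAUC <- function(pos, neg) {
  d <- outer(pos, neg, "-")
  (sum(d > 0) + 0.5 * sum(d == 0)) / length(d)
}

# independent two-sided permutation test oracle for a mean difference
permutationP <- function(a, b, nPerm = 2000, seed = 42) {
  obs <- abs(mean(a) - mean(b))
  x <- c(a, b); na <- length(a)
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    stat <- replicate(nPerm, {
      idx <- sample.int(length(x), na)
      abs(mean(x[idx]) - mean(x[-idx]))
    })
  })
  (sum(stat >= obs) + 1) / (nPerm + 1)
}
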