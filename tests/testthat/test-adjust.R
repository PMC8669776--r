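test_that("the BY correction factor is the harmonic sum", {
  expect_identical(cBY(1), 1)
  expect_identical(cBY(2), 1.5)
  expect_equal(cBY(5), sum(1 / 1:5))
  expect_equal(cBY(5, "negative"), cBY(5, "positive"))
  expect_error(cBY(0), ">= 1")
})

test_that("FDR estimates reproduce the worked example and its structure", {
  p <- example5()
  fdr <- fdrEstimate(p, "BH", pi0 = 1)
  expect_equal(fdr, c(0.025, 0.1225, 5 * 0.050 / 3, 5 * 0.051 / 4, 0.700))
  expect_equal(round(fdr, 3), c(0.025, 0.122, 0.083, 0.064, 0.700))
  # FDR estimates are NOT monotone in rank: 0.122 > 0.083 > 0.064
  expect_gt(fdr[2], fdr[3])
  expect_gt(fdr[3], fdr[4])
  # single p-value: m = rank = 1 so every method is the identity
  for (meth in c("BH", "BY", "Bon", "Holm", "Hoch"))
    expect_equal(fdrEstimate(0.3, meth), 0.3)
  expect_equal(fdrEstimate(0.3, "Sidak"), 0.3)
  # BY multiplies the BH estimate by c(m)
  expect_equal(fdrEstimate(p, "BY")[1], 0.025 * cBY(5))
  # pi0 scales the estimate before capping
  expect_equal(fdrEstimate(p, "BH", pi0 = 0.5), fdr / 2)
  expect_error(fdrEstimate(p, "BH", pi0 = 1.2), "pi0")
})

test_that("exact BH identity holds with pi0 = 1 and no ties", {
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    r <- rank(p)
    expect_equal(fdrEstimate(p, "BH"), pmin(1, p * length(p) / r))
  }
})

test_that("adjusted p-values match the step-smoothed forms", {
  p <- example5()
  expect_equal(round(adjustPValues(p, "BH"), 3),
               c(0.025, 0.064, 0.064, 0.064, 0.700))
  expect_equal(adjustPValues(p, "Hoch"),
               c(0.025, 0.102, 0.102, 0.102, 0.700))
  expect_equal(adjustPValues(p, "Holm"),
               c(0.025, 0.196, 0.196, 0.196, 0.700))
  expect_equal(adjustPValues(p, "Bon"), pmin(1, p * 5))
  expect_equal(adjustPValues(p, "Sidak"), 1 - (1 - p)^5)
})

test_that("adjusted p-values agree with brute-force min/max oracles and p.adjust", {
  set.seed(11)
  for (i in 1:30) {
    p <- runif(sample(2:25, 1))
    for (meth in c("BH", "BY", "Holm", "Hoch"))
      expect_equal(adjustPValues(p, meth), bruteAdjust(p, meth))
    # independent cross-check against the standard library implementation
    expect_equal(adjustPValues(p, "BH"), p.adjust(p, "BH"))
    expect_equal(adjustPValues(p, "BY"), p.adjust(p, "BY"))
    expect_equal(adjustPValues(p, "Holm"), p.adjust(p, "holm"))
    expect_equal(adjustPValues(p, "Hoch"), p.adjust(p, "hochberg"))
    expect_equal(adjustPValues(p, "Bon"), p.adjust(p, "bonferroni"))
  }
})

test_that("adjusted p-values are monotone in rank; all outputs lie in [0,1]", {
  set.seed(21)
  for (i in 1:25) {
    p <- runif(sample(2:60, 1))
    o <- order(p)
    for (meth in c("BH", "BY", "Bon", "Sidak", "Holm", "Hoch")) {
      adj <- adjustPValues(p, meth)
      fdr <- fdrEstimate(p, meth, pi0 = runif(1))
      expect_true(all(adj >= 0 & adj <= 1))
      expect_true(all(fdr >= 0 & fdr <= 1))
      if (meth %in% c("BH", "BY", "Holm", "Hoch"))
        expect_true(all(diff(adj[o]) >= -1e-12))
    }
    # power ordering of the FWER step procedures
    expect_true(all(adjustPValues(p, "Holm") <=
                      adjustPValues(p, "Bon") + 1e-12))
    expect_true(all(adjustPValues(p, "Hoch") <=
                      adjustPValues(p, "Holm") + 1e-12))
  }
})

test_that("BY collapses to BH when the correction factor is 1", {
  set.seed(31)
  p <- runif(40)
  expect_identical(adjustPValues(p, "BY", cm = 1), adjustPValues(p, "BH"))
  expect_identical(fdrEstimate(p, "BY", cm = 1), fdrEstimate(p, "BH"))
})

test_that("raw step search reproduces the worked rejection sets", {
  p <- example5()
  r05 <- stepRejection(p, 0.05, "BH")
  expect_identical(r05$k, 1L)
  expect_identical(r05$reject, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  r07 <- stepRejection(p, 0.07, "BH")
  expect_identical(r07$k, 4L)
  expect_identical(r07$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # but only two of those four have FDR estimates below 0.07
  expect_identical(which(fdrEstimate(p, "BH") < 0.07), c(1L, 4L))
  expect_error(stepRejection(p, 0), "gamma")
  expect_error(stepRejection(p, 1), "gamma")
})

test_that("step search equals thresholding the adjusted p-values", {
  set.seed(41)
  for (i in 1:200) {
    p <- runif(sample(2:50, 1))
    gamma <- runif(1, 0.01, 0.3)
    for (meth in c("BH", "BY", "Holm", "Hoch", "Bon", "Sidak")) {
      flags <- stepRejection(p, gamma, meth)$reject
      expect_identical(flags, adjustPValues(p, meth) <= gamma)
    }
  }
})

test_that("pFDR assembles a coherent result object", {
  p <- example5()
  res <- pFDR(p, adjustMethod = "BH", threshold = 0.05)
  expect_s4_class(res, "FDRResult")
  expect_equal(fdrs(res), fdrEstimate(p, "BH"))
  expect_equal(adjustedPValues(res), adjustPValues(p, "BH"))
  expect_equal(pvalues(res), p)
  expect_identical(rejectFlags(res),
                   c("Reject.H0", rep("FTR.H0", 4)))
  expect_identical(pi0Value(res), 1)
  expect_identical(threshold(res), 0.05)
  expect_identical(adjustMethod(res), "BH")
  expect_equal(round(res@zvalues, 3), c(2.807, 1.969, 1.960, 1.951, 0.385))
  expect_equal(round(lowerBoundFDR(res), 3),
               c(0.019, 0.126, 0.128, 0.130, 0.481))
})

test_that("Bonferroni and Sidak give identical FDRs and adjusted p at pi0 = 1", {
  set.seed(51)
  p <- runif(30)
  for (meth in c("Bon", "Sidak")) {
    res <- pFDR(p, adjustMethod = meth)
    expect_equal(fdrs(res), adjustedPValues(res))
  }
})

test_that("pFDR options: justFdr, sortResults, estimated pi0, m = 1", {
  p <- example5()
  expect_equal(pFDR(p, justFdr = TRUE), fdrEstimate(p, "BH"))
  sorted <- pFDR(p, sortResults = TRUE)
  expect_true(!is.unsorted(fdrs(sorted)))
  expect_identical(sorted@feature, order(fdrEstimate(p, "BH")))
  est <- pFDR(p, estimMethod = "pounds")
  expect_equal(pi0Value(est), min(1, 2 * mean(p)))
  one <- pFDR(0.04)
  expect_equal(fdrs(one), 0.04)
  expect_equal(adjustedPValues(one), 0.04)
  expect_identical(rejectFlags(one), "Reject.H0")
})

test_that("supplied Z-vectors must be consistent with the p-values", {
  p <- example5()
  z <- pToZ(p)
  res <- pFDR(p, zvalues = z)
  expect_equal(res@zvalues, z)
  expect_error(pFDR(p, zvalues = z + 1), "inconsistent")
  expect_error(pFDR(p, zvalues = z[1:3]), "match")
})

test_that("NA removal changes m, unlike counting NAs as features", {
  p <- c(0.01, NA, 0.5)
  res <- pFDR(p, adjustMethod = "Bon")
  expect_equal(nFeatures(res), 2L)
  expect_equal(adjustedPValues(res), pmin(1, c(0.01, 0.5) * 2))
  expect_error(pFDR(p, naRm = FALSE), "NA")
})
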