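test_that("Scott's rule bin count matches the closed form", {
  p <- seq(1 / 1001, 1000 / 1001, length.out = 1000)
  h <- 3.49 * sd(p) * 1000^(-1 / 3)
  expect_identical(scottBinCount(p), as.integer(ceiling(1 / h)))
  expect_identical(scottBinCount(p), 10L)
  p4 <- c(0.2, 0.4, 0.6, 0.8)
  expect_identical(scottBinCount(p4),
                   as.integer(ceiling(1 / (3.49 * sd(p4) * 4^(-1 / 3)))))
  # degenerate spread falls back to ceiling(sqrt(m))
  expect_identical(scottBinCount(rep(0.5, 9)), 3L)
  expect_error(scottBinCount(0.5), "at least 2")
})

test_that("Last Histogram Height counts the bin adjacent to 1", {
  # one value per bin center: exactly uniform occupancy
  expect_equal(pi0Value(pi0LastHist(seq(0.005, 0.995, by = 0.01),
                                    breaks = 100)), 1)
  expect_equal(pi0Value(pi0LastHist(seq(0.05, 0.95, by = 0.1),
                                    breaks = 10)), 1)
  e1 <- pi0LastHist(c(0.1, 0.2, 0.3, 0.9), breaks = 4)
  expect_equal(pi0Value(e1), 1)
  expect_identical(e1@bins, 4L)
  expect_equal(e1@lastBinHeight, 1)
  e0 <- pi0LastHist(c(0.1, 0.2, 0.3, 0.4), breaks = 4)
  expect_equal(pi0Value(e0), 0)
  # p = 1 counts in the closed final bin
  expect_equal(pi0LastHist(c(0.1, 1.0), breaks = 2)@lastBinHeight, 1)
  expect_error(pi0LastHist(c(0.1, 0.9), breaks = 0), "bin count")
})

test_that("Last Histogram Height is invariant to permutation and capped", {
  set.seed(61)
  p <- runif(500)
  a <- pi0Value(pi0LastHist(p))
  for (i in 1:5)
    expect_identical(pi0Value(pi0LastHist(sample(p))), a)
  expect_lte(a, 1)
  # concentration near 1 would push the raw ratio above 1; the cap holds
  expect_equal(pi0Value(pi0LastHist(c(rep(0.99, 8), 0.1, 0.2), breaks = 5)),
               1)
})

test_that("Storey's estimator matches direct tail counts on single lambdas", {
  expect_equal(pi0Value(pi0Storey(c(0.1, 0.2, 0.6, 0.8), lambdaGrid = 0.5)),
               1)  # 2 / (4 * 0.5)
  expect_equal(pi0Value(pi0Storey(c(0.1, 0.2, 0.3, 0.8), lambdaGrid = 0.5)),
               0.5)  # 1 / (4 * 0.5)
  expect_error(pi0Storey(c(0.1, 0.9), lambdaGrid = c(0.2, 1.5)), "lambda")
  expect_error(pi0Storey(c(0.1, 0.9), lambdaGrid = c(0.5, 0.2)),
               "increasing")
  expect_error(pi0Storey(c(0.1, 0.9), lambdaGrid = numeric(0)), "non-empty")
})

test_that("Storey's smoothed estimate is near 1 on uniform nulls", {
  # pi0(lambda) is unbiased for 1 under the uniform null
  set.seed(71)
  ests <- replicate(100, pi0Value(pi0Storey(runif(10000))))
  expect_gte(mean(ests), 0.95)
  expect_lte(mean(ests), 1.0)
})

test_that("the Pounds estimator doubles the mean p-value and caps at 1", {
  expect_equal(pi0Value(pi0Pounds(rep(0.25, 10))), 0.5)
  expect_equal(pi0Value(pi0Pounds(rep(0.75, 10))), 1)
  expect_equal(pi0Value(pi0Pounds(c(0.1, 0.3))), 0.4)
})

test_that("getPi0 dispatches and set.pi0 ignores the data", {
  set.seed(81)
  p <- runif(200)
  expect_equal(pi0Value(getPi0(p, estimMethod = "set.pi0", setPi0 = 0.8)),
               0.8)
  expect_equal(pi0Value(getPi0(p)), 1)  # default set.pi0 = 1
  expect_identical(pi0Value(getPi0(p, estimMethod = "last.hist",
                                   histBreaks = 7)),
                   pi0Value(pi0LastHist(p, breaks = 7)))
  expect_identical(pi0Value(getPi0(p, estimMethod = "storey")),
                   pi0Value(pi0Storey(p)))
  expect_identical(pi0Value(getPi0(p, estimMethod = "pounds")),
                   pi0Value(pi0Pounds(p)))
  expect_error(getPi0(p, estimMethod = "nope"), "unknown")
  expect_error(getPi0(p, estimMethod = "set.pi0", setPi0 = 2), "setPi0")
})

test_that("every estimator stays in [0, 1] over random mixtures", {
  set.seed(91)
  for (i in 1:20) {
    pi0 <- runif(1)
    m <- 300
    n0 <- round(m * pi0)
    p <- c(runif(n0), runif(m - n0, 0, 0.02))
    for (meth in c("last.hist", "storey", "pounds")) {
      v <- pi0Value(getPi0(p, estimMethod = meth))
      expect_gte(v, 0); expect_lte(v, 1)
    }
  }
})

test_that("estimators are close to 1 on pure-null data on average", {
  set.seed(101)
  reps <- 200
  vals <- matrix(NA_real_, reps, 3,
                 dimnames = list(NULL, c("last.hist", "storey", "pounds")))
  for (r in seq_len(reps)) {
    p <- runif(1000)
    for (meth in colnames(vals))
      vals[r, meth] <- pi0Value(getPi0(p, estimMethod = meth))
  }
  for (meth in colnames(vals))
    expect_lt(abs(mean(vals[, meth]) - 1), 0.07)
})
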