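test_that("the generator honors label counts and the [0,1] range", {
  b <- simulatePValues(m = 100, pi0True = 0.8, reps = 5, seed = 3)
  expect_identical(dim(pvalues(b)), c(5L, 100L))
  expect_identical(sum(nullLabels(b)), 80L)
  expect_identical(sum(!nullLabels(b)), 20L)
  expect_true(all(pvalues(b) >= 0 & pvalues(b) <= 1))
  # alternatives from Uniform(0, 0.01) stay below 0.01
  expect_true(all(pvalues(b)[, !nullLabels(b)] <= 0.01))
  expect_error(simulatePValues(0, 0.5), "m must")
  expect_error(simulatePValues(10, 1.5), "pi0True")
})

test_that("identical spec and seed give bit-identical batches", {
  a <- simulatePValues(m = 50, pi0True = 0.6, reps = 4, seed = 42)
  b <- simulatePValues(m = 50, pi0True = 0.6, reps = 4, seed = 42)
  expect_identical(pvalues(a), pvalues(b))
  cc <- simulatePValues(m = 50, pi0True = 0.6, reps = 4, seed = 43)
  expect_false(identical(pvalues(a), pvalues(cc)))
  # generation does not disturb the caller's RNG stream
  set.seed(5); before <- runif(1)
  set.seed(5)
  invisible(simulatePValues(m = 10, pi0True = 1, seed = 9)); after <- runif(1)
  expect_identical(before, after)
})

test_that("pure-null batches look uniform", {
  b <- simulatePValues(m = 200, pi0True = 1, reps = 100, seed = 7)
  expect_true(all(nullLabels(b)))
  pv <- pvalues(b)
  ks <- vapply(seq_len(nrow(pv)),
               function(r) suppressWarnings(ks.test(pv[r, ], "punif"))$p.value,
               numeric(1))
  # at alpha = 0.01 the vast majority of replicates must pass
  expect_lt(mean(ks < 0.01), 0.05)
})

test_that("gaussian-shift alternatives use the stated sidedness transform", {
  b <- simulatePValues(m = 10, pi0True = 0, altKind = "gaussian_shift",
                       altParams = list(mean = 3, sd = 0.5), reps = 200,
                       seed = 13)
  pv <- as.vector(pvalues(b))
  # two-sided p from N(3, 0.5) z-values: median near 2*(1-Phi(3))
  expect_lt(abs(median(pv) - 2 * pnorm(3, lower.tail = FALSE)), 0.01)
  g <- simulatePValues(m = 10, pi0True = 0, altKind = "gaussian_shift",
                       altParams = list(mean = 2), reps = 50, seed = 13,
                       sidedness = "greater")
  expect_true(all(pvalues(g) >= 0 & pvalues(g) <= 1))
})

test_that("realized FDR bookkeeping is correct at the edges", {
  b <- simulatePValues(m = 100, pi0True = 0.8, reps = 20, seed = 17)
  ev0 <- empiricalFDR(b, gamma = 0)
  expect_true(all(ev0$perRep$selections == 0))
  expect_true(all(ev0$perRep$fdr == 0))
  ev <- empiricalFDR(b, method = "BH", gamma = 0.05)
  with(ev$perRep, {
    expect_true(all(false_selections <= selections))
    expect_true(all(fdr >= 0 & fdr <= 1))
    expect_true(all(power >= 0 & power <= 1))
  })
})

test_that("BH controls and BY is more conservative at desk scale", {
  b <- simulatePValues(m = 100, pi0True = 0.8, reps = 200, seed = 23)
  bh <- empiricalFDR(b, method = "BH", gamma = 0.05)
  by <- empiricalFDR(b, method = "BY", gamma = 0.05)
  expect_lte(bh$meanFDR, 0.05 + 3 * bh$seFDR)
  expect_lte(by$meanFDR, bh$meanFDR + 1e-12)
  expect_lte(by$meanPower, bh$meanPower + 1e-12)
})

test_that("Bonferroni's family-wise error rate is controlled", {
  b <- simulatePValues(m = 100, pi0True = 1, reps = 400, seed = 29)
  ev <- empiricalFDR(b, method = "Bon", gamma = 0.05)
  fwer <- mean(ev$perRep$false_selections > 0)
  se <- sqrt(fwer * (1 - fwer) / 400)
  expect_lte(fwer, 0.05 + 3 * max(se, sqrt(0.05 * 0.95 / 400)))
})

test_that("pi0 benchmark tables are reproducible and exact for set.pi0", {
  tab <- evaluatePi0Methods(c(0.8, 1.0), methods = c("pounds", "set.pi0"),
                            setPi0 = 0.8, reps = 10, m = 200, seed = 31)
  tab2 <- evaluatePi0Methods(c(0.8, 1.0), methods = c("pounds", "set.pi0"),
                             setPi0 = 0.8, reps = 10, m = 200, seed = 31)
  expect_identical(tab, tab2)
  expect_named(tab, c("method", "pi0_true", "alt_kind", "mean_estimate",
                      "mse"))
  # the fixed estimator has zero MSE against its own truth
  expect_identical(tab$mse[tab$method == "set.pi0" & tab$pi0_true == 0.8], 0)
  expect_identical(tab$mean_estimate[tab$method == "set.pi0"], c(0.8, 0.8))
})

test_that("last.hist recovers the null proportion at reduced scale", {
  tab <- evaluatePi0Methods(c(0.8, 1.0), methods = "last.hist", reps = 50,
                            m = 1000, seed = 37)
  expect_true(all(abs(tab$mean_estimate - tab$pi0_true) < 0.05))
})
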