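test_that("a pure-null z panel yields intercept 1 and slope 0 within the jackknife CI", {
  ld <- syntheticLdPanel(5000, mSnps = 1e6, seed = 2)
  set.seed(5)
  z <- rnorm(5000)
  est <- univariateIntercept(z, ld, n = 50000)
  expect_lt(abs(intercept(est) - 1), 2.5 * interceptSE(est))
  expect_lt(abs(ldscSlope(est)), 2.5 * ldscSlopeSE(est))
  expect_gt(interceptSE(est), 0)
})

test_that("constant test-statistic inflation moves the intercept, not the slope", {
  ld <- syntheticLdPanel(5000, mSnps = 1e6, seed = 2)
  set.seed(6)
  z <- sqrt(1.2) * rnorm(5000)   # E[z^2] = 1.2 under the null
  est <- univariateIntercept(z, ld, n = 50000)
  expect_lt(abs(intercept(est) - 1.2), 2.5 * interceptSE(est))
  expect_lt(abs(ldscSlope(est)), 2.5 * ldscSlopeSE(est))
})

test_that("the univariate slope recovers the generating heritability", {
  ld <- syntheticLdPanel(20000, mSnps = 1e6, seed = 7)
  zz <- simulateLdscZscores(ld, h2_1 = 0.4, h2_2 = 0.4, rg = 0,
                            n1 = 100000, n2 = 100000, seed = 8)
  est <- univariateIntercept(zz$z1, ld, n = 100000)
  expect_lt(abs(ldscSlope(est) - 0.4), 3 * ldscSlopeSE(est))
})

test_that("cross-trait intercepts detect independence, overlap and duplication", {
  ld <- syntheticLdPanel(8000, mSnps = 1e6, seed = 9)
  set.seed(10)
  z1 <- rnorm(8000); z2 <- rnorm(8000)
  ind <- crossTraitIntercept(z1, z2, ld, 50000, 50000)
  expect_lt(abs(intercept(ind)), 2.5 * interceptSE(ind))
  dup <- crossTraitIntercept(z1, z1, ld, 50000, 50000)
  expect_lt(abs(intercept(dup) - 1), 2.5 * interceptSE(dup))

  n1 <- 60000; n2 <- 40000
  zz <- simulateLdscZscores(ld, 0.3, 0.3, 0.4, n1, n2,
                            nOverlap = 0.5 * n1, rPheno = 0.24, seed = 12)
  ov <- crossTraitIntercept(zz$z1, zz$z2, ld, n1, n2)
  expect_lt(abs(intercept(ov) - 0.5 * n1 * 0.24 / sqrt(n1 * n2)),
            2.5 * interceptSE(ov))
})

test_that("cross-trait regression is symmetric in its two traits", {
  ld <- syntheticLdPanel(3000, mSnps = 1e6, seed = 13)
  zz <- simulateLdscZscores(ld, 0.3, 0.2, 0.5, 40000, 50000,
                            nOverlap = 10000, rPheno = 0.3, seed = 14)
  a <- crossTraitIntercept(zz$z1, zz$z2, ld, 40000, 50000)
  b <- crossTraitIntercept(zz$z2, zz$z1, ld, 50000, 40000)
  expect_equal(intercept(a), intercept(b), tolerance = 1e-12)
  expect_equal(ldscSlope(a), ldscSlope(b), tolerance = 1e-12)
})

test_that("intercept-to-overlap conversion reproduces the published arithmetic", {
  o1 <- overlapFromIntercept(0.1287, 183728, 159471, 0.24)
  expect_equal(nOverlapRaw(o1), 0.1287 * sqrt(183728 * 159471) / 0.24)
  expect_equal(round(nOverlapRaw(o1), -1), 91790)
  o2 <- overlapFromIntercept(0.0161, 98225, 159471, 0.24)
  expect_equal(round(nOverlapRaw(o2)), 8396)
  expect_equal(nOverlap(overlapFromIntercept(0, 1e5, 1e5, 0.24)), 0)
  expect_error(overlapFromIntercept(0.1, 1e5, 1e5, 0), "zero")
})

test_that("negative intercepts clamp to zero overlap but keep the raw value", {
  o <- overlapFromIntercept(-0.05, 1e5, 1e5, 0.24)
  expect_equal(nOverlap(o), 0)
  expect_lt(nOverlapRaw(o), 0)
})

test_that("overlap conversion exactly inverts the forward intercept formula", {
  expect_equal(interceptFromOverlap(85503, 183728, 159471, 0.24),
               85503 * 0.24 / sqrt(183728 * 159471))
  expect_equal(round(interceptFromOverlap(85503, 183728, 159471, 0.24), 4),
               0.1199)
  expect_equal(interceptFromOverlap(0, 1e5, 2e5, 0.3), 0)
  set.seed(15)
  for (i in 1:25) {
    n1 <- sample(1e4:2e5, 1); n2 <- sample(1e4:2e5, 1)
    ns <- runif(1, 0, min(n1, n2)); r <- runif(1, 0.05, 0.9)
    expect_equal(nOverlap(overlapFromIntercept(
      interceptFromOverlap(ns, n1, n2, r), n1, n2, r)), ns,
      tolerance = 1e-9)
  }
  expect_error(interceptFromOverlap(-5, 1e5, 1e5, 0.2), "nOverlap")
})

test_that("genetic correlation recovers self-correlation, independence and a known rg", {
  ld <- syntheticLdPanel(15000, mSnps = 1e6, seed = 16)
  zz <- simulateLdscZscores(ld, 0.35, 0.25, 0.9, 80000, 70000, seed = 17)
  same <- geneticCorrelation(zz$z1, zz$z1, ld, 80000, 80000)
  expect_lt(abs(rgEstimate(same) - 1), 3 * rgSE(same) + 0.02)
  est <- geneticCorrelation(zz$z1, zz$z2, ld, 80000, 70000)
  expect_lt(abs(rgEstimate(est) - 0.9), 3 * rgSE(est))
  z0 <- simulateLdscZscores(ld, 0.35, 0.25, 0, 80000, 70000, seed = 18)
  ind <- geneticCorrelation(z0$z1, z0$z2, ld, 80000, 70000)
  expect_lt(abs(rgEstimate(ind)), 3 * rgSE(ind))
})

test_that("degenerate LDSC inputs are rejected", {
  ld <- syntheticLdPanel(300, seed = 19)
  set.seed(20)
  expect_error(univariateIntercept(rnorm(100), ldScores(ld)$ld_score[1:100],
                                   1000), "at least 200")
  expect_error(univariateIntercept(rnorm(250), ld, 1000), "aligned")
  expect_error(univariateIntercept(rnorm(300), ld, 1000, nBlocks = 400),
               "fewer variants")
})
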