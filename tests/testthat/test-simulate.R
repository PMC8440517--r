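test_that("offspring dosages are Mendelian-consistent with parental dosages", {
  cfg <- simConfig(3000, 20, alleleFreqs = 0.4, trueEffects = c(0, 0),
                   seed = 60)
  fam <- simulateFamilies(cfg)
  G <- familyGenotypes(fam)
  # child of the participant: at most one allele more than each parent
  # could have transmitted; homozygous parents force transmission
  self <- G$self; child <- G$child; mother <- G$mother
  expect_true(all(child >= 0 & child <= 2))
  expect_true(all(child[self == 0] <= 1))  # participant transmits 0
  expect_true(all(self[mother == 2] >= 1)) # mother transmits 1
  expect_true(all(self[mother == 0] <= 1))
})

test_that("parent-offspring genotype correlation is one half", {
  cfg <- simConfig(50000, 4, alleleFreqs = 0.3, trueEffects = c(0, 0),
                   seed = 61)
  fam <- simulateFamilies(cfg)
  G <- familyGenotypes(fam)
  for (j in 1:4) {
    expect_lt(abs(cor(G$mother[, j], G$self[, j]) - 0.5), 0.015)
    expect_lt(abs(cor(G$self[, j], G$child[, j]) - 0.5), 0.015)
    # grandmother-grandchild relatedness is one quarter
    expect_lt(abs(cor(G$mother[, j], G$child[, j]) - 0.25), 0.015)
  }
})

test_that("marginal regressions mix direct and transmitted maternal signal", {
  cfg <- simConfig(50000, 1, alleleFreqs = 0.5,
                   trueEffects = matrix(c(0.1, 0), 1), residualSd = 1,
                   seed = 62)
  fam <- simulateFamilies(cfg)
  y1 <- familyPhenotypes(fam)$own
  G <- familyGenotypes(fam)
  bSelf <- coef(lm(y1 ~ G$self[, 1]))[2]
  bMother <- coef(lm(y1 ~ G$mother[, 1]))[2]
  expect_lt(abs(bSelf - 0.1), 0.02)
  expect_lt(abs(bMother - 0.05), 0.02)
})

test_that("overlap masks hit the requested intersection exactly", {
  m0 <- makeOverlapDesign(1000, 0, seed = 63)
  expect_equal(sum(m0$own & m0$offspring), 0L)
  expect_equal(sum(m0$own | m0$offspring), 1000L)
  m1 <- makeOverlapDesign(1000, 1, seed = 63)
  expect_identical(m1$own, m1$offspring)
  m3 <- makeOverlapDesign(1000, 0.3, seed = 63)
  expect_equal(sum(m3$own & m3$offspring), 300L)
  expect_lte(sum(m3$own | m3$offspring), 1000L)
})

test_that("GWAS on a null trait is calibrated and deterministic", {
  cfg <- simConfig(4000, 400, trueEffects = c(0, 0), seed = 64)
  fam <- simulateFamilies(cfg)
  tab <- runGwas(fam, "self", "own", mask = sampleMasks(fam)$own)
  v <- variantData(tab)
  p <- 2 * pnorm(-abs(v$beta / v$se))
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(p)))
  tab2 <- runGwas(fam, "self", "own", mask = sampleMasks(fam)$own)
  expect_identical(variantData(tab), variantData(tab2))
})

test_that("marginal GWAS slopes follow the o + m/2 structural expectation", {
  cfg <- simConfig(30000, 60, trueEffects = c(0.06, -0.04),
                   residualCorr = 0.2, overlapFraction = 0, seed = 65)
  sim <- simulateGwasPair(cfg)
  b <- betaMatrix(sim$pair)
  expect_lt(abs(mean(b[, "own"]) - (0.06 + 0.5 * (-0.04))), 0.005)
  expect_lt(abs(mean(b[, "offspring"]) - (-0.04 + 0.5 * 0.06)), 0.005)
})

test_that("the whole pipeline is bit-reproducible under a fixed seed", {
  cfg <- simConfig(2000, 30, trueEffects = c(0.05, -0.02),
                   residualCorr = 0.1, overlapFraction = 0.4, seed = 66)
  s1 <- simulateGwasPair(cfg)
  s2 <- simulateGwasPair(cfg)
  expect_identical(betaMatrix(s1$pair), betaMatrix(s2$pair))
  expect_identical(s1$masks, s2$masks)
  # block partitioning does not change the statistics
  s3 <- simulateGwasPair(cfg, blockSize = 7L)
  expect_equal(dim(betaMatrix(s3$pair)), dim(betaMatrix(s1$pair)))
})

test_that("simulated z-scores reproduce the bivariate LDSC moments", {
  ld <- syntheticLdPanel(30000, mSnps = 1e6, seed = 67)
  zz <- simulateLdscZscores(ld, h2_1 = 0, h2_2 = 0, rg = 0,
                            n1 = 5e4, n2 = 5e4, nOverlap = 0, seed = 68)
  expect_lt(abs(mean(zz$z1 * zz$z2)), 3 / sqrt(30000))
  expect_equal(mean(zz$z1^2), 1, tolerance = 0.03)

  zz2 <- simulateLdscZscores(ld, 0.3, 0.3, 0.5, 5e4, 5e4,
                             nOverlap = 2e4, rPheno = 0.3, seed = 69)
  ct <- crossTraitIntercept(zz2$z1, zz2$z2, ld, 5e4, 5e4)
  expect_lt(abs(intercept(ct) - interceptFromOverlap(2e4, 5e4, 5e4, 0.3)),
            2.5 * interceptSE(ct))
  expect_error(simulateLdscZscores(ld, 1.5, 0.3, 0, 1e4, 1e4), "herit")
})

test_that("configurations are validated before any simulation runs", {
  expect_error(simConfig(100, 10, alleleFreqs = 1.2), "frequencies")
  expect_error(simConfig(100, 10, residualCorr = 1), "residualCorr")
  expect_error(simConfig(100, 10, overlapFraction = 2), "overlapFraction")
  expect_error(simConfig(100, 10, trueEffects = matrix(0, 5, 2)),
               "trueEffects")
  # auto residual completion fails loudly when genetics exceed unit variance
  cfg <- simConfig(100, 400, trueEffects = c(0.5, 0.5))
  expect_error(simulateFamilies(cfg), "genetic variance")
})
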