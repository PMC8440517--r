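test_that("with an identity intercept matrix the solver equals the linear adjustment", {
  set.seed(40)
  pair <- makePair(betaOwn = rnorm(50, 0, 0.05), seOwn = runif(50, 0.005, 0.02),
                   betaOff = rnorm(50, 0, 0.05), seOff = runif(50, 0.005, 0.02))
  g <- conditionalGwas(pair, interceptMatrix = diag(2))
  adj <- adjustTable(pair)
  expect_equal(g$beta_offspring, adj$beta_offspring, tolerance = 1e-12)
  expect_equal(g$se_offspring, adj$se_offspring, tolerance = 1e-12)
  expect_equal(g$se_maternal, adj$se_maternal, tolerance = 1e-12)
  expect_equal(g$p_maternal, adj$p_maternal, tolerance = 1e-12)
})

test_that("point estimates do not depend on the sampling covariance", {
  e1 <- conditionalSolve(c(1.0, 0.5), c(0.01, 0.02))
  e2 <- conditionalSolve(c(1.0, 0.5), c(0.05, 0.01),
                         cmat = matrix(c(1, 0.4, 0.4, 1), 2))
  expect_equal(unname(betaAdj(e1)), c(1, 0))
  expect_equal(unname(betaAdj(e2)), c(1, 0))
})

test_that("the solved covariance matches Monte-Carlo sampling of the solver", {
  set.seed(41)
  model <- birthweightModel()
  A <- coefMatrix(model)
  theta0 <- c(0.05, -0.02)
  se <- c(0.012, 0.015)
  cmat <- matrix(c(1, 0.3, 0.3, 1), 2)
  V <- cmat * tcrossprod(se)
  L <- chol(V)
  draws <- matrix(rnorm(2 * 10000), 10000) %*% L
  beta <- sweep(draws, 2, drop(A %*% theta0), "+")
  est <- t(apply(beta, 1, function(b)
    betaAdj(conditionalSolve(b, se, cmat, model))))
  target <- solve(A) %*% V %*% t(solve(A))
  expect_lt(max(abs(cov(est) - target)) / max(abs(target)), 0.05)
  one <- conditionalSolve(beta[1, ], se, cmat, model)
  expect_equal(unname(covAdj(one)), unname(target), tolerance = 1e-12)
})

test_that("the intercept matrix flags duplicated and disjoint GWAS correctly", {
  ld <- syntheticLdPanel(4000, mSnps = 1e6, seed = 42)
  set.seed(43)
  z <- rnorm(4000)
  se <- rep(0.01, 4000)
  meta <- data.frame(variant_id = sprintf("snp%06d", 1:4000),
                     chrom = "1", pos = 1e6 * (1:4000),
                     effect_allele = "A", other_allele = "G", eaf = 0.3,
                     stringsAsFactors = FALSE)
  mk <- function(zv, lab) makeTable(cbind(meta, data.frame(beta = zv * 0.01,
                                                           se = 0.01,
                                                           n = 50000)), lab)
  dup <- new("HarmonizedSet",
             tables = list(a = mk(z, "a"), b = mk(z, "b")),
             droppedLog = data.frame(variant_id = character(),
                                     reason = character()))
  cm <- estimateInterceptMatrix(dup, ld)
  expect_equal(cm["a", "b"], 1, tolerance = 0.15)
  set.seed(44)
  dis <- new("HarmonizedSet",
             tables = list(a = mk(z, "a"), b = mk(rnorm(4000), "b")),
             droppedLog = data.frame(variant_id = character(),
                                     reason = character()))
  cm2 <- estimateInterceptMatrix(dis, ld)
  expect_lt(abs(cm2["a", "b"]), 0.1)
  expect_equal(diag(cm2), c(a = 1, b = 1))
})

test_that("the fertility pipeline recovers female, male and sibling effects", {
  cfg <- simConfig(12000, 120, trueEffects = c(0.07, 0.05, -0.06),
                   residualCorr = 0, overlapFraction = 0, seed = 45,
                   model = "fertility")
  fam <- simulateFamilies(cfg)
  gm <- runGwas(fam, "mother", "children", traitLabel = "mothered")
  gf <- runGwas(fam, "father", "children", traitLabel = "fathered")
  gc_ <- runGwas(fam, "child", "children", traitLabel = "siblings")
  hs <- new("HarmonizedSet", tables = list(mothered = gm, fathered = gf,
                                           siblings = gc_),
            droppedLog = data.frame(variant_id = character(),
                                    reason = character()))
  res <- conditionalGwas(hs, model = fertilityModel(),
                         interceptMatrix = diag(3))
  for (lab in c("female", "male", "sibling")) {
    tr <- c(female = 0.07, male = 0.05, sibling = -0.06)[[lab]]
    est <- res[[paste0("beta_", lab)]]
    expect_lt(abs(mean(est) - tr), 3.5 * sd(est) / sqrt(length(est)))
  }
  # single-variant consistency with the scalar solver
  one <- conditionalSolve(unname(betaMatrix(hs)[1, ]),
                          unname(seMatrix(hs)[1, ]),
                          model = fertilityModel())
  expect_equal(res$beta_female[1], betaAdj(one)[["female"]])
  expect_equal(res$se_sibling[1], seAdj(one)[["sibling"]])
})

test_that("dropping the male GWAS changes the sibling estimate", {
  # the three-trait and two-trait models attribute the male contribution
  # differently, so sibling effects must differ on the same data
  cfg <- simConfig(8000, 60, trueEffects = c(0.06, 0.05, -0.04),
                   residualCorr = 0, overlapFraction = 0, seed = 46,
                   model = "fertility")
  fam <- simulateFamilies(cfg)
  gm <- runGwas(fam, "mother", "children", traitLabel = "mothered")
  gf <- runGwas(fam, "father", "children", traitLabel = "fathered")
  gc_ <- runGwas(fam, "child", "children", traitLabel = "siblings")
  empty <- data.frame(variant_id = character(), reason = character())
  hs3 <- new("HarmonizedSet", tables = list(mothered = gm, fathered = gf,
                                            siblings = gc_),
             droppedLog = empty)
  hs2 <- new("HarmonizedSet", tables = list(mothered = gm, siblings = gc_),
             droppedLog = empty)
  r3 <- conditionalGwas(hs3, fertilityModel(), interceptMatrix = diag(3))
  r2 <- conditionalGwas(hs2, fertilityModel(threeTraits = FALSE),
                        interceptMatrix = diag(2))
  expect_gt(mean(abs(r3$beta_sibling - r2$beta_sibling)), 0.005)
})

test_that("structural misconfigurations are rejected", {
  expect_error(conditionalSolve(c(1, 2, 3), c(0.1, 0.1)), "model order")
  expect_error(conditionalSolve(c(1, 2), c(0.1, -0.1)), "positive")
  pair <- makePair(0.1, 0.01, 0.1, 0.01)
  expect_error(conditionalGwas(pair, fertilityModel()), "expects 3")
  expect_error(conditionalGwas(pair), "LD panel or an intercept")
})
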