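test_that("a well-formed file parses into a complete table", {
  path <- writeSumstatsFixture(threeVariantDf(), name = "ok.txt")
  tab <- readSumstats(path, traitLabel = "bw")
  expect_s4_class(tab, "SumstatsTable")
  expect_equal(nVariants(tab), 3L)
  expect_equal(variantData(tab)$beta, c(0.05, -0.02, 0.1))
  expect_equal(traitLabel(tab), "bw")
})

test_that("rows violating invariants are dropped with reason codes", {
  df <- threeVariantDf()
  df$se[2] <- 0
  path <- writeSumstatsFixture(df, name = "badse.txt")
  tab <- readSumstats(path)
  expect_equal(nVariants(tab), 2L)
  log <- attr(variantData(tab), "droppedLog")
  expect_equal(log$variant_id, "rs2")
  expect_equal(log$reason, "nonpositive se")
})

test_that("a missing mapped column raises a configuration error", {
  df <- threeVariantDf()
  names(df)[names(df) == "beta"] <- "b"
  path <- writeSumstatsFixture(df, name = "nomap.txt")
  expect_error(readSumstats(path), "required column")
  expect_equal(nVariants(readSumstats(path, columnMap = c(beta = "b"))), 3L)
})

test_that("write then re-read round-trips the table", {
  path <- writeSumstatsFixture(threeVariantDf(), name = "rt0.txt")
  tab <- readSumstats(path, traitLabel = "bw")
  out <- file.path(tempdir(), "rt1.txt")
  writeSumstats(tab, out)
  back <- readSumstats(out, columnMap = c(beta = "beta_bw", se = "se_bw"),
                       traitLabel = "bw")
  v0 <- variantData(tab); v1 <- variantData(back)
  attr(v0, "droppedLog") <- NULL; attr(v1, "droppedLog") <- NULL
  expect_equal(v1[names(v0)], v0)
})

test_that("swapped alleles are reconciled by flipping beta and eaf", {
  df1 <- threeVariantDf()
  df2 <- df1
  df2[1, c("effect_allele", "other_allele")] <- df1[1, c("other_allele", "effect_allele")]
  df2$beta[1] <- -df1$beta[1]
  df2$eaf[1] <- 1 - df1$eaf[1]
  hs <- harmonizeSumstats(list(a = makeTable(df1), b = makeTable(df2)))
  expect_equal(nVariants(hs), 3L)
  b <- betaMatrix(hs)
  expect_equal(b[, "a"], b[, "b"])
  expect_equal(variantData(harmonizedTables(hs)$b)$eaf, df1$eaf)
})

test_that("low-MAF and strand-ambiguous variants are excluded as configured", {
  df1 <- threeVariantDf()
  df1$eaf[3] <- 0.003                       # below the 0.5% SEM threshold
  df2 <- df1
  hs <- harmonizeSumstats(list(a = makeTable(df1), b = makeTable(df2)),
                          mafMin = 0.005)
  expect_equal(nVariants(hs), 2L)
  expect_true(any(droppedLog(hs)$variant_id == "rs3" &
                  droppedLog(hs)$reason == "maf"))

  df1 <- threeVariantDf()
  df1$effect_allele[1] <- "A"; df1$other_allele[1] <- "T"
  hs2 <- harmonizeSumstats(list(a = makeTable(df1), b = makeTable(df1)),
                           dropStrandAmbiguous = TRUE)
  expect_equal(nVariants(hs2), 2L)
  expect_true(any(droppedLog(hs2)$reason == "strand ambiguous"))
})

test_that("irreconcilable alleles and discordant frequencies are dropped", {
  df1 <- threeVariantDf()
  df2 <- df1
  df2$effect_allele[2] <- "G"    # C/T vs G/T: no swap, no complement
  hs <- harmonizeSumstats(list(a = makeTable(df1), b = makeTable(df2)))
  expect_equal(nVariants(hs), 2L)
  expect_true(any(droppedLog(hs)$reason == "allele mismatch"))

  df3 <- threeVariantDf()
  df3$eaf[1] <- df1$eaf[1] + 0.25
  hs2 <- harmonizeSumstats(list(a = makeTable(df1), b = makeTable(df3)))
  expect_true(any(droppedLog(hs2)$reason == "eaf mismatch"))
})

test_that("harmonization is invariant to reorienting one input", {
  df1 <- threeVariantDf()
  flipped <- df1
  flipped[c("effect_allele", "other_allele")] <- df1[c("other_allele", "effect_allele")]
  flipped$beta <- -df1$beta
  flipped$eaf <- 1 - df1$eaf
  h1 <- harmonizeSumstats(list(a = makeTable(df1), b = makeTable(df1)))
  h2 <- harmonizeSumstats(list(a = makeTable(df1), b = makeTable(flipped)))
  expect_equal(betaMatrix(h2), betaMatrix(h1))
  expect_equal(variantData(harmonizedTables(h2)$b),
               variantData(harmonizedTables(h1)$b))
})

test_that("no variant appears in both the output and the dropped log", {
  df1 <- threeVariantDf()
  df2 <- df1
  df2$effect_allele[2] <- "G"
  df1$eaf[3] <- 0.001
  hs <- harmonizeSumstats(list(a = makeTable(df1), b = makeTable(df2)),
                          mafMin = 0.005)
  kept <- variantData(harmonizedTables(hs)$a)$variant_id
  expect_length(intersect(kept, droppedLog(hs)$variant_id), 0L)
})

test_that("LD-score panels read from text and validate", {
  df <- data.frame(variant_id = c("rs1", "rs2"), ld_score = c(1.5, 80))
  path <- writeSumstatsFixture(df, name = "ld.txt")
  ld <- readLDScorePanel(path, mSnps = 1e5)
  expect_s4_class(ld, "LDScorePanel")
  expect_equal(mSnps(ld), 1e5)
  df$ld_score[1] <- 0.5   # below self-LD floor
  path2 <- writeSumstatsFixture(df, name = "ldbad.txt")
  expect_error(readLDScorePanel(path2), "ld_score")
})
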