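# in-code fixtures shared across test files

# write a small summary-statistics file and return its path
writeSumstatsFixture <- function(df, dir = tempdir(), name = "sumstats.txt") {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a well-formed three-variant table
threeVariantDf <- function() {
  data.frame(variant_id = c("rs1", "rs2", "rs3"),
             chrom = c("1", "1", "2"),
             pos = c(1000L, 2000L, 500L),
             effect_allele = c("A", "C", "G"),
             other_allele = c("G", "T", "A"),
             eaf = c(0.3, 0.5, 0.12),
             beta = c(0.05, -0.02, 0.1),
             se = c(0.01, 0.02, 0.03),
             n = c(1000, 1000, 1000),
             stringsAsFactors = FALSE)
}

# SumstatsTable built directly from a data.frame
makeTable <- function(df, label = "trait", phenoVar = 1) {
  new("SumstatsTable", traitLabel = label, variants = df,
      phenotypeVariance = phenoVar)
}

# quick harmonized pair from parallel beta/se vectors on shared variants
makePair <- function(betaOwn, seOwn, betaOff, seOff, n1 = 1e5, n2 = 1e5,
                     eaf = 0.3) {
  p <- length(betaOwn)
  meta <- data.frame(variant_id = sprintf("rs%d", seq_len(p)),
                     chrom = "1", pos = 1e6 * seq_len(p),
                     effect_allele = "A", other_allele = "G",
                     eaf = rep_len(eaf, p), stringsAsFactors = FALSE)
  own <- makeTable(cbind(meta, data.frame(beta = betaOwn, se = seOwn, n = n1)),
                   "own")
  off <- makeTable(cbind(meta, data.frame(beta = betaOff, se = seOff, n = n2)),
                   "offspring")
  new("HarmonizedSet", tables = list(own = own, offspring = off),
      droppedLog = data.frame(variant_id = character(),
                              reason = character(), stringsAsFactors = FALSE))
}
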