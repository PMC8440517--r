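## Synthetic family data: trio genotypes under Hardy-Weinberg and
## Mendelian transmission, phenotypes from the generative counterpart of
## the biometrical path models, per-SNP OLS GWAS on configurable
## (possibly overlapping) subsamples, and z-score panels following the
## bivariate LD score regression expectation.

## one master seed expands into independent child seeds per component so
## genotypes, masks, residuals and LDSC panels are separately reproducible
.childSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

## Mendelian transmission: each parent passes one of two alleles at random
.transmit <- function(g) {
  matrix(rbinom(length(g), 1L, g / 2), nrow(g), ncol(g))
}

## variant bookkeeping shared by the GWAS emitters: deterministic IDs and
## coordinates (1 Mb spacing, cycling chromosomes 1..22)
.variantMeta <- function(nVariants) {
  data.frame(variant_id = sprintf("snp%06d", seq_len(nVariants)),
             chrom = as.character(rep_len(1:22, nVariants)),
             pos = 1e6 * (((seq_len(nVariants) - 1) %/% 22) + 1),
             effect_allele = "A", other_allele = "G",
             stringsAsFactors = FALSE)
}

#' Bundle and validate simulation settings
#'
#' @param nFamilies number of independent families (trios).
#' @param nVariants number of variants, simulated in linkage equilibrium.
#' @param alleleFreqs per-variant allele frequency in (0, 1); a scalar is
#'   recycled.
#' @param trueEffects nVariants x K matrix of generating conditional
#'   effects ((o, m) for the birth weight model, (f, m, s) for fertility);
#'   a length-K vector is recycled across variants.
#' @param residualSd per-phenotype residual standard deviation, or NULL to
#'   complete each phenotype to unit total variance.
#' @param residualCorr correlation of the two phenotype residuals
#'   (birth weight model only), in (-1, 1).
#' @param overlapFraction fraction of families contributing to both GWAS
#'   subsamples.
#' @param seed master RNG seed.
#' @param model "birthweight" (two effects) or "fertility" (three).
#' @return a validated list of settings for \code{\link{simulateFamilies}}.
#' @export
simConfig <- function(nFamilies, nVariants, alleleFreqs = 0.3,
                      trueEffects = c(0, 0), residualSd = NULL,
                      residualCorr = 0, overlapFraction = 0, seed = 1L,
                      model = c("birthweight", "fertility")) {
  model <- match.arg(model)
  K <- if (model == "birthweight") 2L else 3L
  if (!is.matrix(trueEffects))
    trueEffects <- matrix(trueEffects, nVariants, K, byrow = TRUE)
  if (ncol(trueEffects) != K || nrow(trueEffects) != nVariants)
    stop("trueEffects must be nVariants x ", K, " for the ", model, " model")
  alleleFreqs <- rep_len(alleleFreqs, nVariants)
  if (any(alleleFreqs <= 0 | alleleFreqs >= 1))
    stop("allele frequencies must lie strictly in (0, 1)")
  if (abs(residualCorr) >= 1) stop("residualCorr must lie in (-1, 1)")
  if (overlapFraction < 0 || overlapFraction > 1)
    stop("overlapFraction must lie in [0, 1]")
  list(nFamilies = as.integer(nFamilies), nVariants = as.integer(nVariants),
       alleleFreqs = alleleFreqs, trueEffects = trueEffects,
       residualSd = residualSd, residualCorr = residualCorr,
       overlapFraction = overlapFraction, seed = as.integer(seed),
       model = model)
}

## genetic variance of each phenotype implied by the generative model
.geneticVariance <- function(config) {
  q <- 2 * config$alleleFreqs * (1 - config$alleleFreqs)
  eff <- config$trueEffects
  if (config$model == "birthweight") {
    o <- eff[, 1]; m <- eff[, 2]
    v <- sum(q * (o^2 + m^2 + o * m))
    c(v, v)
  } else {
    f <- eff[, 1]; m <- eff[, 2]; s <- eff[, 3]
    sum(q * (f^2 + m^2 + s^2 + f * s + m * s))
  }
}

## genotype draws for one block of variants (fixed draw order so blocks
## are reproducible from their seed alone)
.genotypeBlock <- function(seed, nFamilies, freqs, model) {
  set.seed(seed)
  draw <- function() matrix(rbinom(nFamilies * length(freqs), 2L,
                                   rep(freqs, each = nFamilies)),
                            nFamilies, length(freqs))
  if (model == "birthweight") {
    gMother <- draw(); gFather <- draw()
    gSelf <- .transmit(gMother) + .transmit(gFather)
    gMate <- draw()
    gChild <- .transmit(gSelf) + .transmit(gMate)
    list(mother = gMother, self = gSelf, child = gChild)
  } else {
    gMother <- draw(); gFather <- draw()
    gChild <- .transmit(gMother) + .transmit(gFather)
    list(mother = gMother, father = gFather, child = gChild)
  }
}

#' Simulate family genotypes and phenotypes
#'
#' Parental genotypes are drawn under Hardy-Weinberg equilibrium at the
#' configured allele frequencies and offspring dosages by fair Mendelian
#' transmission, giving the 0.5 parent-child (and 0.25
#' grandparent-grandchild) genotype correlations the path models encode.
#' Under the birth weight model the phenotypes are
#' Y1 = o G_self + m G_mother + e1 (own outcome) and
#' Y2 = o G_child + m G_self + e2 (offspring outcome) with
#' corr(e1, e2) = residualCorr; under the fertility model a single family
#' size outcome Y = f G_mother + m G_father + s G_child + e is shared by
#' the three GWAS designs. With \code{residualSd = NULL} the residual
#' variance completes each phenotype to unit total variance, matching the
#' standardized-trait convention of the estimators.
#'
#' @param config a list from \code{\link{simConfig}}.
#' @return a \linkS4class{FamilyDataset} with GWAS subsample masks from
#'   \code{\link{makeOverlapDesign}}.
#' @export
simulateFamilies <- function(config) {
  seeds <- .childSeeds(config$seed, 3L)
  G <- .genotypeBlock(seeds[1], config$nFamilies, config$alleleFreqs,
                      config$model)
  gvar <- .geneticVariance(config)
  nPheno <- if (config$model == "birthweight") 2L else 1L
  sdRes <- config$residualSd
  if (is.null(sdRes)) {
    if (any(gvar >= 1))
      stop("genetic variance >= 1; set residualSd explicitly")
    sdRes <- sqrt(1 - gvar)
  }
  sdRes <- rep_len(sdRes, nPheno)
  set.seed(seeds[2])
  eff <- config$trueEffects
  if (config$model == "birthweight") {
    u1 <- rnorm(config$nFamilies)
    u2 <- config$residualCorr * u1 +
      sqrt(1 - config$residualCorr^2) * rnorm(config$nFamilies)
    phen <- list(own = drop(G$self %*% eff[, 1] + G$mother %*% eff[, 2]) +
                   sdRes[1] * u1,
                 offspring = drop(G$child %*% eff[, 1] + G$self %*% eff[, 2]) +
                   sdRes[2] * u2)
  } else {
    phen <- list(children = drop(G$mother %*% eff[, 1] + G$father %*% eff[, 2] +
                                 G$child %*% eff[, 3]) +
                   sdRes[1] * rnorm(config$nFamilies))
  }
  masks <- makeOverlapDesign(config$nFamilies, config$overlapFraction,
                             seeds[3])
  new("FamilyDataset", genotypes = G, phenotypes = phen,
      alleleFreqs = config$alleleFreqs, trueEffects = eff,
      masks = masks, model = config$model)
}

#' Two GWAS subsample masks with a prescribed overlap
#'
#' Builds two subsample masks whose intersection holds exactly
#' round(overlapFraction * nFamilies) families and whose union covers the
#' sample; fraction 0 gives disjoint halves, fraction 1 identical masks.
#' Families are assigned by a seeded permutation.
#'
#' @param nFamilies total number of families.
#' @param overlapFraction fraction in [0, 1].
#' @param seed RNG seed for the permutation.
#' @return named list of two logical masks (own, offspring).
#' @export
makeOverlapDesign <- function(nFamilies, overlapFraction, seed = 1L) {
  if (overlapFraction < 0 || overlapFraction > 1)
    stop("overlapFraction must lie in [0, 1]")
  set.seed(seed)
  perm <- sample.int(nFamilies)
  k <- round(overlapFraction * nFamilies)
  s1 <- (nFamilies + k) %/% 2L
  own <- logical(nFamilies); off <- logical(nFamilies)
  own[perm[seq_len(s1)]] <- TRUE
  off[perm[seq.int(s1 - k + 1L, nFamilies)]] <- TRUE
  list(own = own, offspring = off)
}

#' Per-SNP ordinary least squares GWAS on a subsample
#'
#' Regresses the chosen phenotype (standardized within the subsample) on
#' each genotype column of the chosen family member. Variants with a
#' constant genotype in the subsample are emitted with missing beta/se.
#' Allele frequencies are the subsample dosage means / 2.
#'
#' @param data a \linkS4class{FamilyDataset}.
#' @param genotype which member's genotype to test ("self", "mother",
#'   "father", "child").
#' @param phenotype which phenotype to test ("own", "offspring",
#'   "children").
#' @param mask logical subsample membership (defaults to everyone).
#' @param traitLabel label for the emitted table.
#' @return a \linkS4class{SumstatsTable}.
#' @export
runGwas <- function(data, genotype, phenotype, mask = NULL,
                    traitLabel = paste0(phenotype, "_on_", genotype)) {
  G <- familyGenotypes(data)[[genotype]]
  if (is.null(G)) stop("no '", genotype, "' genotypes in this dataset")
  y <- familyPhenotypes(data)[[phenotype]]
  if (is.null(y)) stop("no '", phenotype, "' phenotype in this dataset")
  if (is.null(mask)) mask <- rep(TRUE, length(y))
  if (!any(mask)) stop("empty subsample mask")
  G <- G[mask, , drop = FALSE]
  y <- y[mask]
  n <- length(y)
  y <- (y - mean(y)) / sd(y)
  gbar <- colMeans(G)
  gc_ <- sweep(G, 2L, gbar)
  sxx <- colSums(gc_^2)
  sxy <- drop(crossprod(gc_, y))
  syy <- sum(y^2)
  ok <- sxx > 0
  beta <- se <- rep(NA_real_, ncol(G))
  beta[ok] <- sxy[ok] / sxx[ok]
  rss <- pmax(syy - beta[ok]^2 * sxx[ok], 0)
  se[ok] <- sqrt(rss / ((n - 2L) * sxx[ok]))
  meta <- .variantMeta(ncol(G))
  v <- cbind(meta, data.frame(eaf = pmin(pmax(gbar / 2, 1e-6), 1 - 1e-6),
                              beta = beta, se = se, n = n))
  flagged <- v[!ok, , drop = FALSE]
  v <- v[!is.na(v$beta) & !is.na(v$se) & v$se > 0, , drop = FALSE]
  rownames(v) <- NULL
  attr(v, "droppedLog") <- data.frame(variant_id = flagged$variant_id,
                                      reason = rep("constant genotype",
                                                   nrow(flagged)),
                                      stringsAsFactors = FALSE)
  new("SumstatsTable", traitLabel = traitLabel, variants = v,
      phenotypeVariance = 1)
}

#' Simulate a harmonized own/offspring GWAS pair with known truth
#'
#' Full generative pipeline for the birth weight design: families are
#' simulated (in variant blocks, so large panels fit in memory), the own
#' phenotype is tested against the participant's genotype on one subsample
#' and the offspring phenotype against the same genotype on another, with
#' the prescribed overlap between subsamples. Phenotypes aggregate every
#' variant's contribution before any GWAS is run; blocks are regenerated
#' from their child seeds for the association pass.
#'
#' @param config a \code{\link{simConfig}} list (model "birthweight").
#' @param blockSize variants per genotype block.
#' @return a list with elements \code{pair} (a
#'   \linkS4class{HarmonizedSet} of the two GWAS), \code{truth}
#'   (data.frame of generating effects), \code{masks}, \code{nOverlap}
#'   and \code{rPhenoOverlap} (empirical phenotype correlation among
#'   overlapping families; NA when there is no overlap).
#' @export
simulateGwasPair <- function(config, blockSize = 5000L) {
  stopifnot(config$model == "birthweight")
  nV <- config$nVariants
  nF <- config$nFamilies
  nBlocks <- ceiling(nV / blockSize)
  seeds <- .childSeeds(config$seed, 3L + nBlocks)
  blockSeeds <- seeds[seq_len(nBlocks)]
  starts <- (seq_len(nBlocks) - 1L) * blockSize + 1L
  ends <- pmin(starts + blockSize - 1L, nV)

  ## pass 1: accumulate genetic phenotype contributions (identically zero,
  ## and skipped, when every generating effect is zero)
  g1 <- numeric(nF); g2 <- numeric(nF)
  if (any(config$trueEffects != 0)) {
    for (b in seq_len(nBlocks)) {
      idx <- starts[b]:ends[b]
      G <- .genotypeBlock(blockSeeds[b], nF, config$alleleFreqs[idx],
                          "birthweight")
      g1 <- g1 + drop(G$self %*% config$trueEffects[idx, 1] +
                      G$mother %*% config$trueEffects[idx, 2])
      g2 <- g2 + drop(G$child %*% config$trueEffects[idx, 1] +
                      G$self %*% config$trueEffects[idx, 2])
    }
  }
  gvar <- .geneticVariance(config)
  sdRes <- config$residualSd
  if (is.null(sdRes)) {
    if (any(gvar >= 1)) stop("genetic variance >= 1; set residualSd explicitly")
    sdRes <- sqrt(1 - gvar)
  }
  sdRes <- rep_len(sdRes, 2L)
  set.seed(seeds[nBlocks + 1L])
  u1 <- rnorm(nF)
  u2 <- config$residualCorr * u1 + sqrt(1 - config$residualCorr^2) * rnorm(nF)
  y1 <- g1 + sdRes[1] * u1
  y2 <- g2 + sdRes[2] * u2
  masks <- makeOverlapDesign(nF, config$overlapFraction, seeds[nBlocks + 2L])
  both <- masks$own & masks$offspring
  rPhenoOverlap <- if (sum(both) > 2) cor(y1[both], y2[both]) else NA_real_

  ## pass 2: regenerate each block and run the two GWAS
  nOwn <- sum(masks$own); nOff <- sum(masks$offspring)
  y1s <- (y1[masks$own] - mean(y1[masks$own])) / sd(y1[masks$own])
  y2s <- (y2[masks$offspring] - mean(y2[masks$offspring])) / sd(y2[masks$offspring])
  slopeSe <- function(G, ys) {
    gbar <- colMeans(G)
    gc_ <- sweep(G, 2L, gbar)
    sxx <- colSums(gc_^2)
    beta <- drop(crossprod(gc_, ys)) / sxx
    rss <- pmax(sum(ys^2) - beta^2 * sxx, 0)
    list(beta = beta, se = sqrt(rss / ((length(ys) - 2L) * sxx)),
         eaf = gbar / 2)
  }
  res <- vector("list", nBlocks)
  for (b in seq_len(nBlocks)) {
    idx <- starts[b]:ends[b]
    G <- .genotypeBlock(blockSeeds[b], nF, config$alleleFreqs[idx],
                        "birthweight")
    own <- slopeSe(G$self[masks$own, , drop = FALSE], y1s)
    off <- slopeSe(G$self[masks$offspring, , drop = FALSE], y2s)
    res[[b]] <- list(own = own, off = off)
  }
  pull <- function(side, fld) unlist(lapply(res, function(r) r[[side]][[fld]]))
  meta <- .variantMeta(nV)
  mk <- function(side, n, lab, eafSide) {
    v <- cbind(meta, data.frame(
      eaf = pmin(pmax(pull(eafSide, "eaf"), 1e-6), 1 - 1e-6),
      beta = pull(side, "beta"), se = pull(side, "se"), n = n))
    rownames(v) <- NULL
    new("SumstatsTable", traitLabel = lab, variants = v,
        phenotypeVariance = 1)
  }
  tabs <- list(own = mk("own", nOwn, "own", "own"),
               offspring = mk("off", nOff, "offspring", "own"))
  pair <- new("HarmonizedSet", tables = tabs,
              droppedLog = data.frame(variant_id = character(),
                                      reason = character(),
                                      stringsAsFactors = FALSE))
  list(pair = pair,
       truth = data.frame(variant_id = meta$variant_id,
                          offspring = config$trueEffects[, 1],
                          maternal = config$trueEffects[, 2]),
       masks = masks, nOverlap = sum(both), rPhenoOverlap = rPhenoOverlap)
}

#' Synthetic LD-score panel
#'
#' LD scores drawn as 1 + Gamma(shape, scale), mimicking the long-tailed
#' genome-wide LD score distribution; the default shape/scale give a mean
#' near 90. \code{mSnps} is the notional genome-wide variant count the
#' scores refer to, which need not equal the panel size.
#'
#' @param nVariants panel size.
#' @param mSnps genome-wide M (default 1e6).
#' @param seed RNG seed.
#' @param shape,scale Gamma parameters of the LD score spread.
#' @return an \linkS4class{LDScorePanel} whose variant IDs match
#'   \code{.variantMeta} ordering (snp000001, ...).
#' @export
syntheticLdPanel <- function(nVariants, mSnps = 1e6, seed = 1L,
                             shape = 1.5, scale = 60) {
  set.seed(seed)
  sc <- data.frame(variant_id = sprintf("snp%06d", seq_len(nVariants)),
                   ld_score = 1 + rgamma(nVariants, shape = shape,
                                         scale = scale),
                   stringsAsFactors = FALSE)
  new("LDScorePanel", scores = sc, mSnps = mSnps)
}

#' Paired z-scores following the bivariate LD score regression expectation
#'
#' For variant j with LD score l_j, (z1j, z2j) are drawn bivariate normal
#' with Var(z_ij) = 1 + n_i h2_i l_j / M and Cov(z1j, z2j) =
#' sqrt(n1 n2) rg sqrt(h2_1 h2_2) l_j / M + nOverlap rPheno / sqrt(n1 n2),
#' i.e. a polygenic signal proportional to LD plus a constant
#' sample-overlap term equal to the expected cross-trait intercept.
#'
#' @param ld an \linkS4class{LDScorePanel}.
#' @param h2_1,h2_2 SNP heritabilities in [0, 1].
#' @param rg genetic correlation, |rg| <= 1.
#' @param n1,n2 GWAS sample sizes.
#' @param nOverlap individuals in both GWAS.
#' @param rPheno phenotypic correlation among overlapping individuals.
#' @param seed RNG seed.
#' @return data.frame with variant_id, z1, z2 in panel order.
#' @export
simulateLdscZscores <- function(ld, h2_1, h2_2, rg, n1, n2, nOverlap = 0,
                                rPheno = 0, seed = 1L) {
  if (h2_1 < 0 || h2_1 > 1 || h2_2 < 0 || h2_2 > 1)
    stop("heritabilities must lie in [0, 1]")
  if (abs(rg) > 1) stop("|rg| must be <= 1")
  sc <- ldScores(ld)
  ell <- sc$ld_score
  M <- mSnps(ld)
  v1 <- 1 + n1 * h2_1 * ell / M
  v2 <- 1 + n2 * h2_2 * ell / M
  cv <- sqrt(n1 * n2) * rg * sqrt(h2_1 * h2_2) * ell / M +
        interceptFromOverlap(nOverlap, n1, n2, rPheno)
  if (any(v1 * v2 - cv^2 <= 0))
    stop("per-variant z covariance is not positive definite")
  set.seed(seed)
  u1 <- rnorm(length(ell)); u2 <- rnorm(length(ell))
  z1 <- sqrt(v1) * u1
  z2 <- (cv / sqrt(v1)) * u1 + sqrt(v2 - cv^2 / v1) * u2
  data.frame(variant_id = sc$variant_id, z1 = z1, z2 = z2,
             stringsAsFactors = FALSE)
}
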