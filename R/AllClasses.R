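#' @import methods
#' @importFrom stats pnorm pchisq qnorm rbinom rnorm rgamma cor var sd
#'   median optim optimHess setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

# canonical per-variant columns carried by every summary table
.SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                    "other_allele", "eaf", "beta", "se", "n")

#' SumstatsTable: per-variant GWAS summary records for one trait
#'
#' Holds the marginal (unconditional) per-allele effect estimates from a
#' single GWAS: variant identifiers and coordinates, allele coding, effect
#' allele frequency, beta, standard error and sample size, with an optional
#' imputation INFO column. Betas are interpreted on the scale of a phenotype
#' with variance \code{phenotypeVariance} (1 for standardized traits).
#'
#' @slot traitLabel single character label for the trait/GWAS.
#' @slot variants data.frame with columns variant_id, chrom, pos,
#'   effect_allele, other_allele, eaf, beta, se, n and optionally info, p.
#' @slot phenotypeVariance positive scalar variance of the analysed phenotype.
#' @exportClass SumstatsTable
setClass("SumstatsTable",
  representation(traitLabel = "character",
                 variants = "data.frame",
                 phenotypeVariance = "numeric"),
  prototype(traitLabel = "trait", phenotypeVariance = 1))

setValidity("SumstatsTable", function(object) {
  v <- object@variants
  msg <- character()
  missing_cols <- setdiff(.SUMSTATS_COLS, names(v))
  if (length(missing_cols))
    msg <- c(msg, paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (length(msg) == 0L && nrow(v)) {
    if (anyDuplicated(v$variant_id))
      msg <- c(msg, "variant_id values must be unique")
    if (any(v$se <= 0, na.rm = TRUE))
      msg <- c(msg, "all standard errors must be positive")
    if (any(v$eaf <= 0 | v$eaf >= 1, na.rm = TRUE))
      msg <- c(msg, "eaf must lie strictly in (0,1)")
    if (any(v$effect_allele == v$other_allele, na.rm = TRUE))
      msg <- c(msg, "effect_allele must differ from other_allele")
  }
  if (length(object@phenotypeVariance) != 1L || object@phenotypeVariance <= 0)
    msg <- c(msg, "phenotypeVariance must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' HarmonizedSet: K aligned summary tables on a shared variant list
#'
#' All member tables share an identical variant list, order and effect-allele
#' orientation; variants removed during harmonization are recorded with
#' per-variant reason codes.
#'
#' @slot tables named list of \linkS4class{SumstatsTable}, identically ordered.
#' @slot droppedLog data.frame with columns variant_id, reason.
#' @exportClass HarmonizedSet
setClass("HarmonizedSet",
  representation(tables = "list", droppedLog = "data.frame"))

setValidity("HarmonizedSet", function(object) {
  msg <- character()
  if (length(object@tables) < 2L)
    msg <- c(msg, "a HarmonizedSet needs at least two tables")
  ids <- lapply(object@tables, function(t) t@variants$variant_id)
  if (length(unique(vapply(ids, length, 1L))) > 1L)
    msg <- c(msg, "tables differ in length")
  else if (length(ids) > 1L && !all(vapply(ids[-1], identical, TRUE, ids[[1]])))
    msg <- c(msg, "tables differ in variant order")
  ea <- lapply(object@tables, function(t) t@variants$effect_allele)
  if (length(ea) > 1L && !all(vapply(ea[-1], identical, TRUE, ea[[1]])))
    msg <- c(msg, "effect alleles are not aligned across tables")
  if (length(msg)) msg else TRUE
})

#' LDScorePanel: per-variant LD scores and regression weights
#'
#' @slot scores data.frame with columns variant_id, ld_score and optionally
#'   weight. LD scores are at least 1 (a variant is in LD with itself).
#' @slot mSnps genome-wide number of variants the LD scores were computed
#'   over (the M in the LD score regression denominator).
#' @exportClass LDScorePanel
setClass("LDScorePanel",
  representation(scores = "data.frame", mSnps = "numeric"))

setValidity("LDScorePanel", function(object) {
  msg <- character()
  if (!all(c("variant_id", "ld_score") %in% names(object@scores)))
    msg <- c(msg, "scores needs variant_id and ld_score columns")
  else {
    if (any(object@scores$ld_score < 1, na.rm = TRUE))
      msg <- c(msg, "ld_score must be >= 1")
    if ("weight" %in% names(object@scores) &&
        any(object@scores$weight <= 0, na.rm = TRUE))
      msg <- c(msg, "weights must be positive")
  }
  if (length(object@mSnps) != 1L || object@mSnps < nrow(object@scores))
    msg <- c(msg, "mSnps must be a scalar >= number of panel variants")
  if (length(msg)) msg else TRUE
})

#' PathModelSpec: biometrical model mapping conditional to unconditional effects
#'
#' The coefficient matrix A encodes, for each unconditional GWAS (rows), the
#' relatedness weight with which each conditional effect (columns) is tagged:
#' E[beta_unconditional] = A %*% beta_conditional. Diagonals are 1 (each GWAS
#' tags its own conditional effect fully); off-diagonals are identity-by-
#' descent relatedness coefficients, 0.5 for parent-offspring transmission.
#'
#' @slot labels character vector naming the K conditional effects.
#' @slot A K x K numeric coefficient matrix.
#' @slot relatedness fixed path value between observed and latent genotypes.
#' @slot freeResiduals names of free residual variance/covariance parameters.
#' @exportClass PathModelSpec
setClass("PathModelSpec",
  representation(labels = "character", A = "matrix",
                 relatedness = "numeric", freeResiduals = "character"),
  prototype(relatedness = 0.5, freeResiduals = character()))

setValidity("PathModelSpec", function(object) {
  msg <- character()
  K <- length(object@labels)
  if (!is.numeric(object@A) || nrow(object@A) != K || ncol(object@A) != K)
    msg <- c(msg, "A must be a K x K numeric matrix matching labels")
  else {
    if (any(abs(diag(object@A) - 1) > 1e-12))
      msg <- c(msg, "diagonal of A must be 1")
    off <- object@A[row(object@A) != col(object@A)]
    if (any(off < 0 | off > 1))
      msg <- c(msg, "off-diagonal relatedness weights must lie in [0,1]")
    if (abs(det(object@A)) < 1e-12)
      msg <- c(msg, "A must be invertible")
  }
  if (length(msg)) msg else TRUE
})

#' InterceptEstimate: LD score regression intercept and slope
#'
#' @slot intercept,interceptSE regression intercept and its block-jackknife SE.
#' @slot slope,slopeSE regression slope (heritability or genetic covariance
#'   scale, depending on the regressor) and its jackknife SE.
#' @slot nBlocks number of jackknife blocks used.
#' @slot nSnpsUsed number of variants entering the regression.
#' @exportClass InterceptEstimate
setClass("InterceptEstimate",
  representation(intercept = "numeric", interceptSE = "numeric",
                 slope = "numeric", slopeSE = "numeric",
                 nBlocks = "integer", nSnpsUsed = "integer"))

setValidity("InterceptEstimate", function(object) {
  msg <- character()
  if (object@nBlocks < 2L) msg <- c(msg, "nBlocks must be >= 2")
  if (object@nSnpsUsed <= object@nBlocks)
    msg <- c(msg, "need more variants than blocks")
  if (object@interceptSE < 0 || object@slopeSE < 0)
    msg <- c(msg, "jackknife SEs must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' OverlapEstimate: sample overlap implied by a cross-trait intercept
#'
#' @slot nOverlap overlap estimate after clamping to [0, min(n1, n2)].
#' @slot nOverlapRaw unclamped value intercept * sqrt(n1 n2) / rPheno.
#' @slot interceptUsed the cross-trait intercept that was converted.
#' @slot n1,n2 the two GWAS sample sizes.
#' @slot rPheno phenotypic correlation between the paired phenotypes.
#' @exportClass OverlapEstimate
setClass("OverlapEstimate",
  representation(nOverlap = "numeric", nOverlapRaw = "numeric",
                 interceptUsed = "numeric", n1 = "numeric", n2 = "numeric",
                 rPheno = "numeric"))

setValidity("OverlapEstimate", function(object) {
  msg <- character()
  if (object@nOverlap < 0 || object@nOverlap > min(object@n1, object@n2))
    msg <- c(msg, "nOverlap must lie in [0, min(n1, n2)] after clamping")
  if (abs(object@rPheno) > 1) msg <- c(msg, "rPheno must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' GeneticCorrelation: LDSC genetic correlation between two traits
#'
#' rg is reported even when it falls outside [-1, 1]; \code{outOfRange}
#' flags that case, and \code{status} records estimation problems such as a
#' nonpositive heritability.
#'
#' @slot rg,rgSE genetic correlation and its block-jackknife SE.
#' @slot h2_1,h2_2 univariate SNP-heritability slope estimates.
#' @slot gcovIntercept cross-trait regression intercept.
#' @slot outOfRange logical, TRUE when |rg| > 1.
#' @slot status "ok" or a short description of a degenerate estimate.
#' @exportClass GeneticCorrelation
setClass("GeneticCorrelation",
  representation(rg = "numeric", rgSE = "numeric", h2_1 = "numeric",
                 h2_2 = "numeric", gcovIntercept = "numeric",
                 outOfRange = "logical", status = "character"),
  prototype(outOfRange = FALSE, status = "ok"))

#' ConditionalEstimate: conditional effect vector at a single variant
#'
#' @slot variantId variant identifier ("" when not tied to a variant).
#' @slot labels names of the K conditional effects.
#' @slot betaAdj K-vector of conditional effect estimates.
#' @slot covAdj K x K sampling covariance of the estimates.
#' @slot waldP K-vector of two-sided Wald p-values.
#' @slot logP K-vector of natural-log p-values (underflow-safe).
#' @slot methodTag short string naming the estimator that produced it.
#' @exportClass ConditionalEstimate
setClass("ConditionalEstimate",
  representation(variantId = "character", labels = "character",
                 betaAdj = "numeric", covAdj = "matrix", waldP = "numeric",
                 logP = "numeric", methodTag = "character"),
  prototype(variantId = "", methodTag = ""))

setValidity("ConditionalEstimate", function(object) {
  msg <- character()
  K <- length(object@labels)
  if (length(object@betaAdj) != K || length(object@waldP) != K)
    msg <- c(msg, "betaAdj and waldP must match labels in length")
  if (nrow(object@covAdj) != K || ncol(object@covAdj) != K)
    msg <- c(msg, "covAdj must be K x K")
  else {
    if (max(abs(object@covAdj - t(object@covAdj))) > 1e-8 * (1 + max(abs(object@covAdj))))
      msg <- c(msg, "covAdj must be symmetric")
    if (any(diag(object@covAdj) <= 0))
      msg <- c(msg, "covAdj diagonal must be positive")
  }
  # exact zeros are double underflow (|z| > ~38.6); logP keeps the value
  if (length(object@waldP) && any(object@waldP < 0 | object@waldP > 1))
    msg <- c(msg, "waldP must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' GroupCovarianceSet: observed covariance matrices for the SEM groups
#'
#' One matrix per observation group: individuals with their own phenotype
#' only, with their offspring's phenotype only, and with both. Built from a
#' single variant's summary statistics under the assumption that allele
#' frequency, beta and phenotype variance are shared across groups.
#'
#' @slot groups named list (own, offspring, both) of lists with elements
#'   S (covariance matrix), n (group sample size), vars (variable labels).
#' @slot q genotype variance 2p(1-p).
#' @slot rPheno phenotypic correlation used for the both-phenotypes group.
#' @exportClass GroupCovarianceSet
setClass("GroupCovarianceSet",
  representation(groups = "list", q = "numeric", rPheno = "numeric"))

setValidity("GroupCovarianceSet", function(object) {
  msg <- character()
  if (length(object@q) != 1L || object@q <= 0 || object@q > 0.5)
    msg <- c(msg, "q must lie in (0, 0.5]")
  for (g in object@groups) {
    if (g$n < 0) msg <- c(msg, "group sample sizes must be nonnegative")
    if (max(abs(g$S - t(g$S))) > 1e-10) msg <- c(msg, "group S must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' SemFit: maximum-likelihood fit of the summary-statistics SEM
#'
#' @slot theta named estimates (o, m, s1sq, s2sq, c).
#' @slot covTheta covariance matrix of the estimates (observed information).
#' @slot minimum minimized multi-group ML discrepancy F.
#' @slot converged logical convergence status.
#' @slot waldP two-sided Wald p-values for o and m.
#' @slot seOk logical, FALSE when the Hessian was not positive definite.
#' @exportClass SemFit
setClass("SemFit",
  representation(theta = "numeric", covTheta = "matrix", minimum = "numeric",
                 converged = "logical", waldP = "numeric", seOk = "logical"))

#' FamilyDataset: simulated family genotypes, phenotypes and GWAS masks
#'
#' @slot genotypes named list of nFamilies x nVariants dosage matrices.
#' @slot phenotypes named list of length-nFamilies phenotype vectors.
#' @slot alleleFreqs per-variant allele frequencies.
#' @slot trueEffects nVariants x K matrix of generating conditional effects.
#' @slot masks named list of logical subsample membership vectors.
#' @slot model "birthweight" or "fertility".
#' @exportClass FamilyDataset
setClass("FamilyDataset",
  representation(genotypes = "list", phenotypes = "list",
                 alleleFreqs = "numeric", trueEffects = "matrix",
                 masks = "list", model = "character"))

#' LocusSet: sentinel variants defining significant loci
#'
#' @slot sentinels data.frame with columns variant_id, chrom, pos, p (and
#'   novel, once classified).
#' @slot windowBp half-width of the locus window in base pairs.
#' @exportClass LocusSet
setClass("LocusSet",
  representation(sentinels = "data.frame", windowBp = "numeric"))

setValidity("LocusSet", function(object) {
  s <- object@sentinels
  if (nrow(s) > 1L) {
    for (ch in unique(s$chrom)) {
      pos <- sort(s$pos[s$chrom == ch])
      if (length(pos) > 1L && any(diff(pos) <= object@windowBp))
        return("sentinels on the same chromosome must be > windowBp apart")
    }
  }
  TRUE
})

## --- show methods --------------------------------------------------------

setMethod("show", "SumstatsTable", function(object) {
  cat("SumstatsTable '", object@traitLabel, "': ",
      nrow(object@variants), " variants, phenotype variance ",
      format(object@phenotypeVariance), "\n", sep = "")
  if (nrow(object@variants)) print(head(object@variants, 3L))
})

setMethod("show", "HarmonizedSet", function(object) {
  cat("HarmonizedSet: ", length(object@tables), " tables (",
      paste(names(object@tables), collapse = ", "), "), ",
      nrow(object@tables[[1]]@variants), " shared variants, ",
      nrow(object@droppedLog), " dropped\n", sep = "")
})

setMethod("show", "PathModelSpec", function(object) {
  cat("PathModelSpec <", paste(object@labels, collapse = ", "), ">\n", sep = "")
  print(object@A)
})

setMethod("show", "InterceptEstimate", function(object) {
  cat(sprintf("LDSC fit: intercept %.4f (%.4f), slope %.4g (%.4g), %d SNPs / %d blocks\n",
              object@intercept, object@interceptSE, object@slope,
              object@slopeSE, object@nSnpsUsed, object@nBlocks))
})

setMethod("show", "OverlapEstimate", function(object) {
  cat(sprintf("Estimated sample overlap: %.1f individuals (intercept %.4f, n1=%d, n2=%d, r=%.3f)\n",
              object@nOverlap, object@interceptUsed, as.integer(object@n1),
              as.integer(object@n2), object@rPheno))
})

setMethod("show", "GeneticCorrelation", function(object) {
  cat(sprintf("rg = %.3f (SE %.3f)%s; h2: %.3f, %.3f; gcov intercept %.4f [%s]\n",
              object@rg, object@rgSE,
              if (object@outOfRange) " [outside [-1,1]]" else "",
              object@h2_1, object@h2_2, object@gcovIntercept, object@status))
})

setMethod("show", "ConditionalEstimate", function(object) {
  cat("ConditionalEstimate", if (nzchar(object@variantId)) object@variantId else "",
      if (nzchar(object@methodTag)) paste0("[", object@methodTag, "]"), "\n")
  print(data.frame(effect = object@labels, beta = object@betaAdj,
                   se = sqrt(diag(object@covAdj)), p = object@waldP))
})

setMethod("show", "SemFit", function(object) {
  cat("SemFit", if (object@converged) "(converged)" else "(NOT converged)",
      "F =", format(object@minimum), "\n")
  print(object@theta)
})

setMethod("show", "FamilyDataset", function(object) {
  cat("FamilyDataset [", object@model, "]: ",
      nrow(object@genotypes[[1]]), " families x ",
      ncol(object@genotypes[[1]]), " variants\n", sep = "")
})

setMethod("show", "LocusSet", function(object) {
  cat("LocusSet:", nrow(object@sentinels), "loci (window",
      object@windowBp, "bp)\n")
  if (nrow(object@sentinels)) print(head(object@sentinels, 5L))
})
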