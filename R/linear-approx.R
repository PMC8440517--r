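## Closed-form linear adjustment of paired own/offspring GWAS estimates:
## exact inverse of the 2x2 relatedness mixing, with error propagation and
## Wald p-values. Assumes the two GWAS share no samples.

## underflow-safe two-sided normal p-value, optionally on the log scale
.waldP <- function(z) 2 * pnorm(-abs(z))
.waldLogP <- function(z) log(2) + pnorm(-abs(z), log.p = TRUE)

#' Conditional maternal/offspring effects for a single variant
#'
#' Exact linear transformation of the unadjusted estimates:
#' beta_o_adj = -(2/3) beta_m_unadj + (4/3) beta_o_unadj and
#' beta_m_adj = (4/3) beta_m_unadj - (2/3) beta_o_unadj, i.e. the inverse
#' of the relatedness matrix [[1, 0.5], [0.5, 1]] applied to
#' (beta_o_unadj, beta_m_unadj). The covariance of the adjusted estimates
#' is A^{-1} diag(se_o^2, se_m^2) A^{-T}, giving
#' SE(beta_o_adj) = sqrt(4/9 se_m^2 + 16/9 se_o^2) and
#' SE(beta_m_adj) = sqrt(16/9 se_m^2 + 4/9 se_o^2). Two-sided Wald
#' p-values are computed from z = beta/SE against the standard normal,
#' with natural-log p-values retained to avoid underflow.
#'
#' The transformation assumes the two unadjusted GWAS are independent (no
#' sample overlap); no covariance correction is applied when they are not.
#'
#' @param betaMUnadj unadjusted maternal effect (own genotype vs offspring
#'   phenotype GWAS).
#' @param betaOUnadj unadjusted offspring effect (own genotype vs own
#'   phenotype GWAS).
#' @param seM,seO their standard errors (> 0).
#' @param variantId optional variant identifier.
#' @return a \linkS4class{ConditionalEstimate} with labels
#'   (offspring, maternal).
#' @export
adjustPair <- function(betaMUnadj, betaOUnadj, seM, seO, variantId = "") {
  if (!all(is.finite(c(betaMUnadj, betaOUnadj, seM, seO))))
    stop("inputs must be finite")
  if (seM <= 0 || seO <= 0) stop("standard errors must be positive")
  model <- birthweightModel()
  Ainv <- solve(coefMatrix(model))
  ## rows of A are (own_gwas, offspring_gwas) -> betas ordered (o, m)
  beta <- drop(Ainv %*% c(betaOUnadj, betaMUnadj))
  V <- Ainv %*% diag(c(seO^2, seM^2)) %*% t(Ainv)
  z <- beta / sqrt(diag(V))
  dimnames(V) <- list(effectLabels(model), effectLabels(model))
  new("ConditionalEstimate", variantId = as.character(variantId),
      labels = effectLabels(model),
      betaAdj = setNames(beta, effectLabels(model)), covAdj = V,
      waldP = setNames(.waldP(z), effectLabels(model)),
      logP = setNames(.waldLogP(z), effectLabels(model)),
      methodTag = "linear_approx")
}

#' Linear adjustment over a harmonized own/offspring GWAS pair
#'
#' Applies \code{\link{adjustPair}} to every harmonized variant. The first
#' table (or the one named by \code{own}) must be the GWAS of own
#' phenotype on own genotype; the second (\code{offspring}) the GWAS of
#' offspring phenotype on own genotype. Output is deterministic given the
#' input order.
#'
#' @param pair a \linkS4class{HarmonizedSet} of exactly two tables.
#' @param own,offspring names of the two member tables; default the first
#'   and second table.
#' @return a data.frame with one row per variant: variant_id, chrom, pos,
#'   effect_allele, other_allele, eaf, then beta/se/p (and log_p) for the
#'   offspring and maternal conditional effects, the estimate covariance
#'   \code{cov_offspring_maternal}, and the two GWAS sample sizes.
#' @export
adjustTable <- function(pair, own = NULL, offspring = NULL) {
  tabs <- harmonizedTables(pair)
  if (length(tabs) != 2L)
    stop("the linear adjustment needs exactly two harmonized tables")
  if (is.null(own)) own <- names(tabs)[1]
  if (is.null(offspring)) offspring <- names(tabs)[2]
  if (!all(c(own, offspring) %in% names(tabs)))
    stop("own/offspring labels not found among the harmonized tables")
  vo <- variantData(tabs[[own]])
  vm <- variantData(tabs[[offspring]])
  Ainv <- solve(coefMatrix(birthweightModel()))
  bu <- cbind(vo$beta, vm$beta)          # (o_unadj, m_unadj)
  beta <- bu %*% t(Ainv)
  se2 <- cbind(vo$se^2, vm$se^2)
  varAdj <- se2 %*% t(Ainv^2)            # diag of Ainv V Ainv'
  covOM <- se2 %*% (Ainv[1, ] * Ainv[2, ])
  z <- beta / sqrt(varAdj)
  data.frame(variant_id = vo$variant_id, chrom = vo$chrom, pos = vo$pos,
             effect_allele = vo$effect_allele, other_allele = vo$other_allele,
             eaf = vo$eaf,
             beta_offspring = beta[, 1], se_offspring = sqrt(varAdj[, 1]),
             p_offspring = .waldP(z[, 1]), log_p_offspring = .waldLogP(z[, 1]),
             beta_maternal = beta[, 2], se_maternal = sqrt(varAdj[, 2]),
             p_maternal = .waldP(z[, 2]), log_p_maternal = .waldLogP(z[, 2]),
             cov_offspring_maternal = drop(covOM),
             n_own = vo$n, n_offspring = vm$n,
             stringsAsFactors = FALSE)
}
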