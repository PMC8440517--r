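## Overlap-aware conditional effects in the style of Genomic SEM: a
## per-variant sampling covariance whose off-diagonals carry cross-trait
## LD score regression intercepts, and the closed-form (equivalently,
## diagonally weighted least squares) solution of a just-identified
## biometrical path model.

#' Cross-trait intercept matrix over a harmonized set
#'
#' Runs bivariate LD score regression on every pair of member tables and
#' assembles the K x K matrix of cross-trait intercepts (diagonal 1),
#' clamped into [-1, 1]. Entry (i, j) estimates the correlation between
#' the sampling errors of the two GWAS betas at a variant, which is
#' Ns_ij * rp_ij / sqrt(n_i n_j) under sample overlap.
#'
#' @param tables a \linkS4class{HarmonizedSet} (K >= 2).
#' @param ld an \linkS4class{LDScorePanel} covering the harmonized
#'   variants.
#' @param nBlocks jackknife blocks passed through to
#'   \code{\link{crossTraitIntercept}}.
#' @return K x K numeric matrix with unit diagonal.
#' @export
estimateInterceptMatrix <- function(tables, ld, nBlocks = NULL) {
  z <- zMatrix(tables)
  ns <- sampleSizes(tables)
  sc <- .alignPanel(tables, ld)
  K <- ncol(z)
  cmat <- diag(1, K)
  dimnames(cmat) <- list(names(harmonizedTables(tables)),
                         names(harmonizedTables(tables)))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    est <- crossTraitIntercept(z[, i], z[, j], sc$ld_score, ns[i], ns[j],
                               mSnps = mSnps(ld), nBlocks = nBlocks)
    cmat[i, j] <- cmat[j, i] <- min(max(intercept(est), -1), 1)
  }
  cmat
}

## per-variant sampling covariance V with V_ii = se_i^2 and
## V_ij = c_ij se_i se_j; c clamped to +-0.99 so V stays positive
## definite for K <= 3, with an eigenvalue-clip repair as a last resort
.samplingCovariance <- function(se, cmat) {
  cc <- pmin(pmax(cmat, -0.99), 0.99)
  diag(cc) <- 1
  V <- cc * tcrossprod(se)
  ev <- eigen(V, symmetric = TRUE)
  if (any(ev$values <= 0)) {
    warning("sampling covariance not positive definite; nearest-PD repair applied")
    vals <- pmax(ev$values, 1e-12 * max(ev$values))
    V <- ev$vectors %*% (vals * t(ev$vectors))
    V <- (V + t(V)) / 2
  }
  V
}

#' Conditional effects at one variant with overlap-aware covariance
#'
#' For a just-identified path model the diagonally weighted least squares
#' solution is the exact closed form theta = A^{-1} beta, with sampling
#' covariance A^{-1} V A^{-T} where V_ii = se_i^2 and V_ij = c_ij se_i
#' se_j carries the cross-trait intercepts. Two-sided Wald p-values from
#' Z tests on the estimates. With c = identity this reduces exactly to
#' the linear adjustment covariance.
#'
#' @param betaVec K-vector of unconditional betas, ordered as the rows of
#'   the model's coefficient matrix.
#' @param seVec K-vector of their standard errors (> 0).
#' @param cmat K x K cross-trait intercept matrix (diagonal 1), e.g. from
#'   \code{\link{estimateInterceptMatrix}} or
#'   \code{\link{interceptFromOverlap}}; defaults to the identity
#'   (no overlap).
#' @param model a \linkS4class{PathModelSpec}.
#' @param variantId optional identifier.
#' @return a \linkS4class{ConditionalEstimate}.
#' @export
conditionalSolve <- function(betaVec, seVec, cmat = NULL,
                             model = birthweightModel(), variantId = "") {
  K <- length(effectLabels(model))
  if (length(betaVec) != K || length(seVec) != K)
    stop("betaVec and seVec must match the model order K = ", K)
  if (any(seVec <= 0)) stop("standard errors must be positive")
  if (is.null(cmat)) cmat <- diag(1, K)
  Ainv <- solve(coefMatrix(model))
  V <- .samplingCovariance(seVec, cmat)
  beta <- drop(Ainv %*% betaVec)
  cov <- Ainv %*% V %*% t(Ainv)
  cov <- (cov + t(cov)) / 2
  z <- beta / sqrt(diag(cov))
  dimnames(cov) <- list(effectLabels(model), effectLabels(model))
  new("ConditionalEstimate", variantId = as.character(variantId),
      labels = effectLabels(model),
      betaAdj = setNames(beta, effectLabels(model)), covAdj = cov,
      waldP = setNames(.waldP(z), effectLabels(model)),
      logP = setNames(.waldLogP(z), effectLabels(model)),
      methodTag = "gsem")
}

#' Overlap-aware conditional GWAS over a harmonized set
#'
#' Estimates the cross-trait intercept matrix once genome-wide (or takes
#' one supplied, e.g. built from a known overlap via
#' \code{\link{interceptFromOverlap}}), then applies
#' \code{\link{conditionalSolve}} to every variant. Deterministic and
#' invariant to how the variant table is partitioned.
#'
#' @param tables a \linkS4class{HarmonizedSet} with K member tables
#'   matching the model's unconditional GWAS (same order as the rows of
#'   the coefficient matrix).
#' @param model a just-identified \linkS4class{PathModelSpec}.
#' @param ld \linkS4class{LDScorePanel}, required when
#'   \code{interceptMatrix} is not supplied.
#' @param interceptMatrix optional K x K cross-trait intercept matrix;
#'   bypasses the LDSC estimation stage.
#' @return a data.frame with one row per variant: identifiers, then for
#'   each conditional label beta_<label>, se_<label>, p_<label>, and the
#'   pairwise estimate covariances cov_<l1>_<l2>.
#' @export
conditionalGwas <- function(tables, model = birthweightModel(), ld = NULL,
                            interceptMatrix = NULL) {
  K <- length(effectLabels(model))
  if (length(harmonizedTables(tables)) != K)
    stop("the model expects ", K, " unconditional GWAS")
  if (is.null(interceptMatrix)) {
    if (is.null(ld)) stop("supply an LD panel or an intercept matrix")
    interceptMatrix <- estimateInterceptMatrix(tables, ld)
  }
  cc <- pmin(pmax(interceptMatrix, -0.99), 0.99)
  diag(cc) <- 1
  B <- betaMatrix(tables)
  SE <- seMatrix(tables)
  Ainv <- solve(coefMatrix(model))
  beta <- B %*% t(Ainv)
  labels <- effectLabels(model)
  ## vectorized A^{-1} V A^{-T}: entry (a,b) = sum_{i,j} Ainv[a,i] c_ij
  ## Ainv[b,j] se_i se_j
  covCols <- list()
  varAdj <- matrix(0, nrow(B), K)
  for (a in seq_len(K)) for (b in a:K) {
    w <- outer(Ainv[a, ], Ainv[b, ]) * cc
    val <- rowSums((SE %*% w) * SE)
    if (a == b) varAdj[, a] <- val
    else covCols[[paste0("cov_", labels[a], "_", labels[b])]] <- val
  }
  z <- beta / sqrt(varAdj)
  v1 <- variantData(harmonizedTables(tables)[[1]])
  out <- data.frame(variant_id = v1$variant_id, chrom = v1$chrom,
                    pos = v1$pos, eaf = v1$eaf, stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    out[[paste0("beta_", labels[k])]] <- beta[, k]
    out[[paste0("se_", labels[k])]] <- sqrt(varAdj[, k])
    out[[paste0("p_", labels[k])]] <- .waldP(z[, k])
    out[[paste0("log_p_", labels[k])]] <- .waldLogP(z[, k])
  }
  for (nm in names(covCols)) out[[nm]] <- covCols[[nm]]
  attr(out, "interceptMatrix") <- cc
  out
}
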