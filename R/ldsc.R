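## LD score regression: univariate and cross-trait intercepts with block
## jackknife standard errors, intercept <-> sample-overlap conversion, and
## genetic correlation.

## number of position-contiguous jackknife blocks: 200 by default, reduced
## to floor(n/50) for desk-scale panels
.nJackBlocks <- function(nSnps, nBlocks = NULL) {
  if (is.null(nBlocks)) nBlocks <- min(200L, max(2L, nSnps %/% 50L))
  nBlocks <- as.integer(nBlocks)
  if (nSnps <= nBlocks) stop("fewer variants (", nSnps, ") than jackknife blocks (",
                             nBlocks, ")")
  nBlocks
}

## weighted regression of y on x with delete-one-block jackknife.
## Returns full-sample (intercept, slope) and the nBlocks x 2 matrix of
## leave-one-block-out coefficients, computed from per-block sufficient
## statistics so the jackknife is O(n + nBlocks).
.ldscWls <- function(y, x, w, nBlocks) {
  n <- length(y)
  blocks <- cut(seq_len(n), nBlocks, labels = FALSE)
  X1 <- w; X2 <- w * x  # columns of sqrt-weighted design folded into sums
  ## sufficient statistics per block for X'WX and X'Wy with X = [1, x]
  s11 <- rowsum(w, blocks);      s12 <- rowsum(w * x, blocks)
  s22 <- rowsum(w * x * x, blocks)
  t1 <- rowsum(w * y, blocks);   t2 <- rowsum(w * x * y, blocks)
  S11 <- sum(s11); S12 <- sum(s12); S22 <- sum(s22)
  T1 <- sum(t1); T2 <- sum(t2)
  solve2 <- function(a11, a12, a22, b1, b2) {
    d <- a11 * a22 - a12 * a12
    c((a22 * b1 - a12 * b2) / d, (a11 * b2 - a12 * b1) / d)
  }
  full <- solve2(S11, S12, S22, T1, T2)
  loo <- matrix(0, nBlocks, 2L)
  for (b in seq_len(nBlocks))
    loo[b, ] <- solve2(S11 - s11[b], S12 - s12[b], S22 - s22[b],
                       T1 - t1[b], T2 - t2[b])
  list(coef = full, loo = loo, nBlocks = nBlocks)
}

.jackSE <- function(loo) {
  nb <- nrow(loo)
  m <- colMeans(loo)
  sqrt((nb - 1) / nb * colSums(sweep(loo, 2L, m)^2))
}

## two-step weights: heteroskedasticity weights 1/max(l,1) in the first
## pass, then multiplied by the inverse squared predicted mean of the
## regressand (variance of a z^2 / z1*z2 product under normality)
.ldscFit <- function(y, x, ell, nBlocks, varFun) {
  w0 <- 1 / pmax(ell, 1)
  fit0 <- .ldscWls(y, x, w0, nBlocks)
  vhat <- pmax(varFun(fit0$coef[1] + fit0$coef[2] * x), 1e-6)
  w <- w0 / vhat
  fit <- .ldscWls(y, x, w, nBlocks)
  list(coef = fit$coef, se = .jackSE(fit$loo), loo = fit$loo,
       nBlocks = fit$nBlocks)
}

#' Univariate LD score regression
#'
#' Weighted regression of squared z-scores on n*l/M. Under no confounding
#' the intercept is near 1 and the slope estimates the SNP heritability.
#' Standard errors come from a delete-one-block jackknife over
#' position-contiguous blocks (200 blocks by default, floor(nSnps/50) for
#' small panels). Weights are 1/max(l,1) in a first pass, refined by the
#' inverse squared predicted mean of z^2 in a second pass.
#'
#' @param z per-variant z-scores, aligned with the panel.
#' @param ld an \linkS4class{LDScorePanel} aligned to \code{z} (same
#'   variants, same order), or a numeric vector of LD scores.
#' @param n GWAS sample size.
#' @param mSnps genome-wide variant count M; taken from the panel when
#'   \code{ld} is an LDScorePanel.
#' @param nBlocks number of jackknife blocks (default as above).
#' @return an \linkS4class{InterceptEstimate}; the slope is on the
#'   heritability scale.
#' @export
univariateIntercept <- function(z, ld, n, mSnps = NULL, nBlocks = NULL) {
  ell <- if (is(ld, "LDScorePanel")) ldScores(ld)$ld_score else as.numeric(ld)
  if (is(ld, "LDScorePanel") && is.null(mSnps)) mSnps <- mSnps(ld)
  if (is.null(mSnps)) mSnps <- length(ell)
  if (length(z) != length(ell)) stop("z and LD scores must be aligned")
  if (length(z) < 200L) stop("need at least 200 variants for LD score regression")
  nb <- .nJackBlocks(length(z), nBlocks)
  x <- n * ell / mSnps
  fit <- .ldscFit(z^2, x, ell, nb, varFun = function(mu) 2 * mu^2)
  new("InterceptEstimate", intercept = fit$coef[1], interceptSE = fit$se[1],
      slope = fit$coef[2], slopeSE = fit$se[2], nBlocks = nb,
      nSnpsUsed = length(z))
}

#' Cross-trait (bivariate) LD score regression
#'
#' Weighted regression of z1*z2 on sqrt(n1*n2)*l/M. The intercept estimates
#' Ns*rp/sqrt(n1*n2), where Ns is the number of individuals in both GWAS
#' and rp the phenotypic correlation; the slope is on the genetic-covariance
#' scale. Jackknife SEs as in \code{\link{univariateIntercept}}.
#'
#' @inheritParams univariateIntercept
#' @param z1,z2 aligned per-variant z-scores of the two GWAS.
#' @param n1,n2 the two GWAS sample sizes.
#' @return an \linkS4class{InterceptEstimate}.
#' @export
crossTraitIntercept <- function(z1, z2, ld, n1, n2, mSnps = NULL, nBlocks = NULL) {
  ell <- if (is(ld, "LDScorePanel")) ldScores(ld)$ld_score else as.numeric(ld)
  if (is(ld, "LDScorePanel") && is.null(mSnps)) mSnps <- mSnps(ld)
  if (is.null(mSnps)) mSnps <- length(ell)
  if (length(z1) != length(ell) || length(z2) != length(ell))
    stop("z-scores and LD scores must be aligned")
  if (length(z1) < 200L) stop("need at least 200 variants for LD score regression")
  nb <- .nJackBlocks(length(z1), nBlocks)
  x <- sqrt(n1 * n2) * ell / mSnps
  ## product variance approximation: Var(z1 z2) ~ E[z1^2]E[z2^2] + E[z1 z2]^2;
  ## the per-trait means are folded into the second-pass weights via cheap
  ## univariate first passes
  u1 <- .ldscWls(z1^2, n1 * ell / mSnps, 1 / pmax(ell, 1), nb)$coef
  u2 <- .ldscWls(z2^2, n2 * ell / mSnps, 1 / pmax(ell, 1), nb)$coef
  m1 <- pmax(u1[1] + u1[2] * n1 * ell / mSnps, 0.1)
  m2 <- pmax(u2[1] + u2[2] * n2 * ell / mSnps, 0.1)
  fit <- .ldscFit(z1 * z2, x, ell, nb,
                  varFun = function(mu) mu^2 + m1 * m2)
  new("InterceptEstimate", intercept = fit$coef[1], interceptSE = fit$se[1],
      slope = fit$coef[2], slopeSE = fit$se[2], nBlocks = nb,
      nSnpsUsed = length(z1))
}

#' Convert a cross-trait intercept to a sample-overlap estimate
#'
#' The cross-trait LD score regression intercept equals Ns*rp/sqrt(n1*n2),
#' so the number of overlapping individuals is recovered as
#' intercept * sqrt(n1*n2) / rp. The raw value is retained; the reported
#' estimate is clamped to [0, min(n1, n2)]. Rounding is left to the caller.
#'
#' @param intercept cross-trait regression intercept.
#' @param n1,n2 the two GWAS sample sizes.
#' @param rPheno nonzero phenotypic correlation between the two phenotypes.
#' @return an \linkS4class{OverlapEstimate}.
#' @export
overlapFromIntercept <- function(intercept, n1, n2, rPheno) {
  if (rPheno == 0) stop("overlap is undefined for a zero phenotypic correlation")
  n1 <- as.numeric(n1); n2 <- as.numeric(n2)   # avoid integer overflow in n1*n2
  raw <- intercept * sqrt(n1 * n2) / rPheno
  new("OverlapEstimate", nOverlap = min(max(raw, 0), min(n1, n2)),
      nOverlapRaw = raw, interceptUsed = intercept,
      n1 = n1, n2 = n2, rPheno = rPheno)
}

#' Expected cross-trait intercept for a known sample overlap
#'
#' Exact inverse of \code{\link{overlapFromIntercept}}: returns
#' nOverlap * rPheno / sqrt(n1*n2). Used by the simulator and by the
#' overlap-aware sampling covariance when the overlap is known.
#'
#' @param nOverlap number of individuals in both GWAS (0 <= nOverlap <=
#'   min(n1, n2)).
#' @inheritParams overlapFromIntercept
#' @return the expected intercept (numeric scalar).
#' @export
interceptFromOverlap <- function(nOverlap, n1, n2, rPheno) {
  if (nOverlap < 0 || nOverlap > min(n1, n2))
    stop("nOverlap must lie in [0, min(n1, n2)]")
  nOverlap * rPheno / sqrt(as.numeric(n1) * as.numeric(n2))
}

#' LDSC genetic correlation between two traits
#'
#' rg = gcov / sqrt(h2_1 * h2_2), with the genetic covariance from the
#' cross-trait slope and the heritabilities from the univariate slopes.
#' The SE is a delete-one-block jackknife of the ratio, using the same
#' block partition for all three regressions. rg is reported even when it
#' falls outside [-1, 1] (flagged); a nonpositive heritability yields an
#' NA rg with a warning status.
#'
#' @inheritParams crossTraitIntercept
#' @return a \linkS4class{GeneticCorrelation}.
#' @export
geneticCorrelation <- function(z1, z2, ld, n1, n2, mSnps = NULL, nBlocks = NULL) {
  ell <- if (is(ld, "LDScorePanel")) ldScores(ld)$ld_score else as.numeric(ld)
  if (is(ld, "LDScorePanel") && is.null(mSnps)) mSnps <- mSnps(ld)
  if (is.null(mSnps)) mSnps <- length(ell)
  nb <- .nJackBlocks(length(z1), nBlocks)
  x1 <- n1 * ell / mSnps; x2 <- n2 * ell / mSnps
  xc <- sqrt(n1 * n2) * ell / mSnps
  f1 <- .ldscFit(z1^2, x1, ell, nb, varFun = function(mu) 2 * mu^2)
  f2 <- .ldscFit(z2^2, x2, ell, nb, varFun = function(mu) 2 * mu^2)
  m1 <- pmax(f1$coef[1] + f1$coef[2] * x1, 0.1)
  m2 <- pmax(f2$coef[1] + f2$coef[2] * x2, 0.1)
  fc <- .ldscFit(z1 * z2, xc, ell, nb, varFun = function(mu) mu^2 + m1 * m2)
  h2_1 <- f1$coef[2]; h2_2 <- f2$coef[2]; gcov <- fc$coef[2]
  if (h2_1 <= 0 || h2_2 <= 0) {
    warning("nonpositive heritability estimate; rg undefined")
    return(new("GeneticCorrelation", rg = NA_real_, rgSE = NA_real_,
               h2_1 = h2_1, h2_2 = h2_2, gcovIntercept = fc$coef[1],
               outOfRange = FALSE, status = "nonpositive heritability"))
  }
  rg <- gcov / sqrt(h2_1 * h2_2)
  rg_loo <- fc$loo[, 2] / sqrt(pmax(f1$loo[, 2], 1e-12) * pmax(f2$loo[, 2], 1e-12))
  rgSE <- .jackSE(cbind(rg_loo, rg_loo))[1]
  new("GeneticCorrelation", rg = rg, rgSE = rgSE, h2_1 = h2_1, h2_2 = h2_2,
      gcovIntercept = fc$coef[1], outOfRange = abs(rg) > 1, status = "ok")
}
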