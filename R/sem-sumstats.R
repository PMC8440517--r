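## Multi-group maximum-likelihood SEM fitted to covariance matrices
## reconstructed from GWAS summary statistics. Structural parameters:
## o (offspring/direct effect), m (maternal effect), residual variances
## s1sq, s2sq, and residual covariance c (free only when a group observes
## both phenotypes).

#' Observed covariance matrices for the three SEM groups
#'
#' Reconstructs, for one variant, the covariance matrices the SEM is
#' fitted to, under the stated assumption that allele frequency, beta and
#' phenotype variance are shared across groups while sample sizes differ.
#' Own-phenotype-only group over (G, Y1): [[q, beta_own q], [beta_own q,
#' VarY1]]; offspring-only group analogous with beta_off; the
#' both-phenotypes group is 3x3 with Cov(Y1, Y2) = rPheno *
#' sqrt(VarY1 * VarY2).
#'
#' @param eaf effect allele frequency p, strictly in (0, 1); the genotype
#'   variance is q = 2p(1-p).
#' @param betaOwn,betaOff unadjusted betas from the own- and
#'   offspring-phenotype GWAS.
#' @param nOwnOnly,nOffOnly,nBoth group sample sizes (>= 0).
#' @param rPheno phenotypic correlation between own and offspring
#'   phenotype, used only in the both-phenotypes group.
#' @param varY1,varY2 phenotype variances (1 for standardized traits).
#' @return a \linkS4class{GroupCovarianceSet}.
#' @export
buildGroupCovariances <- function(eaf, betaOwn, betaOff, nOwnOnly, nOffOnly,
                                  nBoth, rPheno, varY1 = 1, varY2 = 1) {
  if (eaf <= 0 || eaf >= 1) stop("eaf must lie strictly in (0, 1)")
  if (min(nOwnOnly, nOffOnly, nBoth) < 0) stop("group sizes must be >= 0")
  q <- 2 * eaf * (1 - eaf)
  sOwn <- matrix(c(q, betaOwn * q, betaOwn * q, varY1), 2L, 2L,
                 dimnames = list(c("G", "Y1"), c("G", "Y1")))
  sOff <- matrix(c(q, betaOff * q, betaOff * q, varY2), 2L, 2L,
                 dimnames = list(c("G", "Y2"), c("G", "Y2")))
  c12 <- rPheno * sqrt(varY1 * varY2)
  sBoth <- matrix(c(q, betaOwn * q, betaOff * q,
                    betaOwn * q, varY1, c12,
                    betaOff * q, c12, varY2), 3L, 3L,
                  dimnames = list(c("G", "Y1", "Y2"), c("G", "Y1", "Y2")))
  new("GroupCovarianceSet",
      groups = list(own = list(S = sOwn, n = nOwnOnly, vars = c("G", "Y1")),
                    offspring = list(S = sOff, n = nOffOnly, vars = c("G", "Y2")),
                    both = list(S = sBoth, n = nBoth, vars = c("G", "Y1", "Y2"))),
      q = q, rPheno = rPheno)
}

## multi-group Wishart ML discrepancy
## F = sum_g (N_g - 1) [ln|Sigma_g| + tr(S_g Sigma_g^{-1}) - ln|S_g| - p_g]
.semDiscrepancy <- function(theta, covset) {
  q <- covset@q
  total <- 0
  for (nm in names(covset@groups)) {
    g <- covset@groups[[nm]]
    if (g$n <= 1) next
    grp <- switch(nm, own = "own", offspring = "offspring", both = "both")
    Sg <- g$S
    if (any(!is.finite(theta))) return(1e10)
    Sig <- impliedSigma(theta, q, grp)
    ldS <- determinant(Sig, logarithm = TRUE)
    if (ldS$sign <= 0) return(1e10)  # flagged for the optimizer
    tr <- tryCatch(sum(diag(solve(Sig, Sg))), error = function(e) NULL)
    if (is.null(tr) || !is.finite(tr)) return(1e10)
    total <- total + (g$n - 1) *
      (as.numeric(ldS$modulus) + tr -
       as.numeric(determinant(Sg, logarithm = TRUE)$modulus) - nrow(Sg))
  }
  total
}

## closed-form parameter values reproducing covariance matrices that were
## built by buildGroupCovariances (shared q/beta across groups); exact
## ML optimum with F = 0 whenever the residual variances come out positive
.semClosedForm <- function(covset) {
  q <- covset@q
  gs <- covset@groups
  betaOwn <- if (gs$own$n > 1) gs$own$S["G", "Y1"] / q else gs$both$S["G", "Y1"] / q
  betaOff <- if (gs$offspring$n > 1) gs$offspring$S["G", "Y2"] / q else gs$both$S["G", "Y2"] / q
  om <- conditionalFromUnconditional(c(betaOwn, betaOff), birthweightModel())
  o <- om[["offspring"]]; m <- om[["maternal"]]
  gvar <- q * (o^2 + m^2 + o * m)
  v1 <- if (gs$own$n > 1) gs$own$S["Y1", "Y1"] else gs$both$S["Y1", "Y1"]
  v2 <- if (gs$offspring$n > 1) gs$offspring$S["Y2", "Y2"] else gs$both$S["Y2", "Y2"]
  theta <- c(o = o, m = m, s1sq = v1 - gvar, s2sq = v2 - gvar)
  if (gs$both$n > 1)
    theta <- c(theta, c = gs$both$S["Y1", "Y2"] -
                 (0.5 * q * (o^2 + m^2) + 1.25 * o * m * q))
  theta
}

## observed information of F/2 at theta (exact Hessian when the model
## reproduces every S_g): I_jk = sum_g (N_g-1)/2 tr(Sigma^-1 dSigma_j
## Sigma^-1 dSigma_k), using the analytic derivative matrices
.semObservedInfo <- function(theta, q, ns, freeC) {
  o <- theta[["o"]]; m <- theta[["m"]]
  d_gv_o <- q * (2 * o + m); d_gv_m <- q * (2 * m + o)
  pars <- c("o", "m", "s1sq", "s2sq", if (freeC) "c")
  K <- length(pars)
  info <- matrix(0, K, K, dimnames = list(pars, pars))
  derivs <- function(grp) {
    switch(grp,
      own = list(
        o = matrix(c(0, q, q, d_gv_o), 2L),
        m = matrix(c(0, 0.5 * q, 0.5 * q, d_gv_m), 2L),
        s1sq = matrix(c(0, 0, 0, 1), 2L),
        s2sq = matrix(0, 2L, 2L),
        c = matrix(0, 2L, 2L)),
      offspring = list(
        o = matrix(c(0, 0.5 * q, 0.5 * q, d_gv_o), 2L),
        m = matrix(c(0, q, q, d_gv_m), 2L),
        s1sq = matrix(0, 2L, 2L),
        s2sq = matrix(c(0, 0, 0, 1), 2L),
        c = matrix(0, 2L, 2L)),
      both = {
        dc_o <- q * (o + 1.25 * m); dc_m <- q * (m + 1.25 * o)
        list(
          o = matrix(c(0, q, 0.5 * q,
                       q, d_gv_o, dc_o,
                       0.5 * q, dc_o, d_gv_o), 3L, byrow = TRUE),
          m = matrix(c(0, 0.5 * q, q,
                       0.5 * q, d_gv_m, dc_m,
                       q, dc_m, d_gv_m), 3L, byrow = TRUE),
          s1sq = diag(c(0, 1, 0)),
          s2sq = diag(c(0, 0, 1)),
          c = matrix(c(0, 0, 0, 0, 0, 1, 0, 1, 0), 3L))
      })
  }
  for (nm in names(ns)) {
    if (ns[[nm]] <= 1) next
    Sig <- impliedSigma(theta, q, nm)
    SigInv <- solve(Sig)
    D <- derivs(nm)
    Mj <- lapply(pars, function(p) SigInv %*% D[[p]])
    for (j in seq_len(K)) for (k in j:K) {
      tr <- sum(Mj[[j]] * t(Mj[[k]]))
      info[j, k] <- info[j, k] + (ns[[nm]] - 1) / 2 * tr
      if (k > j) info[k, j] <- info[j, k]
    }
  }
  info
}

## closed-form optimum + analytic observed information for one variant,
## bypassing object construction; returns NULL when the closed form is
## inadmissible so the caller can fall back to the numerical optimizer
.semFastVariant <- function(eaf, betaOwn, betaOff, nOwnOnly, nOffOnly,
                            nBoth, rPheno, varY1, varY2) {
  q <- 2 * eaf * (1 - eaf)
  o <- 4 / 3 * betaOwn - 2 / 3 * betaOff
  m <- 4 / 3 * betaOff - 2 / 3 * betaOwn
  gvar <- q * (o^2 + m^2 + o * m)
  s1 <- varY1 - gvar; s2 <- varY2 - gvar
  if (!is.finite(s1) || !is.finite(s2) || s1 <= 0 || s2 <= 0) return(NULL)
  freeC <- nBoth > 1
  cc <- if (freeC)
    rPheno * sqrt(varY1 * varY2) - (0.5 * q * (o^2 + m^2) + 1.25 * o * m * q)
  else 0
  theta <- c(o = o, m = m, s1sq = s1, s2sq = s2, c = cc)
  ns <- list(own = nOwnOnly, offspring = nOffOnly, both = nBoth)
  info <- .semObservedInfo(theta, q, ns, freeC)
  covTheta <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(covTheta)) return(NULL)
  list(theta = theta, covTheta = covTheta)
}

#' Fit the summary-statistics SEM by multi-group maximum likelihood
#'
#' Minimizes the multi-group Wishart discrepancy
#' F = sum_g (N_g - 1) [ln|Sigma_g(theta)| + tr(S_g Sigma_g(theta)^{-1}) -
#' ln|S_g| - p_g] over theta = (o, m, s1sq, s2sq, c) using a quasi-Newton
#' optimizer with residual variances log-transformed to stay positive and
#' up to five jittered restarts on failure. The residual covariance c is
#' fixed at 0 when no group observes both phenotypes. Standard errors come
#' from the inverse of the numerical Hessian of F/2 at the optimum
#' (observed information); Wald p-values for o and m from z = theta/SE.
#'
#' Starting values default to the closed-form solution that reproduces the
#' observed matrices exactly (the exact optimum for covariance sets built
#' by \code{\link{buildGroupCovariances}}).
#'
#' @param covset a \linkS4class{GroupCovarianceSet}.
#' @param start optional named starting vector (o, m, s1sq, s2sq, c).
#' @param relTol relative convergence tolerance on F.
#' @return a \linkS4class{SemFit}.
#' @export
fitSemML <- function(covset, start = NULL, relTol = 1e-8) {
  freeC <- covset@groups$both$n > 1
  if (is.null(start)) {
    start <- tryCatch(.semClosedForm(covset), error = function(e) NULL)
    if (is.null(start) || any(!is.finite(start)) ||
        start[["s1sq"]] <= 0 || start[["s2sq"]] <= 0)
      start <- c(o = 0, m = 0, s1sq = 0.5, s2sq = 0.5, c = 0)
  }
  if (freeC && !("c" %in% names(start))) start <- c(start, c = 0)
  pars <- c("o", "m", "s1sq", "s2sq", if (freeC) "c")
  toOpt <- function(th) {  # log-transform the variances
    x <- th[pars]
    x[c("s1sq", "s2sq")] <- log(x[c("s1sq", "s2sq")])
    x
  }
  fromOpt <- function(x) {
    th <- setNames(x, pars)
    th[c("s1sq", "s2sq")] <- exp(th[c("s1sq", "s2sq")])
    if (!freeC) th <- c(th, c = 0)
    th
  }
  obj <- function(x) .semDiscrepancy(fromOpt(x), covset)
  best <- NULL
  x0 <- toOpt(start)
  for (attempt in 0:5) {
    xs <- if (attempt == 0) x0 else x0 + rnorm(length(x0), sd = 0.1 * attempt)
    fit <- tryCatch(optim(xs, obj, method = "BFGS",
                          control = list(reltol = relTol, maxit = 500L)),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$convergence == 0 && is.finite(fit$value)) {
      best <- fit; break
    }
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best) || !is.finite(best$value)) {
    return(new("SemFit", theta = setNames(rep(NA_real_, 5),
                                          c("o", "m", "s1sq", "s2sq", "c")),
               covTheta = matrix(NA_real_, 2, 2), minimum = NA_real_,
               converged = FALSE, waldP = c(o = NA_real_, m = NA_real_),
               seOk = FALSE))
  }
  theta <- fromOpt(best$par)
  ## observed information on the untransformed scale, with step sizes
  ## scaled by parameter magnitude
  objRaw <- function(v) {
    th <- setNames(v, pars)
    if (!freeC) th <- c(th, c = 0)
    if (th[["s1sq"]] <= 0 || th[["s2sq"]] <= 0) return(1e10)
    .semDiscrepancy(th, covset)
  }
  vhat <- theta[pars]
  H <- tryCatch(optimHess(vhat, objRaw,
                          control = list(ndeps = pmax(abs(vhat), 0.05) * 1e-3)),
                error = function(e) NULL)
  seOk <- FALSE
  covTheta <- matrix(NA_real_, length(pars), length(pars),
                     dimnames = list(pars, pars))
  if (!is.null(H)) {
    ev <- eigen(H / 2, symmetric = TRUE, only.values = TRUE)$values
    if (all(ev > 0)) {
      covTheta <- solve(H / 2)
      dimnames(covTheta) <- list(pars, pars)
      seOk <- TRUE
    }
  }
  z <- theta[c("o", "m")] / sqrt(diag(covTheta)[c("o", "m")])
  new("SemFit", theta = theta, covTheta = covTheta,
      minimum = best$value, converged = best$convergence == 0,
      waldP = setNames(.waldP(z), c("o", "m")), seOk = seOk)
}

#' Per-variant SEM over a harmonized own/offspring GWAS pair
#'
#' Table-level driver: for each harmonized variant it reconstructs the
#' group covariance matrices and evaluates the SEM. Because matrices built
#' from a shared beta/eaf are reproduced exactly by the model, the ML
#' optimum is available in closed form (F = 0) and the observed
#' information equals the analytic expected information there; this driver
#' uses that fast path and falls back to the numerical optimizer
#' (\code{\link{fitSemML}}) for any variant where the closed form is
#' inadmissible (nonpositive residual variance). Per-variant fits are
#' independent, so results do not depend on how the table is partitioned.
#'
#' @param pair a \linkS4class{HarmonizedSet} of the own and offspring GWAS
#'   (first table own, second offspring, or name them).
#' @param rPheno phenotypic correlation between own and offspring
#'   phenotype.
#' @param nOverlapEst estimated number of individuals in both GWAS
#'   (e.g. from \code{\link{overlapFromIntercept}}).
#' @param own,offspring table names, as in \code{\link{adjustTable}}.
#' @return a data.frame with per-variant conditional estimates
#'   (beta/se/p for offspring and maternal effects), the estimate
#'   covariance, the minimized discrepancy and a convergence flag.
#' @export
semGwas <- function(pair, rPheno, nOverlapEst, own = NULL, offspring = NULL) {
  tabs <- harmonizedTables(pair)
  if (length(tabs) != 2L) stop("the SEM pathway needs exactly two tables")
  if (is.null(own)) own <- names(tabs)[1]
  if (is.null(offspring)) offspring <- names(tabs)[2]
  vo <- variantData(tabs[[own]]); vm <- variantData(tabs[[offspring]])
  varY1 <- phenotypeVariance(tabs[[own]])
  varY2 <- phenotypeVariance(tabs[[offspring]])
  p <- nrow(vo)
  out <- data.frame(variant_id = vo$variant_id, chrom = vo$chrom,
                    pos = vo$pos, eaf = vo$eaf,
                    beta_offspring = NA_real_, se_offspring = NA_real_,
                    p_offspring = NA_real_,
                    beta_maternal = NA_real_, se_maternal = NA_real_,
                    p_maternal = NA_real_,
                    cov_offspring_maternal = NA_real_,
                    discrepancy = NA_real_, converged = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(p)) {
    nBoth <- min(nOverlapEst, vo$n[i], vm$n[i])
    fast <- .semFastVariant(vo$eaf[i], vo$beta[i], vm$beta[i],
                            nOwnOnly = vo$n[i] - nBoth,
                            nOffOnly = vm$n[i] - nBoth, nBoth = nBoth,
                            rPheno = rPheno, varY1 = varY1, varY2 = varY2)
    if (!is.null(fast)) {
      covTheta <- fast$covTheta
      se <- sqrt(diag(covTheta)[c("o", "m")])
      out$beta_offspring[i] <- fast$theta[["o"]]
      out$beta_maternal[i] <- fast$theta[["m"]]
      out$se_offspring[i] <- se[["o"]]
      out$se_maternal[i] <- se[["m"]]
      out$p_offspring[i] <- .waldP(fast$theta[["o"]] / se[["o"]])
      out$p_maternal[i] <- .waldP(fast$theta[["m"]] / se[["m"]])
      out$cov_offspring_maternal[i] <- covTheta["o", "m"]
      out$discrepancy[i] <- 0
      out$converged[i] <- TRUE
      next
    }
    covset <- buildGroupCovariances(vo$eaf[i], vo$beta[i], vm$beta[i],
                                    nOwnOnly = vo$n[i] - nBoth,
                                    nOffOnly = vm$n[i] - nBoth,
                                    nBoth = nBoth, rPheno = rPheno,
                                    varY1 = varY1, varY2 = varY2)
    fit <- fitSemML(covset)
    if (isConverged(fit) && fit@seOk) {
      th <- semTheta(fit); ct <- semCov(fit)
      out$beta_offspring[i] <- th[["o"]]; out$beta_maternal[i] <- th[["m"]]
      out$se_offspring[i] <- sqrt(ct["o", "o"])
      out$se_maternal[i] <- sqrt(ct["m", "m"])
      out$p_offspring[i] <- waldP(fit)[["o"]]
      out$p_maternal[i] <- waldP(fit)[["m"]]
      out$cov_offspring_maternal[i] <- ct["o", "m"]
      out$discrepancy[i] <- fit@minimum
      out$converged[i] <- TRUE
    }
  }
  out
}
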