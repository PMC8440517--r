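## Biometrical path models: coefficient matrices mapping conditional
## effects to unconditional GWAS expectations, and model-implied
## covariance algebra for the summary-statistics SEM.

#' Birth weight maternal/offspring path model
#'
#' Two conditional effects (offspring o, maternal m) observed through two
#' unconditional GWAS: a GWAS of own phenotype on own genotype tags
#' o + 0.5 m, and a GWAS of offspring phenotype on own genotype tags
#' m + 0.5 o, because parent and child genotypes are correlated 0.5. The
#' coefficient matrix is A = [[1, 0.5], [0.5, 1]]; its inverse
#' [[4/3, -2/3], [-2/3, 4/3]] carries the coefficients of the closed-form
#' linear adjustment.
#'
#' @return a \linkS4class{PathModelSpec} with labels (offspring, maternal).
#' @export
birthweightModel <- function() {
  A <- matrix(c(1, 0.5, 0.5, 1), 2L, 2L,
              dimnames = list(c("own_gwas", "offspring_gwas"),
                              c("offspring", "maternal")))
  new("PathModelSpec", labels = c("offspring", "maternal"), A = A,
      relatedness = 0.5, freeResiduals = c("s1sq", "s2sq", "c"))
}

#' Fertility female/male/sibling path model
#'
#' Three conditional effects (female fertility f, male fertility m,
#' sibling-specific s) observed through three unconditional GWAS of family
#' size: mothers' genotype vs children mothered tags f + 0.5 s, fathers'
#' genotype vs children fathered tags m + 0.5 s, and offspring genotype vs
#' number of siblings tags 0.5 f + 0.5 m + s. With \code{threeTraits =
#' FALSE} the male row/column is removed, giving the two-trait
#' female/sibling model [[1, 0.5], [0.5, 1]].
#'
#' @param threeTraits include the male fertility effect (default TRUE).
#' @return a \linkS4class{PathModelSpec}.
#' @export
fertilityModel <- function(threeTraits = TRUE) {
  A <- matrix(c(1,   0,   0.5,
                0,   1,   0.5,
                0.5, 0.5, 1), 3L, 3L, byrow = TRUE,
              dimnames = list(c("mothered_gwas", "fathered_gwas", "siblings_gwas"),
                              c("female", "male", "sibling")))
  labels <- c("female", "male", "sibling")
  if (!threeTraits) {
    A <- A[-2L, -2L]
    labels <- labels[-2L]
  }
  new("PathModelSpec", labels = labels, A = A, relatedness = 0.5,
      freeResiduals = character())
}

#' Recover conditional effects from unconditional GWAS betas
#'
#' Solves beta_unconditional = A %*% beta_conditional for the conditional
#' effect vector: theta = A^{-1} %*% beta. For the birth weight model this
#' is exactly the linear adjustment with coefficients 4/3 and -2/3.
#'
#' @param betaUnadj K-vector (or nVariants x K matrix) of unconditional
#'   betas, ordered as the rows of \code{coefMatrix(model)}.
#' @param model a \linkS4class{PathModelSpec}.
#' @return conditional effects in the same shape as the input, named by
#'   the model's effect labels.
#' @export
conditionalFromUnconditional <- function(betaUnadj, model) {
  Ainv <- solve(coefMatrix(model))
  if (is.matrix(betaUnadj)) {
    out <- betaUnadj %*% t(Ainv)
    colnames(out) <- effectLabels(model)
    out
  } else {
    setNames(drop(Ainv %*% betaUnadj), effectLabels(model))
  }
}

#' Model-implied covariance matrices for the birth weight SEM
#'
#' Expected covariance over the observed variables of each group, at
#' structural parameters theta = (o, m, s1sq, s2sq, c) and genotype
#' variance q = 2p(1-p). For the group observing both phenotypes, over
#' (G, Y1 = own, Y2 = offspring):
#' Var(G) = q; Cov(G, Y1) = (o + 0.5 m) q; Cov(G, Y2) = (m + 0.5 o) q;
#' Var(Y1) = q(o^2 + m^2 + om) + s1sq; Var(Y2) = q(o^2 + m^2 + om) + s2sq;
#' Cov(Y1, Y2) = 0.5 q (o^2 + m^2) + 1.25 om q + c, where the 0.25 q
#' grandmother-grandchild genotype covariance enters the om cross terms.
#' Single-phenotype groups return the corresponding 2x2 submodel (no c).
#'
#' @param theta named vector with elements o, m, s1sq, s2sq and (for the
#'   both-phenotypes group) c.
#' @param q genotype variance 2p(1-p), in (0, 0.5].
#' @param group which observed variables are present: "own" (G, Y1),
#'   "offspring" (G, Y2) or "both" (G, Y1, Y2).
#' @return the implied covariance matrix.
#' @export
impliedSigma <- function(theta, q, group = c("both", "own", "offspring")) {
  group <- match.arg(group)
  if (q <= 0) stop("genotype variance q must be positive")
  o <- theta[["o"]]; m <- theta[["m"]]
  s1 <- theta[["s1sq"]]; s2 <- theta[["s2sq"]]
  if (s1 <= 0 || s2 <= 0) stop("residual variances must be positive")
  gvar <- q * (o^2 + m^2 + o * m)
  covG1 <- (o + 0.5 * m) * q
  covG2 <- (m + 0.5 * o) * q
  switch(group,
    own = matrix(c(q, covG1, covG1, gvar + s1), 2L, 2L,
                 dimnames = list(c("G", "Y1"), c("G", "Y1"))),
    offspring = matrix(c(q, covG2, covG2, gvar + s2), 2L, 2L,
                       dimnames = list(c("G", "Y2"), c("G", "Y2"))),
    both = {
      cc <- if ("c" %in% names(theta)) theta[["c"]] else 0
      cov12 <- 0.5 * q * (o^2 + m^2) + 1.25 * o * m * q + cc
      matrix(c(q,     covG1,      covG2,
               covG1, gvar + s1,  cov12,
               covG2, cov12,      gvar + s2), 3L, 3L,
             dimnames = list(c("G", "Y1", "Y2"), c("G", "Y1", "Y2")))
    })
}
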