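## Between-method heterogeneity tests, genome-wide significance and locus
## counting, and known/novel classification of sentinel variants.

#' Heterogeneity test between two effect estimates
#'
#' Cochran-style statistic Q = (beta1 - beta2)^2 / (se1^2 + se2^2),
#' referred to a chi-square with 1 degree of freedom. When the two
#' estimates come from the same underlying data their correlation is
#' ignored, which makes the test conservative for positively correlated
#' estimators (and liberal for negatively correlated ones).
#'
#' @param beta1,beta2 the two effect estimates (vectorized).
#' @param se1,se2 their standard errors (> 0).
#' @param nTests number of tests for the Bonferroni-adjusted significance
#'   threshold reported alongside (default 1).
#' @param alpha family-wise level for that threshold.
#' @return a data.frame with columns Q, p, and the Bonferroni threshold
#'   \code{alpha_bonferroni}.
#' @export
heterogeneityTest <- function(beta1, se1, beta2, se2, nTests = 1L,
                              alpha = 0.05) {
  if (any(se1 <= 0) || any(se2 <= 0)) stop("standard errors must be positive")
  Q <- (beta1 - beta2)^2 / (se1^2 + se2^2)
  data.frame(Q = Q, p = pchisq(Q, df = 1L, lower.tail = FALSE),
             alpha_bonferroni = alpha / nTests)
}

#' Count genome-wide significant loci by greedy sentinel selection
#'
#' Repeatedly takes the smallest-p variant with p < alpha that does not
#' lie within \code{windowBp} of an already chosen sentinel on the same
#' chromosome. Ties in p are broken deterministically by (chrom, pos,
#' variant_id). The result is invariant to input row order.
#'
#' @param results data.frame with columns chrom, pos, p and (optionally)
#'   variant_id.
#' @param alpha significance threshold (default genome-wide 5e-8).
#' @param windowBp locus half-width in base pairs (default 500 kb): a
#'   variant within |pos - sentinel| <= windowBp on the same chromosome
#'   belongs to that sentinel's locus.
#' @return a \linkS4class{LocusSet}.
#' @export
countLoci <- function(results, alpha = 5e-8, windowBp = 5e5) {
  if (!all(c("chrom", "pos", "p") %in% names(results)))
    stop("results needs chrom, pos and p columns")
  if (!"variant_id" %in% names(results))
    results$variant_id <- paste0(results$chrom, ":", results$pos)
  sig <- results[!is.na(results$p) & results$p < alpha,
                 c("variant_id", "chrom", "pos", "p")]
  ord <- order(sig$p, as.character(sig$chrom), sig$pos,
               as.character(sig$variant_id))
  sig <- sig[ord, , drop = FALSE]
  keep <- logical(nrow(sig))
  for (i in seq_len(nrow(sig))) {
    prior <- sig[keep & sig$chrom == sig$chrom[i], , drop = FALSE]
    if (nrow(prior) == 0L || all(abs(prior$pos - sig$pos[i]) > windowBp))
      keep[i] <- TRUE
  }
  sent <- sig[keep, , drop = FALSE]
  rownames(sent) <- NULL
  new("LocusSet", sentinels = sent, windowBp = windowBp)
}

#' Classify loci as known or novel against a sentinel list
#'
#' A locus is flagged known when its sentinel lies within \code{windowBp}
#' of any known sentinel on the same chromosome; loci strictly more than
#' \code{windowBp} away from every known sentinel are novel.
#'
#' @param loci a \linkS4class{LocusSet}.
#' @param known data.frame of known sentinels with columns chrom, pos
#'   (an empty data.frame marks every locus novel).
#' @param windowBp window defining "known" (defaults to the locus window).
#' @return the \linkS4class{LocusSet} with a logical \code{novel} column
#'   added to its sentinels.
#' @export
classifyNovel <- function(loci, known, windowBp = NULL) {
  if (is.null(windowBp)) windowBp <- loci@windowBp
  sent <- sentinels(loci)
  if (nrow(sent) == 0L) {
    sent$novel <- logical(0)
  } else if (is.null(known) || nrow(known) == 0L) {
    sent$novel <- rep(TRUE, nrow(sent))
  } else {
    sent$novel <- vapply(seq_len(nrow(sent)), function(i) {
      near <- known$chrom == sent$chrom[i] &
              abs(known$pos - sent$pos[i]) <= windowBp
      !any(near)
    }, TRUE)
  }
  initialize(loci, sentinels = sent)
}
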