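---
title: "Partitioning GWAS effects into direct and indirect components from summary statistics"
author: "famcond"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning GWAS effects into direct and indirect components from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famcond)
```

## The problem

A standard GWAS regression of a phenotype on an individual's genotype
estimates a *marginal* (unconditional) effect. When a relative's genotype
also influences the phenotype — a maternal genotype acting through the
intrauterine environment on birth weight, or an offspring's genotype
influencing parental fertility decisions — the marginal slope mixes the
direct and indirect components, because parent and child genotypes are
correlated 0.5 under additive Mendelian transmission. Conditional analyses
on genotyped parent–offspring pairs disentangle the two, but few cohorts
have enough such pairs. This package recovers the conditional components
from *summary statistics alone*: pairs (or triples) of unconditional GWAS
of the same phenotype measured against different family members'
genotypes.

## The structural model

Let $\theta$ be the vector of conditional effects at a variant and
$\beta$ the vector of expected unconditional GWAS slopes. The biometrical
relatedness structure gives a fixed mixing matrix $A$ with
$E[\hat\beta] = A\theta$. For the own/offspring birth weight design, with
$o$ the direct (offspring) effect and $m$ the maternal effect,

$$A = \begin{pmatrix} 1 & 0.5 \\ 0.5 & 1 \end{pmatrix}, \qquad
E[\hat\beta_{own}] = o + 0.5\,m, \quad
E[\hat\beta_{offspring}] = m + 0.5\,o,$$

because the latent parental/offspring genotypes are correlated 0.5 with
the observed genotype (`birthweightModel()`). For the fertility design
(`fertilityModel()`), family size is regressed on the mother's, father's
and an offspring's genotype, giving female ($f$), male ($m$) and
sibling-specific ($s$) effects with

$$A = \begin{pmatrix} 1 & 0 & 0.5 \\ 0 & 1 & 0.5 \\ 0.5 & 0.5 & 1 \end{pmatrix}.$$

The exact fertility path diagram is a modelling decision of this package:
it encodes assortment-free additive transmission, with the sibling GWAS
tagging each parental effect at 0.5 and the sibling effect fully. Both
matrices are invertible, so every model here is just-identified and
$\hat\theta = A^{-1}\hat\beta$ is the unique moment solution.

Three estimators share this structural core and differ in how they treat
sampling error:

1. **Linear adjustment** (`adjustPair()`, `adjustTable()`): the exact
   closed form $\hat\theta = A^{-1}\hat\beta$, i.e.
   $\hat\beta_{o,adj} = -\tfrac{2}{3}\hat\beta_{m,unadj} +
   \tfrac{4}{3}\hat\beta_{o,unadj}$ and symmetrically for the maternal
   component, with covariance $A^{-1}\,\mathrm{diag}(se^2)\,A^{-T}$. It
   assumes the two GWAS share no samples; with overlap its standard
   errors omit a (positive) covariance term and become conservative. No
   overlap correction is applied — that term is a documented limitation,
   and the overlap-aware solver below is the remedy.

2. **Summary-statistics SEM** (`buildGroupCovariances()`, `fitSemML()`,
   `semGwas()`): reconstructs per-group observed covariance matrices over
   (genotype, own phenotype, offspring phenotype) for the three
   observation groups — own phenotype only, offspring phenotype only,
   both — assuming allele frequency, beta and phenotype variance are
   shared across groups while sample sizes differ. Structural parameters
   $(o, m, \sigma_1^2, \sigma_2^2, c)$ are fitted by multi-group maximum
   likelihood with the Wishart discrepancy
   $F = \sum_g (N_g-1)\left[\ln|\Sigma_g(\theta)| +
   \mathrm{tr}(S_g\Sigma_g^{-1}(\theta)) - \ln|S_g| - p_g\right]$.
   The implied moments use $\mathrm{Var}(Y) = q(o^2+m^2+om)+\sigma^2$ and
   $\mathrm{Cov}(Y_1,Y_2) = 0.5q(o^2+m^2) + 1.25\,om\,q + c$ with
   genotype variance $q = 2p(1-p)$ and a 0.25 grandmother–grandchild
   genotype covariance; the expansion is verified in the test suite by
   moment-matching against the generative simulator. The size of the
   "both" group comes from the cross-trait LD score regression intercept
   (below). When no group observes both phenotypes, $c$ is fixed at 0.

3. **Overlap-aware solver** (`conditionalSolve()`, `conditionalGwas()`),
   in the style of Genomic SEM: the same closed-form point estimate, but
   a per-variant sampling covariance $V$ with $V_{ii} = se_i^2$ and
   $V_{ij} = c_{ij}\,se_i\,se_j$, where $c_{ij}$ is the cross-trait LD
   score regression intercept between GWAS $i$ and $j$. For
   just-identified models the diagonally weighted least squares solution
   coincides with $A^{-1}\hat\beta$, so no iterative SEM engine is
   needed; the package restricts itself to just-identified models for
   exactly this reason. With $c = I$ the estimator reduces *exactly* to
   the linear adjustment.

## Sample overlap and LD score regression

The cross-trait LD score regression of $z_1 z_2$ on
$\sqrt{n_1 n_2}\,\ell/M$ has intercept $N_s r_p / \sqrt{n_1 n_2}$, where
$N_s$ is the number of individuals in both GWAS and $r_p$ the phenotypic
correlation. `overlapFromIntercept()` inverts this to an overlap estimate
(clamped to $[0, \min(n_1, n_2)]$, with the raw value retained);
`interceptFromOverlap()` is its exact inverse and feeds the sampling
covariance when the overlap is known. The univariate regression of $z^2$
on $n\ell/M$ supplies intercept diagnostics and heritability slopes, and
`geneticCorrelation()` forms $r_g = \widehat{gcov}/\sqrt{\hat h^2_1 \hat
h^2_2}$.

Implementation choices, all exercised by the tests:

* **Weights**: a first pass with heteroskedasticity weights
  $1/\max(\ell, 1)$, then a second pass additionally down-weighting by
  the squared predicted mean of the regressand (the variance of a
  product of correlated normals). This mirrors common LD score
  regression practice while staying fully specified here.
* **Jackknife**: delete-one-block over 200 position-contiguous blocks,
  falling back to $\lfloor n_{snps}/50\rfloor$ blocks for desk-scale
  panels, computed from per-block sufficient statistics. The delete-block
  jackknife is known to be slightly anti-conservative at these block
  counts, so internal checks use 99% rather than 95% intervals.
* **No stratification-adjusted intercept**: the plain intercept is
  converted to overlap; modified intercepts that absorb population
  stratification are deliberately out of scope.
* **Negative overlap estimates** clamp to zero (the raw value is kept
  for diagnostics).

## The simulator defines the test conditions

`simulateFamilies()` draws parental genotypes under Hardy–Weinberg
equilibrium and transmits alleles fairly, reproducing the 0.5
parent–child and 0.25 grandparent–grandchild genotype correlations.
Phenotypes follow the generative mirror of the structural model:
$Y_1 = o\,G_{self} + m\,G_{mother} + e_1$ and
$Y_2 = o\,G_{child} + m\,G_{self} + e_2$ with correlated residuals; for
fertility, a single family-size outcome
$Y = f\,G_{mother} + m\,G_{father} + s\,G_{child} + e$ is tested against
each member's genotype. Defaults are chosen once as the study
conditions:

* allele frequency 0.3 (common variants, $q = 0.42$);
* residual variance completed so each phenotype has unit total variance,
  matching the standardized-trait convention of the estimators — the
  residual *correlation* is exposed separately (default in the package's
  own studies: 0.24, the scale of the phenotypic correlation between own
  and offspring birth weight) because the total phenotypic correlation
  additionally contains a small genetic term;
* variants in linkage equilibrium — the estimators act per variant, so
  LD matters only where LD score regression itself is tested, and there
  `simulateLdscZscores()` generates z-scores directly from the bivariate
  LDSC expectation over a long-tailed synthetic LD score panel
  ($1 + \Gamma(1.5, 60)$, genome-wide $M = 10^6$);
* overlap masks assign families to the two GWAS so that the intersection
  is exactly `round(overlapFraction * nFamilies)` and the union covers
  the sample;
* one master seed expands into child seeds per component (genotypes,
  residuals, masks, panels), making every piece independently
  reproducible and the whole pipeline bit-reproducible.

What the simulator deliberately does not emulate: linkage disequilibrium
in family data, assortative mating, dynastic structures beyond trios,
imputation noise, count-type fertility outcomes (a Gaussian latent scale
is used, matching how linear GWAS treat such phenotypes), and
mixed-model GWAS machinery (plain per-SNP OLS replaces it). Passing
tests therefore demonstrate correctness of the estimators under the
stated model, not robustness to those real-data features.

## Numerical choices

* The SEM optimizer is BFGS on $(o, m, \log\sigma_1^2, \log\sigma_2^2,
  c)$ — the log transform enforces positive variances — with up to five
  jittered restarts and a relative tolerance of $10^{-8}$; degenerate
  implied covariances return a large penalty rather than an error.
  Starting values come from the closed-form solution, which for
  covariance sets built from a shared beta and allele frequency is the
  exact optimum ($F = 0$).
* Standard errors use the observed information (Hessian of $F/2$) at the
  optimum, with finite-difference steps scaled by parameter magnitude.
  The table driver `semGwas()` exploits the fact that observed and
  expected information coincide at $F = 0$ and evaluates the analytic
  information instead (agreement with the numerical Hessian to $10^{-6}$
  relative is part of the test suite), falling back to the numerical
  optimizer when the closed form is inadmissible (nonpositive residual
  variance, as can happen for low-frequency variants — the reason the
  SEM pathway conventionally gates at MAF $\ge$ 0.5%).
* The multiplier is $N_g - 1$ (Wishart convention); immaterial at GWAS
  sample sizes.
* Intercept matrices are clamped to $[-0.99, 0.99]$ off the diagonal so
  the sampling covariance stays positive definite for $K \le 3$; an
  eigenvalue-clip repair (with a warning) is the last resort.
* Wald p-values are two-sided normal; natural-log p-values are carried
  alongside because extreme signals underflow double precision below
  about $10^{-308}$ (an exact zero in `waldP` marks underflow).
* Harmonization aligns everything to the first table: swapped alleles
  flip beta and allele frequency; strand complements are reconciled only
  when they match exactly and strand-ambiguous filtering is off;
  anything else is dropped, as are variants whose aligned allele
  frequencies disagree by more than 0.2 — conservative choices that
  favour dropping a variant over a silent sign error. Ties in locus
  sentinel selection break deterministically by (chrom, pos, id).

## Scales used by the checks

The packaged checks run at desk scale, chosen to keep the full suite in
minutes while leaving Monte-Carlo error well inside the asserted bands:
parameter recovery uses 20,000 families x 200 variants with
$(o, m) = (0.06, -0.04)$; overlap calibration 10,000 families x 1,000
variants at 45% overlap (mirroring the 85,503/183,728 overlap fraction
of the motivating design, with the phenotypic correlation estimated from
the overlapping families exactly as one would from real data); null
calibration 2,000 families x 100,000 variants; LD score regression loops
20,000-variant panels. Larger runs only tighten the same comparisons.

## Known limitations

* The linear adjustment's standard errors ignore sample overlap by
  construction; under overlap they over-cover (the package reproduces
  this as a testable contrast with the overlap-aware solver).
* Conversely, feeding the SEM a spurious positive overlap estimate
  (e.g. from cryptic relatedness inflating the cross-trait intercept)
  shrinks its standard errors below nominal — the anti-conservative
  failure mode of the no-overlap configuration. The package reports raw
  overlap estimates and leaves any correction to the analyst.
* SEM estimates are sensitive to misspecification of the phenotypic
  correlation $r_p$; it is a required input, and a sensitivity sweep
  (refitting over a grid of $r_p$) is the recommended practice.
* Over-identified or latent-factor structural models, LD-aware clumping,
  genome-build liftover and INFO-based filtering are out of scope.
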