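---
title: "Methods: single-step genomic reaction-norm models in ssrnm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-step genomic reaction-norm models in ssrnm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrnm)
```

## The scientific problem

Livestock populations are raised across farms, years and seasons that
differ in management and climate. If the genetic merit of an animal
depends on the environment it is expressed in — genotype-by-environment
interaction (G×E) — then animals selected in good environments may not be
the best in poor ones, and genetic progress realized in nucleus herds may
not carry over to commercial conditions. `ssrnm` implements a complete
workflow for quantifying such interactions when the environment is not
measured directly but must itself be inferred from the data, and when only
part of the pedigree is genotyped.

## Model

For a record of animal $j$ in contemporary group (CG) $i$,

$$
y_{ij} = \mathbf{x}'_{ij}\boldsymbol\beta + b\,\hat\theta_i +
  \sum_{r}\left(n_{0rj} + n_{1rj}\hat\theta_i\right) + e_{ij},
$$

where $\hat\theta_i$ is a standardized environmental gradient (below),
$b$ a fixed overall regression on the gradient, and each random effect
$r \in \{a, pe, ce\}$ (additive genetic, permanent environment, common
litter environment) contributes an intercept $n_{0rj}$ and a slope
$n_{1rj}$ — a linear reaction norm. For the additive effect,

$$
\begin{bmatrix}\mathbf a_0\\ \mathbf a_1\end{bmatrix} \sim
N\!\left(\mathbf 0,\; \mathbf B_a \otimes \mathbf H\right),
\qquad
\mathbf B_a = \begin{bmatrix}\sigma^2_{a_0} & \sigma_{a_0a_1}\\
\sigma_{a_0a_1} & \sigma^2_{a_1}\end{bmatrix},
$$

with $\mathbf H$ the single-step hybrid relationship matrix; `pe` and
`ce` use identity kernels. The residual is either homogeneous
($\sigma^2_e$, model RNM1) or varies exponentially along the gradient,
$\sigma^2_e(\theta) = \exp(d_0 + d_1\theta)$ (model RNM2). RNM1 is
implemented as the $d_1 = 0$ special case of the same code path, so the
two models are nested by construction and comparable by AIC,
$\mathrm{AIC} = -2\log L + 2k$ with $k$ the number of estimated
(co)variance parameters.

Derived gradient-dependent parameters follow from $\mathbf B_a$:

* additive variance
  $\sigma^2_u(\theta) = \sigma^2_{a_0} + 2\sigma_{a_0a_1}\theta +
  \sigma^2_{a_1}\theta^2$;
* heritability $h^2(\theta)$ as its share of the total variance at
  $\theta$ (every fitted block contributes the same quadratic form);
* the genetic correlation between environments $\theta_i$ and
  $\theta_j$, which equals 1 for all pairs exactly when
  $\sigma^2_{a_1} = 0$ — correlations below about 0.8 are the practical
  re-ranking signal;
* the intercept–slope correlation
  $\sigma_{a_0a_1}/\sqrt{\sigma^2_{a_0}\sigma^2_{a_1}}$.

## The environmental gradient

The environment enters as the estimated mean effect of the contemporary
group. The workflow is deliberately two-stage:

1. record filters: CGs with fewer than 10 records are dropped first, then
   records beyond 3.5 SD of the trait mean (mean and SD computed before
   any removal);
2. systematic effects are pruned by backward elimination on an ordinary
   linear model (partial F-tests at $\alpha = 0.05$), always retaining
   the CG factor;
3. CG effects are estimated by BLUE under a sum-to-zero constraint;
4. the estimates are z-scored, CGs beyond 3.5 SD discarded, and the
   remainder re-standardized, so the retained gradient has mean 0 and SD
   1 exactly.

Treating $\hat\theta_i$ as a known covariate ignores its estimation
error; with the default CG sizes this is a mild attenuation (CG mean
standard errors are an order of magnitude below the gradient SD), and it
is the standard practice this package follows. `rnm(cg_as_class = TRUE)`
additionally lets the user absorb CG means as fixed classes instead of
the single regression $b\hat\theta$.

## Single-step relationship matrix

Genotype QC keeps SNPs with call rate ≥ 0.90, MAF ≥ 0.01 and an absolute
difference between observed and expected heterozygosity ≤ 0.15 (the
classical proxy for Hardy–Weinberg disequilibrium that does not require a
test statistic), and animals with call rate ≥ 0.90. On the X chromosome
males are hemizygous and coded on the {0, 2} dosage scale, so the
heterozygosity check uses females only.

The genomic matrix is VanRaden's method 1,
$\mathbf G = \mathbf Z\mathbf Z' / 2\sum_k p_k(1-p_k)$ with observed
frequencies, blended as $0.95\,\mathbf G + 0.05\,\mathbf A_{22}$ to
guarantee invertibility. The single-step inverse is

$$
\mathbf H^{-1} = \mathbf A^{-1} +
\begin{bmatrix}\mathbf 0 & \mathbf 0\\
\mathbf 0 & \mathbf G^{-1} - \mathbf A_{22}^{-1}\end{bmatrix},
$$

with $\mathbf A^{-1}$ from Henderson's rules with inbreeding
(Meuwissen–Luo recursion for $F$); no additional scaling parameters are
applied. When no genotypes are supplied every downstream computation
falls back to $\mathbf A^{-1}$ transparently.

## REML implementation and numerical choices

The restricted likelihood is evaluated exactly through the sparse
Cholesky factorization of the mixed-model equations:

$$
-2\log L = \log|\mathbf R| + \sum_r\left(q_r\log|\mathbf B_r| +
\log|\mathbf K_r|\right) + \log|\mathbf C| + \mathbf y'\mathbf P\mathbf y
+ (n-p)\log 2\pi .
$$

Classical implementations iterate average-information (AI) REML updates.
`ssrnm` instead maximizes the same exact likelihood with a quasi-Newton
box-constrained optimizer (`nlminb`) on an unconstrained scale — log
variances, Fisher-z transformed correlations, raw $d_0, d_1$ — which
keeps every 2×2 block positive semi-definite by construction and removes
the step-halving heuristics AI-REML needs near boundaries. The AI matrix
is still computed exactly at the optimum, and the reported standard
errors of all (co)variance parameters are from its inverse, so the
uncertainty quantification matches the AI-REML convention. Standard
errors of individual solutions (used for accuracies) come from the
diagonal of the inverse coefficient matrix, computed in bounded-memory
column blocks.

Two implementation details matter for speed. The coefficient matrix
pattern is emitted identically at every likelihood evaluation (kronecker
products are filled through precomputed triplet templates, never
re-symbolized), which lets CHOLMOD reuse its symbolic analysis across the
whole optimization. And because the heteroscedastic residual only
re-weights records, all design cross-products are rebuilt from cached
structures in $O(\text{nnz})$.

Accuracy of a GEBV coefficient uses the prediction error variance:
$\mathrm{Acc} = \sqrt{1 - \mathrm{SE}^2 / ((1+F)\,\sigma^2)}$, with the
radicand clamped to $[0,1]$.

## Windowed single-step GWAS

SNP effects are back-solved from the intercept and slope GEBV of the
genotyped animals, $\hat{\mathbf u} = \mathbf Z'(\mathbf Z\mathbf
Z')^{-1}\hat{\mathbf a}$ (pseudo-inverse when $\mathbf Z\mathbf Z'$ is
singular), i.e. the minimum-norm effect vector reproducing the GEBV.
Sliding windows of 5 map-adjacent SNPs (stride 1, never crossing a
chromosome boundary) are scored by the variance across genotyped animals
of the windowed genomic value, expressed as a percentage of the additive
variance of the *same* coefficient — intercept windows against
$\sigma^2_{a_0}$, slope windows against $\sigma^2_{a_1}$. Windows at or
above 0.5 % are relevant; overlapping relevant windows on a chromosome
are merged into regions (1-based inclusive coordinates).

## The simulator

`simulate_dataset()` is a gene-dropping generator whose defaults are the
package's reference study conditions, not tuned conveniences:

* overlapping-generation pedigree with a restricted sire pool (about one
  sire per four litters), Poisson litter sizes;
* founder alleles drawn at per-SNP frequencies uniform on a configurable
  range; offspring inherit one random allele per parent; on the X,
  daughters receive the sire's single X, sons only a maternal allele,
  dosage-coded {0, 2};
* true additive intercept/slope pairs by a bivariate gene-flow recursion
  with Mendelian-sampling variance scaled by parental inbreeding, so
  their covariance over the pedigree is exactly
  $\mathbf B_a \otimes \mathbf A$;
* a true per-CG gradient (standard normal, standardized), unequal CG
  sizes, and records with parity/age effects and homogeneous or
  exponentially heteroscedastic residuals;
* genotyping probability increasing quadratically with generation,
  mimicking the recency bias of real genotyping programmes.

Known simplifications: no selection (matings are random, so genetic
trend and the selection-induced covariance between gradient and merit
are absent), linkage equilibrium among founder SNPs (gene dropping
creates family-level LD only), records assigned to CGs at random (no
herd structure confounded with genetics), and the simulated trait is
continuous Gaussian. These are acceptable because the package's claims —
likelihood correctness, parameter recovery, model selection, detection
behaviour — do not depend on selection or LD structure.

## Validation strategy and problem sizes

The test suite validates each numerical component against an independent
oracle written in the most transparent possible form: recursive
coancestry for $\mathbf A$ (agreement < 1e-12), element-wise VanRaden for
$\mathbf G$ (< 1e-10), direct construction and dense inversion of
$\mathbf H$ (< 1e-8), a dense-$\mathbf V$ evaluation of the restricted
likelihood on ≤ 30-record instances (< 1e-6), and brute-force window
variances (< 1e-10). Statistical behaviour is checked by simulation:
parameter recovery within 3 reported SE of truth in ≥ 90 % of 10
replicates of about 1.6 k animals / 30 CGs under a published additive
block as truth; AIC model selection choosing the generating residual
structure in the majority of 20 replicates per scenario; and pipeline
G×E detection separating a slope-variance-positive simulation (minimum
cross-environment correlation well below 0.8) from a null one (all
correlations above 0.99).

Simulation sizes in the tests (1.5–2 k animals for recovery, 600–900 for
selection and detection) are the package's own choice, scaled so the
whole suite runs in minutes on one CPU; they are far smaller than the
tens of thousands of animals a national evaluation would use, but large
enough that the asymptotic standard errors are trustworthy, which is
what the acceptance properties rely on.

## Limitations

* Reaction norms are linear in $\theta$; curvature requires higher-order
  random regressions the package does not fit.
* The gradient is estimated from the same data the model is fitted to;
  a fully joint analysis (reaction norm + unknown covariate) is outside
  scope.
* One trait at a time; the cross-trait comparisons in the workflow are
  built from separately fitted models via weighted GEBV correlations.
* Dense $\mathbf G$ blocks make the per-iteration Cholesky cost grow
  roughly cubically in the number of genotyped animals; tens of
  thousands of genotypes would need APY-style approximations that are
  not implemented.
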