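---
title: "Sparse smooth varying-coefficient models for regional mQTL mapping"
author: "sparsevcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse smooth varying-coefficient models for regional mQTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsevcm)
```

## The model

Bisulfite sequencing summarizes methylation at CpG site $j$ of sample $i$ by
a methylated read count $Y_{ij}$ out of $X_{ij}$ total reads at genomic
position $t_{ij}$. Given dosages $Z_{ip} \in [0,2]$ at $P$ candidate SNPs,
the package fits the binomial varying-coefficient model

$$\operatorname{logit}\,\pi_{ij} \;=\; \beta_0(t_{ij}) + \sum_{p=1}^{P}
\beta_p(t_{ij})\, Z_{ip}, \qquad Y_{ij} \sim
\mathrm{Binomial}(X_{ij}, \pi_{ij}),$$

where each $\beta_p(\cdot)$ is a smooth function of genomic position
represented in a natural cubic spline basis of dimension $K$,
$\beta_p(t) = \theta_p^\top B(t)$. The scientific question is which SNPs are
regional mQTLs: only a few $\beta_p$ are expected to be nonzero, but those
that are should vary smoothly along the region. Estimation minimizes the
twice-negative binomial log-likelihood plus a composite
sparsity–smoothness penalty

$$\lambda \sum_{p=1}^{P} \sqrt{(1-\alpha)\,J_1(\beta_p) +
\alpha\,J_2(\beta_p)}, \qquad
J_1 = \int \beta_p^2, \quad J_2 \propto \int (\beta_p'')^2,$$

a generalized group lasso on whole coefficient functions: the square root
over the group quadratic form produces exact functional zeros, while
$\alpha \in [0,1)$ shifts weight between the function's size ($J_1$) and its
curvature energy ($J_2$). $\alpha = 1$ is rejected: a pure-curvature penalty
leaves constant and linear components unpenalized and the solution can be
non-unique and unbounded. The intercept function $\beta_0$ is never
penalized. In basis coordinates the two functionals are quadratic forms in
the penalty matrices $\Omega^{(1)}$ (basis Gram matrix) and $\Omega^{(2)}$
(curvature Gram matrix), so the group penalty is
$\lambda\sum_p\sqrt{\theta_p^\top H_\alpha \theta_p}$ with
$H_\alpha = (1-\alpha)\Omega^{(1)} + \alpha\Omega^{(2)}$.

Two special cases are first-class citizens because they are the standard
comparators: `ssp0` sets $\alpha = 0$ (sparsity only, no curvature control),
and `glasso` replaces $H_\alpha$ by the identity, which is an ordinary group
LASSO on the raw basis coefficients.

## Basis and penalty construction

Positions are mapped affinely to $[0,1]$ and $K$ knots are placed at equally
spaced quantiles of the distinct rescaled positions (first and last at the
region boundaries). Quantile placement is robust to the irregular CpG
spacing of real regions. The basis is the cardinal natural-spline basis
($b_k$ interpolates the indicator of knot $k$), which spans all linear
functions and is linear beyond the boundary knots. Both penalty matrices are
computed by per-interval Gauss–Legendre quadrature that is *exact* for the
piecewise-polynomial integrands (degree 6 for $\Omega^{(1)}$, degree 2 for
$\Omega^{(2)}$); adding nodes changes nothing beyond rounding, and the unit
tests verify both against dense trapezoid-rule oracles.

**Scaling of the curvature penalty.** The curvature functional carries the
conventional factor $M^2$ ($M = \sum_i m_i$, the total record count) so that
$J_1$ and $J_2$ are comparable and one $\alpha$ grid serves all datasets.
That calibration presumes the integrals are taken in base-pair units. On
the rescaled axis the bp-unit curvature integral equals
$W^{-3}\int_0^1 f''(u)^2\,du$ for a region of width $W$ bp, so the package
computes $\Omega^{(2)}$ with the scale $(M/W^2)^2$ applied to the unit-axis
curvature Gram matrix, and $\Omega^{(1)}$ as the unit-axis basis Gram. This
equals the bp-unit construction with one global factor $1/W$ applied to both
functionals — absorbed into $\lambda$, hence invisible to the fit — and
keeps the $J_2/J_1$ ratio, and therefore the meaning of the $\alpha$ grid,
identical to the bp-unit convention while standardizing magnitudes across
regions of different widths. Computing the curvature Gram directly on the
unit axis *without* this correction inflates $J_2/J_1$ by roughly $W^4$,
which silently turns every positive $\alpha$ into a near-total smoothness
constraint; we verified this degeneracy empirically before fixing the scale.

```{r basis-example}
pos <- sort(unique(round(cumsum(c(10000, 1 + rpois(122, 9))))))
basis <- build_basis(pos, K = 10)
mats <- penalty_matrices(basis, M = 50 * length(pos))
round(range(eigen(mats$omega1)$values), 4)
```

## Optimization

With the Cholesky factor $H_\alpha = L^\top L$ and $\eta_p = L\theta_p$, the
penalty becomes the plain group norm $\lambda\sum_p\|\eta_p\|_2$ and the
problem is solved by proximal gradient descent: a gradient step on the
likelihood followed by group-wise soft thresholding
$\eta_p \mapsto (1 - t\lambda/\|\eta_p\|_2)_+\,\eta_p$, iterated until the
relative change of the penalized objective falls below `tol` (default
`1e-8`, cap 5000 iterations). Step sizes come from a backtracking line
search with the standard generalized-gradient majorization condition and
shrink factor $\delta = 0.5$ from `t_init = 1`. By default the accepted step
is carried to the next iteration with a single growth attempt rather than
restarting at `t_init`: at binomial-count curvature the accepted step is
orders of magnitude below 1, and restarting costs roughly twenty extra
objective evaluations per iteration for identical iterates (we verified
equal objectives both ways; `solver_config(reset_step = TRUE)` restores the
restarting rule). The line-search condition guarantees monotone descent
either way, which the tests assert on every fit.

The inner loop is compiled (RcppArmadillo) and exploits the Kronecker-like
structure of the design — basis rows times genotype columns — so one
iteration costs $O(MK + NPK)$ rather than $O(MPK)$.

Groups whose design block is identically zero (monomorphic SNPs) are held at
exactly zero; probabilities are clipped at $10^{-10}$ inside the likelihood
so objectives stay finite during line search; if the Cholesky factorization
of an ill-conditioned $H_\alpha$ (possible as $\alpha \to 1$) fails, a
jitter of $10^{-10}\,\mathrm{tr}(H)/K$ is added once.

## Regularization path and tuning

For fixed $\alpha$ the path anchor is the analytic
$\lambda_{\max} = \max_p \sqrt{b_p^\top H_\alpha^{-1} b_p}$ from the KKT
conditions at the intercept-only fit ($b_p$ the block-$p$ score). The path
takes `L = 100` log-spaced values down to $\tau\lambda_{\max}$
($\tau = 0.01$ when $M < (P+1)K$, else $0.001$), each fit warm-started at
the previous solution. The first path point is the intercept-only fit
itself: at $\lambda_{\max}$ it satisfies the KKT conditions with every
penalized group exactly zero, so it is recorded directly instead of
resolving a boundary case numerically.

Tuning uses K-fold cross-validation (default 5) of the mean validation
deviance. Folds split *individuals*, not records: records within a sample
share the genotype and are dependent, so record-level splits would leak.
The lambda path is the full-data path, reused across folds so grid points
are comparable; the SE of the CV error is the across-fold standard
deviation of per-fold mean deviances divided by $\sqrt{n_{folds}}$ (the SE
estimator is not prescribed by the method, this is the package's
definition). The `min` rule takes the global minimizer over the
$(\lambda,\alpha)$ grid; the `one_se` rule stays at the minimizing $\alpha$
and takes the largest $\lambda$ within one SE of the minimum, trading a
little error for parsimony. A SNP that becomes monomorphic inside a
training fold is unselectable in that fold and logged.

**Adaptive penalty.** From an initial ordinary fit, per-covariate weights
$w_{1p} = J_1(\hat\beta_p)^{-1/2}$ and $w_{2p} = J_2(\hat\beta_p)^{-1/2}$
rescale the penalty per group,
$H_p = w_{1p}(1-\alpha)\Omega^{(1)} + w_{2p}\alpha\Omega^{(2)}$; covariates
with a zero initial estimate get infinite weights and are excluded, and the
whole pipeline (group-specific $\lambda_{\max}$ metric included) is rerun.
A near-linear initial estimate has $J_2 \approx 0$; its smoothness weight is
capped at $(10^{-8}J_1)^{-1/2}$ so $H_p$ stays positive definite without
excluding genuinely linear effects. For regional mapping the recommended
mode is the adaptive fit tuned under the 1-SE rule.

## The simulation generator

`generate_scenario()` emulates the benchmark design this class of methods is
evaluated on: a region of 123 CpG sites with irregular spacing (unit gaps
plus Poisson(9) jitter, drawn once per region seed), genotypes from
thresholded latent-Gaussian haplotypes with block-diagonal exchangeable
correlation $\rho$ in blocks of 20 SNPs (dosage = sum of two independent
haplotypes; minor allele frequency 0.3 by default), causal SNPs co-located
in one block when $\rho > 0$, read depths from a zero-truncated
Poisson(30), and counts drawn from the assumed binomial model. The exact
effect curves and read-depth model of the original benchmark are not
public; the package defines a closed-form shape library
(constant, linear, centered parabola, two-bump Gaussian mixture, and a
piecewise-constant "nonsmooth" shape with interior jumps) at peak magnitude
`effect_scale = 1.2` on the logit scale, with alternating signs across the
causal set, and an intercept $\beta_0(u) = 0.3 + 0.8\sin(2\pi u)$. These
are this package's own stand-ins chosen to match the benchmark's verbal
description — smooth shapes of varied type spanning the region for the
smooth example, sharp transitions for the nonsmooth one — so quantitative
comparisons against the published tables are meaningful only as orderings
and coarse magnitudes, and are tested as such.

What passing the simulation-based tests does *not* show about real data:
the generator has no realistic LD beyond exchangeable blocks, no
beta-binomial overdispersion, no missing CpGs or sample-specific site sets,
no bisulfite-conversion error, and genotypes are hard calls. The model
itself accepts irregular, sample-specific records; the basis is built from
the union of observed positions across samples.

## Replicated evaluation

`run_simulation_study()` fits the variants on `R` replicate regions sharing
one CpG grid and truth (fresh genotypes and counts per run) and aggregates
the standard measures: integrated squared bias, variance and MSE summed
over the observed positions (the bias/variance decomposition is exact and
asserted to machine precision), true/false positive counts, and held-out
prediction measures (deviance error relative to the truth, RMSE on the
arcsine scale $h(\pi) = \arcsin(2\pi - 1)$, and predicted-versus-observed
correlations on both scales) computed on an independently simulated region
of the same size.

The packaged study (acceptance script and stochastic tests) uses $N = 50$,
$P = 100$, 5 causal SNPs, $\rho = 0$, $R = 8$ replicates, a 30-value lambda
path, the $\alpha$ grid $\{0, 0.5, 0.99\}$, 5-fold CV, and solver tolerance
$10^{-6}$ for the cross-validated fits. Eight replicates are sufficient
here because every comparison under test (SSP versus SSP0/gLASSO, adaptive
versus ordinary, 1-SE versus min) is paired within runs, which removes most
Monte-Carlo variation from the contrasts; the basis-robustness check
repeats the three ordinary variants at $K = 30$ on the same replicate
seeds.

## Defaults that matter

| parameter | default | meaning |
|---|---|---|
| `K` | 10 (intercept always 10; SNPs `min(10, n_cpgs/10)`, floor 4) | basis dimension; the floor is the natural-cubic minimum |
| `alpha_grid` | $0, 0.1, \ldots, 0.9, 0.95, 0.99$ | smoothness mixing candidates |
| `L`, `tau` | 100, 0.01 or 0.001 | lambda path resolution and depth |
| `n_folds` | 5 | CV folds, split by individual |
| `tol`, `max_iter` | $10^{-8}$, 5000 | solver convergence (relative objective change) |
| `t_init`, `shrink` | 1, 0.5 | line-search start and shrink factor |
| `maf`, `depth_mean` | 0.3, 30 | generator allele frequency and mean read depth |
| `r2_threshold` | 0.2 | LD-pruning threshold for regional scans |

A caveat on the group-LASSO comparator: penalizing the raw basis
coefficients through the identity matrix is not basis-invariant. In the
cardinal natural-spline basis used here the coefficients *are* function
values at the knots, so the identity group norm is close to a discretized
function norm and the comparator behaves like a well-conditioned
sparsity-only penalty; under other natural-spline parameterizations the
same "identity" penalty induces a different shrinkage geometry and can
perform much worse. Fitted functions $\beta_p(t)$ are basis-invariant and
are what all estimation metrics and oracles compare; only the identity-
penalty comparator itself inherits this basis dependence.

## Known limitations

Binomial (no overdispersion) likelihood; spline bases are a poor match for
spiky, discontinuous effects — on the nonsmooth example all variants are
biased and the smoothness term buys little, consistent with the benchmark's
own report; no measurement-error model for incomplete bisulfite conversion;
no momentum/FISTA acceleration (plain proximal gradient with backtracking
was fast enough at the intended problem sizes); inference (standard errors,
selection-adjusted p-values) is out of scope.
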