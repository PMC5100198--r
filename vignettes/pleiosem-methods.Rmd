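---
title: "Sparse structural equation models for genotype-phenotype networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse structural equation models for genotype-phenotype networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiosem)
```

## The model

`pleiosem` jointly infers a causal network among quantitative phenotypes and
the genetic architecture feeding into it. With $n$ samples, $M$ phenotypes
$Y = [y_1, \dots, y_M]$ (endogenous) and $K$ exogenous columns
$X = [x_1, \dots, x_K]$ (coded genotypes or, in the gene-based variant,
functional principal component scores), the linear structural system is

$$ Y \Gamma + X B + E = 0, $$

with the diagonal of $\Gamma$ normalized to $-1$, so equation $i$ reads
$y_i = Y_{-i}\gamma_{-i} + X B_i + e_i = W_i \Delta_i + e_i$ with
$W_i = [Y_{-i}\; X]$. Off-diagonal $\Gamma_{ji}$ is the path coefficient of
the phenotype edge $j \to i$; $B_{ki}$ is the direct genetic effect of
column $k$ on phenotype $i$. Errors are homoscedastic within an equation and
uncorrelated with $X$.

Ordinary least squares on such an equation is inconsistent because $Y_{-i}$
is endogenous. The estimator is therefore the instrumented (generalized
least squares / two-stage least squares) criterion

$$ f(\Delta_i) = (X^\top y_i - X^\top W_i \Delta_i)^\top (X^\top X)^{-1}
   (X^\top y_i - X^\top W_i \Delta_i), $$

penalized with $\lambda \lVert \Delta_i \rVert_1$ to make the network sparse
and the per-equation problem identifiable. Each equation is solved
independently.

### The ADMM solver

With $A = X^\top W_i$, $M = (X^\top X)^{-1}$, $b = X^\top y_i$, the
objective is the quadratic $f(\Delta) = (b - A\Delta)^\top M (b - A\Delta)$
plus the L1 term. The solver is a scaled-form ADMM: the quadratic update
solves $(A^\top M A + \rho I)\,\Delta = A^\top M b + \rho(z - u)$ through a
Cholesky factor computed once per equation (and reused across the whole
cross-validation grid); the $z$ update soft-thresholds at $\lambda/(2\rho)$
(the objective carries leading coefficient 1, not $1/2$); the returned
solution is $z$, whose zeros are exact. Stopping uses the standard primal
and dual residual criteria with `tol_abs = 1e-6`, `tol_rel = 1e-4` and
`max_iter = 2000`; a non-converged run returns the best iterate with a
warning.

The default $\rho$ is matched to the problem scale,
$\rho = \operatorname{mean}(\operatorname{diag}(A^\top M A))$, rather than a
fixed constant: the quadratic's eigenvalues grow linearly in $n$, and a
fixed $\rho$ makes the iteration count grow with the sample size for no
statistical benefit. A fixed value can still be set via
`admm_control(rho = )`. Against a coordinate-descent lasso solver on the
Cholesky-reformulated problem ($ (X^\top X)^{-1} = LL^\top $, standard
lasso on $(L^\top A,\, L^\top b)$), the ADMM objective agrees to $10^{-6}$
on random instances; the test suite asserts this.

$(X^\top X)^{-1}$ is computed by eigendecomposition with an eigenvalue floor
of $10^{-10}\,\mathrm{trace}(X^\top X)$, and an optional ridge supports
$K \gtrsim n$ settings. All columns of $Y$ and $X$ are mean-centered before
fitting (the system has no intercept); columns are not rescaled to unit
variance by default (`standardize`-style rescaling would change the L1
geometry between phenotype and genotype blocks, and the coefficient
distributions in the simulation design are specified on the raw scale).

### Identifiability and what the penalty does

A structural point that matters for interpreting fits: $X^\top W_i$ has rank
at most $K$, while $\Delta_i$ has $M - 1 + K$ entries, so the unpenalized
criterion is always rank-deficient for $M > 1$. In particular a phenotype
column and its reduced-form representation through the instruments
($y_j = X \Pi_j + \text{noise}$) are observationally equivalent to the
criterion, and the L1 penalty is the only arbiter between them. This is why
the unpenalized `gls_estimate` refuses singular systems (advising a ridge or
the gene-based dimension reduction), why hypothesis tests are computed on
restricted refits (below), and why recovered networks should be read with
the false-discovery behaviour from the simulation harness in mind.

### Penalty selection

`cross_validate_lambda` performs per-equation k-fold (default 5) CV, scoring
each candidate by the mean held-out instrumented criterion evaluated with
the held-out fold's own $(X^\top X)^{-1}$, and selects the minimizer. Fold
assignment is deterministic given `seed`. The default grid is 10
log-spaced fractions of the per-equation zero-solution threshold
$\lambda_{\max} = 2\lVert A^\top M b\rVert_\infty$ down to
$10^{-2}\lambda_{\max}$ — the floor follows lasso practice for
underdetermined problems, which these always are (previous section). Users
should know this criterion is conservative about shrinkage bias: with
strong signal it tends to select near the bottom of the grid, so the fitted
support errs on the inclusive side; the stability-selection and
path-coefficient-test filters are the intended pruning tools.

## Gene-based functional variant

Sequencing data bring many rare variants whose single-SNP columns carry
little information. The gene-based variant treats the coded genotypes of a
gene's SNPs as discrete observations of a genotype function of genomic
position. Coding is frequency-weighted:
$QQ \to 2P_q$, $Qq \to P_q - P_Q$, $qq \to -2P_Q$, which has mean zero
under Hardy-Weinberg equilibrium. Positions are affinely rescaled to
$[0, 1]$ and a discretized Karhunen-Loève decomposition — PCA of the
centered profile matrix under trapezoid quadrature weights — yields
orthonormal eigenfunctions $\phi_{jl}(t)$ and per-sample scores
$\eta_{ijl}$. No spline smoothing is applied: SNP grids are sparse and
irregular, and the discretized decomposition keeps the score geometry exact
(orthonormality and score decorrelation hold to machine precision, which
the tests assert).

Components are retained until a `var_target` fraction (default 0.8, a
conventional figure in FPCA association work; configurable) of profile
variance is explained; components below $10^{-10}$ of the leading
eigenvalue are always dropped. The score blocks of all genes are
concatenated into $\eta$, and the solver runs unchanged with $X$ replaced
by $\eta$. The fitted block $b_{ji}$ reconstructs the genetic effect
function $\beta_{ji}(t) = \sum_g b_{jig}\phi_{jg}(t)$.

For genome-scale runs, `screen_and_refit` implements the two-stage
strategy: genes are grouped (pathways if provided, otherwise chunks of at
most 100 genes), a functional SEM is fitted per group, genes with any
gene-level path test $p <$ `alpha1` (default 0.05, unadjusted — the screen
is a filter, not an inference) are pooled, and a final model is refitted on
the union.

## Tests, multiplicity, stability

Path-coefficient inference uses the classical two-stage least squares
covariance $\widehat\Sigma_i = \sigma_{ii}[W_i^\top \eta (\eta^\top
\eta)^{-1} \eta^\top W_i]^{-1}$ with $\sigma_{ii} = \lVert y_i - W_i
\widehat\Delta_i\rVert^2 / n$, which presumes no shrinkage. The package
therefore refits the selected support without penalty before testing; a
tested column or gene block is added to the conditioning set if the penalty
had removed it. When a very small penalty leaves a support larger than the
instrument rank, the smallest-magnitude support coefficients are dropped
from the conditioning set so the restricted system stays well-posed (the
tested block is never dropped). The gene test $T_g = \widehat b_{ji}^\top
\Lambda_i^{-1} \widehat b_{ji}$ is referred to $\chi^2(G)$; the
single-coefficient test $T_c = \widehat\Delta_{il}^2 /
\widehat{\mathrm{var}}$ to $\chi^2(1)$. Under null simulations both are
calibrated at $\alpha = 0.05$ within Monte Carlo error (asserted over 1000
replicates in the test suite).

Bonferroni and Benjamini-Hochberg adjustments are available. Stability
selection refits the model on resampled data (bootstrap of size $n$ by
default; half-sample subsampling available — the resampling scheme is a
documented choice, as "resampling" alone underdetermines it) 100 times and
keeps an edge when its full-data $p < 0.05$ and its selection frequency is
at least 0.8.

## Effect decomposition

On the fitted directed network, the direct effect of $X$ on $Y$ is the
$X \to Y$ edge coefficient; the indirect effect is the sum over directed
simple paths of length $\ge 2$ of the products of path coefficients; the
total effect is their sum, and equals the derivative of
$E[Y \mid do(X = x)]$ in the linear-Gaussian model. The package computes
totals two ways — path enumeration (igraph simple paths) and the
intervention regression of the outcome on the source plus its parents — and
the test suite asserts their agreement on data simulated from known DAGs,
plus the closed-form check against the Neumann series
$(I - A)^{-1} - I$ of the phenotype coefficient matrix. Sources without
parents (SNPs, genes) reduce to the simple-regression marginal effect,
which is also reported separately.

Fitted networks can contain two-directional phenotype edges (a known
limitation of per-equation sparse SEMs). Effects along cyclic routes are
refused and flagged per pair rather than guessed; `effect_table` marks such
pairs in a `cyclic` column. Report rounding is 4 decimals.

## Simulation harness

`sim_network`, `sim_genotypes`, `sim_phenotypes` and `power_experiment`
reproduce the evaluation design: a random-topological-order DAG with edge
probability $d/(M-1)$ (expected total degree $d = 3$); nonzero
$\Gamma_{ji}$ uniform on $(0.5, 1) \cup (-1, -0.5)$; genotype effects
uniform on $(0, 1) \cup (-1, 0)$ with, by default, three causal variants
per phenotype; HWE genotypes with MAF uniform on $(0.05, 0.5)$ for common
variants and on $(0.005, 0.01)$ for rare ones (the rare band is a package
choice — no threshold is standard — set so the expected minor-allele count
at $n = 3000$ stays estimable; both bands are arguments); phenotypes from
$Y = -(XB + \varepsilon)\Gamma^{-1}$ with
$\varepsilon \sim N(0, 0.01 I)$. Monomorphic draws are resampled so every
SNP is polymorphic. Genotypes are synthetic HWE draws rather than resampled
exomes, so linkage disequilibrium between SNPs is weaker than in real
sequencing data; gene-level FPC compression is correspondingly easier, and
passing recovery rates here do not certify recovery under strong LD or
population structure.

Power of detection is the fraction of true edges recovered and FDR the
fraction of detected edges that are false (detected = nonzero in the CV-λ
fit; gene-based runs are scored on gene-level edges). PD uses the true-edge
denominator and FDR the detected-edge denominator — the standard recall /
false-discovery pairing (variants of these definitions that share one
denominator would force the two to sum to one and are not used).

Problem sizes used in the shipped checks — 10 phenotypes × 10 genes × 10
rare SNPs at $n = 3200$ and 30 phenotypes × 100 rare SNPs at $n = 3000$,
20 replicates each — are the package's scaled-down reference experiments;
`power_experiment` accepts larger designs unchanged.

## Known limitations

* Per-equation penalized 2SLS cannot distinguish a phenotype edge from its
  reduced-form SNP proxy (rank deficiency above); in dense small networks
  with moderate genetic effects the support includes such proxies, so the
  raw-support FDR can be substantial even at large $n$ — mirroring the high
  rare-variant FDR the method family is known for. Stability selection and
  the path tests are the mitigation, not a cure.
* Acyclicity is not enforced; two-directional edges are reported, and
  effect decomposition refuses cyclic routes.
* Missing genotype calls are mean-imputed (exactly 0 under the coding);
  no genotype imputation beyond that, no multiallelic sites, no phasing.
* The covariance formula used for tests assumes the FSEM instrument; for
  SNP-based fits the same formula is applied with $X$ in place of $\eta$,
  consistent with the two solvers being the same algorithm under that
  substitution.
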