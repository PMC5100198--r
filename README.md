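# pleiosem

Joint inference of genetic architecture and causal phenotype networks from
multi-phenotype genotype data, for statistical geneticists analyzing
pleiotropy with GWAS or sequencing data.

Standard multi-trait association methods regress each phenotype on genotype
and stop there: they cannot say which phenotypes drive which, nor whether a
genetic effect is direct or mediated by another trait. `pleiosem` models the
phenotypes and genotypes as one linear structural system

```
Y Γ + X B + E = 0,        diag(Γ) = −1,
```

where `Y` (n × M) holds the phenotypes (endogenous), `X` (n × K) the coded
genotypes or per-gene functional principal component (FPC) scores
(exogenous), off-diagonal `Γ[j, i]` is the path coefficient of the
phenotype edge j → i and `B[k, i]` the direct genetic effect of column k on
phenotype i. Each equation `y_i = W_i Δ_i + e_i` with `W_i = [Y_−i X]` is
estimated by L1-penalized two-stage least squares,

```
min_Δ  (X'y_i − X'W_i Δ)' (X'X)⁻¹ (X'y_i − X'W_i Δ)  +  λ‖Δ‖₁ ,
```

solved by ADMM with exact-zero supports, λ chosen per equation by 5-fold
cross-validation. On top of the fit the package provides:

* **Gene-based functional modeling** for rare variants: per-gene genotype
  profiles over genomic position are compressed by functional PCA
  (discretized Karhunen–Loève with trapezoid weights) and the same solver
  runs on the score matrix η; a two-stage genome screen
  (`screen_and_refit`) scales it up.
* **Path-coefficient tests**: gene-level `T_g = b' Λ⁻¹ b ~ χ²(G)` and
  single-coefficient `T_c ~ χ²(1)` on unpenalized post-selection refits,
  with Bonferroni/BH adjustment and stability selection (100 resamples,
  p < 0.05, frequency ≥ 0.8).
* **Effect decomposition**: direct (edge coefficient), indirect (sum of
  path products over mediating routes), total (their sum, equal to the
  do-intervention regression coefficient) and marginal (simple-regression)
  effects per causal–outcome pair.
* **A simulation harness** reproducing the method's evaluation design
  (random expected-degree-3 phenotype DAGs, path coefficients uniform on
  (0.5, 1)/(−1, −0.5), genetic effects on (0, 1)/(−1, 0), HWE genotypes at
  common/rare MAF, noise N(0, 0.01·I)), scoring recovered networks by power
  of detection (PD) and false discovery rate (FDR).

## Worked example

Simulate a 4-phenotype, 12-SNP system and refit it:

```r
library(pleiosem)
set.seed(11)
dat <- sim_dataset(n = 600, M = 4, n_snps = 12, maf_regime = "common",
                   expected_degree = 2)
fit <- fit_s2sem(dat$Y, dat$X, seed = 11)   # CV-selected lambda
fit
#> <sem_fit> 4 phenotypes, 12 exogenous columns, n = 600
#>   edges: 4 phenotype -> phenotype, 20 genotype -> phenotype
#>   lambda in [2.75, 4.94]

tests <- test_all_paths(fit)
net <- network_edges(fit, tests)
dplyr::arrange(net, p_value)
#> # A tibble: 24 × 5
#>   from  to    type      coefficient p_value
#> 1 P3    P4    phenotype       0.582       0
#> 2 snp1  P1    genotype        1.03        0
#> 3 snp7  P1    genotype        0.792       0
#> ...

evaluate_edges(dat$edges, net)
#> # A tibble: 1 × 6
#>      pd   fdr n_true_detected n_false_detected n_detected n_true_total
#> 1 0.812 0.458              13               11         24           16
```

The fit recovers 13 of the 16 planted edges (PD 0.81); as is typical for
CV-min lasso supports in this model class, it also carries false edges
(FDR 0.46 here) — prune with `stability_selection()` and the p-values, and
read the methods vignette (`vignettes/pleiosem-methods.Rmd`) on why a
phenotype edge and its SNP proxy can be observationally equivalent to this
estimator. `effect_table(net)` then decomposes every connected pair into
direct/indirect/total (and marginal, when data are supplied) effects, e.g.
`snp1 → P1: direct 1.03, indirect 0, total 1.03`.

Gene-based rare-variant analysis differs only in the design step:

```r
eta <- build_fsem_design(X_coded, var_target = 0.8)  # FPC scores per gene
fit <- fit_fsem(Y, eta)
test_gene(fit, "GENE1", "BMI")
```

A thin CLI over the same functions lives at `inst/cli/pleiosem.R`
(subcommands `fit`, `effects`, `simulate`, `screen`).

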