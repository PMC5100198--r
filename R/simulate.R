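# Synthetic genotype-phenotype network generator and the power-of-detection /
# false-discovery-rate evaluation harness.
#
# Study conditions emulated: a random acyclic phenotype network with expected
# total degree 3 per node; nonzero phenotype path coefficients drawn
# uniformly from (0.5, 1) or (-1, -0.5); genotype-to-phenotype coefficients
# from (0, 1) or (-1, 0); Hardy-Weinberg genotypes at common or rare minor
# allele frequencies; phenotypes generated from Y = -(XB + eps) Gamma^-1 with
# eps ~ N(0, 0.01 I).

#' Draw a random genotype-phenotype network
#'
#' The phenotype sub-network is a DAG sampled by drawing a random topological
#' order and including each forward edge independently with probability
#' `expected_degree / (M - 1)`, which makes the expected total degree per
#' node equal `expected_degree`. Nonzero `Gamma[j, i]` (edge j -> i) are
#' uniform on (0.5, 1) or (-1, -0.5) with equal probability. Genotype
#' effects: under `qtl_scheme = "pleiotropic"` each phenotype is affected by
#' `n_qtl` distinct exogenous columns chosen at random; `"one_to_one"`
#' assigns SNP k to phenotype k (requires `K >= M`). Nonzero `B[k, i]` are
#' uniform on (0, 1) or (-1, 0).
#'
#' @param M number of phenotypes.
#' @param K number of exogenous columns (SNPs).
#' @param expected_degree expected total (in + out) phenotype degree.
#' @param n_qtl number of causal SNPs per phenotype.
#' @param qtl_scheme `"pleiotropic"` or `"one_to_one"`.
#' @param phen_names,snp_names optional node labels.
#' @return list with `Gamma` (M x M, diagonal -1), `B` (K x M), and `edges`,
#'   a tibble of the true directed edges (`from`, `to`, `type`,
#'   `coefficient`).
#' @export
sim_network <- function(M, K, expected_degree = 3, n_qtl = 3,
                        qtl_scheme = c("pleiotropic", "one_to_one"),
                        phen_names = NULL, snp_names = NULL) {
  qtl_scheme <- match.arg(qtl_scheme)
  stopifnot(M >= 1, K >= 1, expected_degree >= 0)
  if (M > 1) stopifnot(expected_degree < M)
  phen_names <- phen_names %||% paste0("P", seq_len(M))
  snp_names <- snp_names %||% paste0("snp", seq_len(K))
  Gamma <- matrix(0, M, M, dimnames = list(phen_names, phen_names))
  diag(Gamma) <- -1
  if (M > 1 && expected_degree > 0) {
    ord <- sample(M)  # ord[j] = topological rank of node j
    p_edge <- expected_degree / (M - 1)
    for (j in seq_len(M)) {
      for (i in seq_len(M)) {
        if (ord[j] < ord[i] && stats::runif(1) < p_edge) {
          Gamma[j, i] <- runif_signed(1, 0.5, 1)
        }
      }
    }
  }
  B <- matrix(0, K, M, dimnames = list(snp_names, phen_names))
  if (n_qtl > 0) {
    if (qtl_scheme == "one_to_one") {
      stopifnot(K >= M)
      for (i in seq_len(M)) B[i, i] <- runif_signed(1, 0, 1)
    } else {
      for (i in seq_len(M)) {
        picks <- sample.int(K, min(n_qtl, K))
        B[picks, i] <- runif_signed(length(picks), 0, 1)
      }
    }
  }
  list(Gamma = Gamma, B = B, edges = network_true_edges(Gamma, B))
}

runif_signed <- function(n, lo, hi) {
  mag <- stats::runif(n, lo, hi)
  mag * ifelse(stats::runif(n) < 0.5, 1, -1)
}

network_true_edges <- function(Gamma, B) {
  M <- ncol(Gamma)
  phen <- colnames(Gamma)
  snps <- rownames(B)
  gidx <- which(Gamma != 0 & !diag(TRUE, M), arr.ind = TRUE)
  bidx <- which(B != 0, arr.ind = TRUE)
  dplyr::bind_rows(
    tibble::tibble(from = phen[gidx[, 1]], to = phen[gidx[, 2]],
                   type = "phenotype", coefficient = Gamma[gidx]),
    tibble::tibble(from = snps[bidx[, 1]], to = phen[bidx[, 2]],
                   type = "genotype", coefficient = B[bidx]))
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Minor allele frequencies are drawn uniformly from `common_band`
#' (default (0.05, 0.5)) or `rare_band` (default (0.005, 0.01)); the
#' `"mixed"` regime uses half of each. Genotype calls are binomial draws of
#' the minor allele under HWE; columns that come out monomorphic are redrawn
#' so every SNP is polymorphic in the sample. The minor allele is `q` (the
#' alternate allele) and calls are coded with [encode_genotypes()] using the
#' generating frequencies. SNPs are laid out on consecutive per-gene
#' intervals with sorted uniform positions when `n_genes` is given.
#'
#' @param n sample size.
#' @param n_snps total number of SNPs (ignored when `n_genes` is given).
#' @param maf_regime `"common"`, `"rare"`, or `"mixed"`.
#' @param n_genes,snps_per_gene optional gene layout for gene-based runs.
#' @param common_band,rare_band MAF bands.
#' @return a [genotype_data] of coded genotypes with SNP metadata (including
#'   `gene` when a gene layout was requested).
#' @export
sim_genotypes <- function(n, n_snps = 100,
                          maf_regime = c("common", "rare", "mixed"),
                          n_genes = NULL, snps_per_gene = 10,
                          common_band = c(0.05, 0.5),
                          rare_band = c(0.005, 0.01)) {
  maf_regime <- match.arg(maf_regime)
  if (!is.null(n_genes)) n_snps <- n_genes * snps_per_gene
  maf <- switch(maf_regime,
    common = stats::runif(n_snps, common_band[1], common_band[2]),
    rare = stats::runif(n_snps, rare_band[1], rare_band[2]),
    mixed = {
      half <- n_snps %/% 2
      c(stats::runif(half, common_band[1], common_band[2]),
        stats::runif(n_snps - half, rare_band[1], rare_band[2]))
    })
  calls <- matrix(NA_character_, n, n_snps)
  for (j in seq_len(n_snps)) {
    repeat {
      g <- stats::rbinom(n, 2, maf[j])
      if (length(unique(g)) > 1) break
    }
    calls[, j] <- c("QQ", "Qq", "qq")[g + 1]
  }
  gene <- if (!is.null(n_genes)) {
    rep(paste0("G", seq_len(n_genes)), each = snps_per_gene)
  } else NA_character_
  position <- if (!is.null(n_genes)) {
    span <- 10000L
    unlist(lapply(seq_len(n_genes), function(g) {
      start <- (g - 1L) * 2L * span
      sort(sample.int(span, snps_per_gene)) + start
    }))
  } else seq_len(n_snps) * 1000L
  freqs <- tibble::tibble(
    id = paste0("snp", seq_len(n_snps)), position = position,
    freq_Q = 1 - maf, freq_q = maf, gene = gene)
  encode_genotypes(calls, freqs)
}

#' Generate phenotypes from a structural system
#'
#' Solves the structural equations for the endogenous block:
#' `Y = -(X B + eps) Gamma^-1` with `eps ~ N(0, noise_sd^2 I)`, so the drawn
#' data satisfy `Y Gamma + X B + eps = 0` exactly.
#'
#' @param Gamma M x M phenotype coefficient matrix (diagonal -1, acyclic
#'   off-diagonal).
#' @param B K x M exogenous coefficient matrix.
#' @param X coded genotypes (matrix or [genotype_data]).
#' @param noise_sd residual standard deviation (default 0.1, variance 0.01).
#' @return list with the phenotype matrix `Y` (columns named as `Gamma`) and
#'   the drawn noise `eps`.
#' @export
sim_phenotypes <- function(Gamma, B, X, noise_sd = 0.1) {
  Xv <- exogenous_values(X)
  n <- nrow(Xv)
  M <- ncol(Gamma)
  eps <- matrix(stats::rnorm(n * M, sd = noise_sd), n, M)
  Ginv <- tryCatch(solve(Gamma), error = function(e) {
    stop("Gamma is singular; the phenotype network must be acyclic with ",
         "diagonal -1", call. = FALSE)
  })
  Y <- -(Xv %*% B + eps) %*% Ginv
  colnames(Y) <- colnames(Gamma)
  rownames(Y) <- rownames(Xv)
  list(Y = Y, eps = eps)
}

#' Draw one complete synthetic dataset
#'
#' Convenience wrapper: draws a network, genotypes and phenotypes under the
#' emulated study conditions.
#'
#' @inheritParams sim_network
#' @inheritParams sim_genotypes
#' @inheritParams sim_phenotypes
#' @return list with `Y`, `X` ([genotype_data]), `Gamma`, `B`, `edges`
#'   (true edge tibble), and `gene_edges` (true edges collapsed to gene
#'   level) when a gene layout was used.
#' @export
sim_dataset <- function(n, M = 10, n_snps = 100, maf_regime = "common",
                        n_genes = NULL, snps_per_gene = 10,
                        expected_degree = 3, n_qtl = 3,
                        qtl_scheme = "pleiotropic", noise_sd = 0.1,
                        common_band = c(0.05, 0.5),
                        rare_band = c(0.005, 0.01)) {
  X <- sim_genotypes(n, n_snps = n_snps, maf_regime = maf_regime,
                     n_genes = n_genes, snps_per_gene = snps_per_gene,
                     common_band = common_band, rare_band = rare_band)
  net <- sim_network(M, ncol(X$values), expected_degree = expected_degree,
                     n_qtl = n_qtl, qtl_scheme = qtl_scheme,
                     snp_names = X$columns$id)
  ph <- sim_phenotypes(net$Gamma, net$B, X, noise_sd = noise_sd)
  gene_edges <- if (!is.null(n_genes)) {
    collapse_edges_to_genes(net$edges, X$columns)
  } else NULL
  list(Y = ph$Y, X = X, Gamma = net$Gamma, B = net$B,
       edges = net$edges, gene_edges = gene_edges)
}

# Collapse SNP-level true edges to gene-level edges using SNP metadata.
collapse_edges_to_genes <- function(edges, snp_columns) {
  map <- stats::setNames(snp_columns$gene, snp_columns$id)
  edges |>
    dplyr::mutate(from = ifelse(.data$type == "genotype",
                                unname(map[.data$from]), .data$from)) |>
    dplyr::distinct(.data$from, .data$to, .data$type)
}

#' Compare detected and true edge sets
#'
#' Power of detection is the fraction of true edges recovered
#' (`n_true_detected / n_true_total`); the false discovery rate is the
#' fraction of detected edges that are not true
#' (`n_false_detected / n_detected`, 0 when nothing is detected). Edges are
#' matched on (`from`, `to`); direction matters.
#'
#' @param true,detected data frames with columns `from` and `to`.
#' @return one-row tibble with `pd`, `fdr` and the underlying counts.
#' @export
evaluate_edges <- function(true, detected) {
  tk <- edge_keys(true)
  dk <- edge_keys(detected)
  n_true_detected <- sum(dk %in% tk)
  n_false <- sum(!(dk %in% tk))
  tibble::tibble(
    pd = if (length(tk) > 0) n_true_detected / length(tk) else 0,
    fdr = if (length(dk) > 0) n_false / length(dk) else 0,
    n_true_detected = n_true_detected, n_false_detected = n_false,
    n_detected = length(dk), n_true_total = length(tk))
}

edge_keys <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0) return(character(0))
  unique(paste(edges$from, edges$to, sep = "\r"))
}

#' Replicated network-recovery experiment
#'
#' For each replicate: draw a network, genotypes and phenotypes; select the
#' penalty by k-fold cross-validation; fit the sparse SEM (SNP-based) or the
#' gene-based functional SEM on FPC scores; call detected edges from the
#' support of the fit; score against the true edges. Gene-based runs are
#' scored on gene-level edges (a gene-phenotype edge is true when the gene
#' contains any causal SNP for that phenotype).
#'
#' @inheritParams sim_dataset
#' @param estimator `"s2sem"` (SNP-based) or `"fsem"` (gene-based on FPC
#'   scores; requires a gene layout).
#' @param n_replicates number of independent replicates.
#' @param var_target FPCA explained-variance target (gene-based runs).
#' @param lambda_grid,cv_folds,ridge,control passed to the solver.
#' @param seed integer; each replicate uses `seed + replicate`.
#' @return list with `replicates` (per-replicate metric tibble) and
#'   `summary` (one-row tibble of mean PD/FDR with Monte Carlo standard
#'   errors and the failed-replicate count).
#' @export
power_experiment <- function(estimator = c("s2sem", "fsem"), n = 3000,
                             M = 10, n_snps = 100, maf_regime = "common",
                             n_genes = NULL, snps_per_gene = 10,
                             n_replicates = 20, expected_degree = 3,
                             n_qtl = 3, qtl_scheme = "pleiotropic",
                             noise_sd = 0.1, var_target = 0.8,
                             lambda_grid = NULL, cv_folds = 5, ridge = 0,
                             control = admm_control(), seed = 1,
                             common_band = c(0.05, 0.5),
                             rare_band = c(0.005, 0.01)) {
  estimator <- match.arg(estimator)
  if (estimator == "fsem" && is.null(n_genes)) {
    stop("gene-based runs need a gene layout (n_genes)", call. = FALSE)
  }
  reps <- vector("list", n_replicates)
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    res <- tryCatch(
      with_seed(seed + r, {
        dat <- sim_dataset(n = n, M = M, n_snps = n_snps,
                           maf_regime = maf_regime, n_genes = n_genes,
                           snps_per_gene = snps_per_gene,
                           expected_degree = expected_degree, n_qtl = n_qtl,
                           qtl_scheme = qtl_scheme, noise_sd = noise_sd,
                           common_band = common_band, rare_band = rare_band)
        if (estimator == "fsem") {
          eta <- build_fsem_design(dat$X, var_target = var_target)
          fit <- fit_fsem(dat$Y, eta, lambda = NULL,
                          lambda_grid = lambda_grid, cv_folds = cv_folds,
                          ridge = ridge, control = control, seed = seed + r)
          detected <- support_edges(fit, level = "gene")
          truth <- dat$gene_edges
        } else {
          fit <- fit_s2sem(dat$Y, dat$X, lambda = NULL,
                           lambda_grid = lambda_grid, cv_folds = cv_folds,
                           ridge = ridge, control = control, seed = seed + r)
          detected <- support_edges(fit)
          truth <- dat$edges
        }
        evaluate_edges(truth, detected)
      }),
      error = function(e) {
        warning("replicate ", r, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      reps[[r]] <- dplyr::mutate(res, replicate = r, .before = 1)
    }
  }
  replicates <- dplyr::bind_rows(reps)
  n_ok <- nrow(replicates)
  summary <- tibble::tibble(
    estimator = estimator, maf_regime = maf_regime, n = n,
    pd = mean(replicates$pd), fdr = mean(replicates$fdr),
    pd_se = stats::sd(replicates$pd) / sqrt(max(n_ok, 1)),
    fdr_se = stats::sd(replicates$fdr) / sqrt(max(n_ok, 1)),
    n_replicates = n_ok, n_failed = n_failed)
  list(replicates = replicates, summary = summary)
}

#' Edges present in the support of a fitted model
#'
#' @param fit a `sem_fit` (or `fsem_fit`).
#' @param level `"column"` reports one edge per nonzero exogenous column;
#'   `"gene"` collapses exogenous columns to their gene blocks (an edge per
#'   gene with any nonzero column).
#' @return tibble with `from`, `to`, `type`, `coefficient` (gene-level rows
#'   report the largest-magnitude column coefficient in the block).
#' @export
support_edges <- function(fit, level = c("column", "gene")) {
  level <- match.arg(level)
  phen <- fit$phenotypes
  gidx <- which(fit$support_Gamma, arr.ind = TRUE)
  phen_edges <- tibble::tibble(
    from = phen[gidx[, 1]], to = phen[gidx[, 2]],
    type = "phenotype", coefficient = fit$Gamma[gidx])
  bidx <- which(fit$support_B, arr.ind = TRUE)
  exo_edges <- tibble::tibble(
    from = fit$exogenous[bidx[, 1]], to = phen[bidx[, 2]],
    type = "genotype", coefficient = fit$B[bidx])
  if (level == "gene") {
    if (is.null(fit$gene_blocks)) {
      stop("fit has no gene block structure; refit on FPC scores or supply ",
           "gene metadata", call. = FALSE)
    }
    gene_of <- stats::setNames(
      rep(names(fit$gene_blocks), lengths(fit$gene_blocks)),
      fit$exogenous[unlist(fit$gene_blocks)])
    exo_edges <- exo_edges |>
      dplyr::mutate(from = unname(gene_of[.data$from])) |>
      dplyr::group_by(.data$from, .data$to, .data$type) |>
      dplyr::summarise(
        coefficient = .data$coefficient[which.max(abs(.data$coefficient))],
        .groups = "drop")
  }
  dplyr::bind_rows(phen_edges, exo_edges)
}
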