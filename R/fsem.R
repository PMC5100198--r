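# Gene-based sparse functional SEM: the SNP-based solver applied with the
# exogenous matrix replaced by the functional principal component score
# matrix eta, plus the two-stage whole-genome screening strategy.

#' Fit a sparse functional structural equation model
#'
#' Identical solver path to [fit_s2sem()] with the exogenous matrix replaced
#' by a matrix of per-gene functional principal component scores (built with
#' [build_fsem_design()]). The fitted `B` is partitioned into per-gene
#' coefficient blocks `b_ji = (b_ji1, ..., b_jiG)` used by the gene-level
#' test and the genetic effect function.
#'
#' @inheritParams fit_s2sem
#' @param eta a [genotype_data] of FPC scores from [build_fsem_design()].
#' @return an object of class `fsem_fit` (inherits `sem_fit`) with
#'   `gene_blocks` mapping each gene to its score columns and the FPC bases
#'   attached as `bases`.
#' @export
fit_fsem <- function(Y, eta, lambda = NULL, lambda_grid = NULL, cv_folds = 5,
                     ridge = 0, control = admm_control(), seed = 1) {
  if (!inherits(eta, "genotype_data") || !"gene" %in% names(eta$columns)) {
    stop("eta must come from build_fsem_design()", call. = FALSE)
  }
  fit <- fit_s2sem(Y, eta, lambda = lambda, lambda_grid = lambda_grid,
                   cv_folds = cv_folds, ridge = ridge, control = control,
                   seed = seed)
  fit$bases <- attr(eta, "bases")
  class(fit) <- c("fsem_fit", class(fit))
  fit
}

#' Genetic effect function of a gene on a phenotype
#'
#' Reconstructs `beta_ji(t) = sum_g b_jig phi_jg(t)` on the gene's SNP grid
#' from the fitted per-gene coefficient block and the gene's eigenfunctions.
#' A gene entirely absent from the fit's support yields the zero function
#' (flagged in the result).
#'
#' @param fit an `fsem_fit`.
#' @param gene gene identifier.
#' @param phenotype phenotype (outcome) name.
#' @param basis optional [fpc_scores()] basis; taken from the fit when
#'   available.
#' @return tibble with `position`, `grid`, and `beta` (the effect function
#'   values); attribute `in_support` flags whether any block coefficient is
#'   nonzero.
#' @export
effect_function <- function(fit, gene, phenotype, basis = NULL) {
  stopifnot(inherits(fit, "sem_fit"))
  basis <- basis %||% fit$bases[[gene]]
  if (is.null(basis)) stop("no FPC basis available for gene ", gene,
                           call. = FALSE)
  cols <- fit$gene_blocks[[gene]]
  if (is.null(cols)) stop("gene ", gene, " is not in the fit", call. = FALSE)
  if (!phenotype %in% fit$phenotypes) {
    stop("unknown phenotype ", phenotype, call. = FALSE)
  }
  b <- fit$B[cols, phenotype]
  beta <- drop(basis$eigenfunctions %*% b)
  out <- tibble::tibble(position = basis$positions, grid = basis$grid,
                        beta = beta)
  attr(out, "in_support") <- any(b != 0)
  out
}

#' Two-stage whole-genome screening and refit
#'
#' Stage 1 splits the genes into groups (supplied, or chromosome-order
#' chunks of at most `group_size` genes), fits a sparse functional SEM per
#' group, and retains every gene whose gene-level path test reaches
#' `p < alpha1` for any phenotype. Stage 2 refits a single functional SEM on
#' the union of retained genes to produce the final network.
#'
#' @param Y phenotype matrix or data frame.
#' @param X [genotype_data] of coded genotypes with gene metadata.
#' @param groups optional named vector or two-column data frame mapping
#'   `gene` to `group`; genes are chunked in order when `NULL`.
#' @param alpha1 stage-1 retention threshold on unadjusted gene-test
#'   p-values.
#' @param group_size maximum genes per stage-1 group.
#' @param var_target FPCA explained-variance target.
#' @inheritParams fit_s2sem
#' @return list with `stage1` (gene-by-phenotype test tibble with `group`
#'   and `retained`), `retained` (gene ids), `fit` (stage-2 `fsem_fit`, or
#'   `NULL` when nothing was retained), and `network` (stage-2 support edge
#'   tibble at gene level).
#' @export
screen_and_refit <- function(Y, X, groups = NULL, alpha1 = 0.05,
                             group_size = 100, var_target = 0.8,
                             lambda = NULL, lambda_grid = NULL, cv_folds = 5,
                             ridge = 0, control = admm_control(), seed = 1) {
  stopifnot(inherits(X, "genotype_data"))
  gene_ids <- unique(X$columns$gene)
  if (all(is.na(gene_ids))) stop("X carries no gene assignment",
                                 call. = FALSE)
  group_of <- resolve_groups(gene_ids, groups, group_size)
  stage1 <- vector("list", length(unique(group_of)))
  for (g in seq_along(unique(group_of))) {
    grp <- unique(group_of)[g]
    genes_g <- gene_ids[group_of == grp]
    Xg <- subset_genes(X, genes_g)
    eta <- build_fsem_design(Xg, var_target = var_target)
    fit_g <- fit_fsem(Y, eta, lambda = lambda, lambda_grid = lambda_grid,
                      cv_folds = cv_folds, ridge = ridge, control = control,
                      seed = seed)
    tests_g <- test_all_paths(fit_g, level = "gene")
    stage1[[g]] <- tests_g |>
      dplyr::filter(.data$causal %in% genes_g) |>
      dplyr::mutate(group = grp)
  }
  stage1 <- dplyr::bind_rows(stage1)
  retained <- stage1 |>
    dplyr::group_by(.data$causal) |>
    dplyr::summarise(min_p = min(.data$p_value), .groups = "drop") |>
    dplyr::filter(.data$min_p < alpha1) |>
    dplyr::pull(.data$causal)
  stage1$retained <- stage1$causal %in% retained
  if (length(retained) == 0) {
    message("no genes retained at stage 1; stage 2 skipped")
    return(list(stage1 = stage1, retained = character(0), fit = NULL,
                network = NULL))
  }
  X2 <- subset_genes(X, retained)
  eta2 <- build_fsem_design(X2, var_target = var_target)
  fit2 <- fit_fsem(Y, eta2, lambda = lambda, lambda_grid = lambda_grid,
                   cv_folds = cv_folds, ridge = ridge, control = control,
                   seed = seed)
  list(stage1 = stage1, retained = retained, fit = fit2,
       network = support_edges(fit2, level = "gene"))
}

resolve_groups <- function(gene_ids, groups, group_size) {
  if (is.null(groups)) {
    return(paste0("chunk", ceiling(seq_along(gene_ids) / group_size)))
  }
  if (inherits(groups, "data.frame")) {
    groups <- stats::setNames(as.character(groups[[2]]),
                              as.character(groups[[1]]))
  }
  missing <- setdiff(gene_ids, names(groups))
  if (length(missing)) {
    stop("genes without a group: ", paste(utils::head(missing, 5),
                                          collapse = ", "), call. = FALSE)
  }
  unname(groups[gene_ids])
}

subset_genes <- function(X, genes) {
  keep <- which(X$columns$gene %in% genes)
  genotype_data(X$values[, keep, drop = FALSE],
                columns = X$columns[keep, , drop = FALSE],
                sample_ids = X$sample_ids)
}
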