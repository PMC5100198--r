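# Functional principal component representation of per-gene genotype
# profiles. Coded genotypes across the SNPs of a gene are treated as noisy
# observations of a genotype function of genomic position; a discretized
# Karhunen-Loeve decomposition (PCA of the centered profiles with trapezoid
# quadrature weights on the position grid) yields orthonormal eigenfunctions
# and per-sample scores that compress the gene's variants.

#' Represent per-gene coded genotypes as a discretized function of position
#'
#' Positions are affinely rescaled to the unit interval (so downstream
#' scores do not depend on the physical scale) and trapezoid quadrature
#' weights are attached. Duplicate positions are jittered deterministically
#' by a small fraction of the smallest positive gap.
#'
#' @param X_gene numeric matrix (samples by SNPs) of coded genotypes.
#' @param positions increasing genomic coordinates, one per column.
#' @return list with `values`, `grid` (positions in \[0, 1\]), `weights`
#'   (trapezoid, summing to the grid span), and the raw `positions`.
#' @export
genotype_profile <- function(X_gene, positions) {
  X_gene <- as.matrix(X_gene)
  m <- ncol(X_gene)
  stopifnot(m >= 1, length(positions) == m)
  if (is.unsorted(positions)) {
    stop("positions must be increasing", call. = FALSE)
  }
  if (anyDuplicated(positions)) {
    gaps <- diff(sort(unique(positions)))
    step <- if (length(gaps)) min(gaps) * 1e-3 else 1e-3
    positions <- positions + (seq_len(m) - 1) * step
    warning("duplicate positions jittered deterministically", call. = FALSE)
  }
  grid <- if (m == 1) 0.5 else {
    (positions - positions[1]) / (positions[m] - positions[1])
  }
  weights <- trapezoid_weights(grid)
  list(values = X_gene, grid = grid, weights = weights,
       positions = positions)
}

trapezoid_weights <- function(grid) {
  m <- length(grid)
  if (m == 1) return(1)
  d <- diff(grid)
  c(d[1] / 2, (d[-1] + d[-(m - 1)]) / 2, d[m - 1] / 2)
}

#' Functional principal components of a gene's genotype profiles
#'
#' Eigen-decomposes the empirical covariance of the centered profiles under
#' the trapezoid quadrature inner product. Eigenfunctions are orthonormal on
#' the grid (`Phi' W Phi = I`); scores are quadrature projections of the
#' centered profiles onto the eigenfunctions, so their sample covariance is
#' diagonal with the eigenvalues on the diagonal. The number of retained
#' components is the smallest count explaining at least `var_target` of the
#' total variance; components with eigenvalue below
#' `min_eigval_ratio * max(eigenvalue)` are always dropped.
#'
#' @inheritParams genotype_profile
#' @param var_target fraction of variance to capture, in (0, 1\].
#' @param min_eigval_ratio relative eigenvalue cutoff.
#' @param gene_id label used in messages and score column names.
#' @return object of class `fpc_basis`: `eigenfunctions` (SNPs by L),
#'   `eigenvalues`, `scores` (samples by L), `var_explained` (cumulative),
#'   `grid`, `weights`, `positions`, `center`, `gene_id`.
#' @export
fpc_scores <- function(X_gene, positions, var_target = 0.8,
                       min_eigval_ratio = 1e-10, gene_id = "gene") {
  stopifnot(var_target > 0, var_target <= 1)
  prof <- genotype_profile(X_gene, positions)
  n <- nrow(prof$values)
  stopifnot(n >= 2)
  center <- colMeans(prof$values)
  Xc <- sweep(prof$values, 2, center)
  if (all(abs(Xc) < 1e-12)) {
    stop("gene ", gene_id, " has no genotype variance (monomorphic)",
         call. = FALSE)
  }
  w <- prof$weights
  sw <- sqrt(w)
  C <- crossprod(Xc) / n
  Kw <- t(C * sw) * sw  # diag(sw) C diag(sw)
  ee <- eigen(Kw, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  keep <- vals >= min_eigval_ratio * vals[1] & vals > 0
  cum <- cumsum(vals) / sum(vals)
  L <- which(cum >= var_target - 1e-12)[1]
  L <- min(max(L, 1), sum(keep))
  phi <- (ee$vectors / sw)[, seq_len(L), drop = FALSE]
  scores <- Xc %*% (phi * w)
  colnames(scores) <- paste0(gene_id, ".", seq_len(L))
  rownames(scores) <- rownames(X_gene)
  structure(
    list(gene_id = gene_id, eigenfunctions = phi,
         eigenvalues = vals[seq_len(L)], scores = scores,
         var_explained = cum[seq_len(L)], grid = prof$grid,
         weights = w, positions = prof$positions, center = center),
    class = "fpc_basis")
}

#' @export
print.fpc_basis <- function(x, ...) {
  cat("<fpc_basis> gene ", x$gene_id, ": ", length(x$eigenvalues),
      " component(s), ", length(x$grid), " SNP(s), ",
      round(100 * utils::tail(x$var_explained, 1), 1),
      "% variance explained\n", sep = "")
  invisible(x)
}

#' Assemble the exogenous design of functional principal component scores
#'
#' Computes (or accepts) one [fpc_scores()] basis per gene and concatenates
#' the per-gene score blocks into a single exogenous matrix `eta`, tagging
#' every column with its gene and component index so gene-level tests can
#' recover the blocks.
#'
#' @param X a [genotype_data] of coded genotypes whose column metadata
#'   carries `gene` and `position`, or a list of `fpc_basis` objects.
#' @param var_target,min_eigval_ratio passed to [fpc_scores()].
#' @return a [genotype_data] whose `values` are the concatenated scores and
#'   whose `columns` tibble has `id`, `gene`, `component`; the bases are
#'   attached as attribute `bases`.
#' @export
build_fsem_design <- function(X, var_target = 0.8, min_eigval_ratio = 1e-10) {
  if (inherits(X, "genotype_data")) {
    if (!"gene" %in% names(X$columns) || all(is.na(X$columns$gene))) {
      stop("genotype columns carry no gene assignment; supply a gene map",
           call. = FALSE)
    }
    genes <- split(seq_len(ncol(X$values)), X$columns$gene)
    genes <- genes[unique(X$columns$gene)]  # keep genomic order
    bases <- lapply(names(genes), function(g) {
      idx <- genes[[g]]
      fpc_scores(X$values[, idx, drop = FALSE],
                 positions = X$columns$position[idx],
                 var_target = var_target,
                 min_eigval_ratio = min_eigval_ratio, gene_id = g)
    })
    names(bases) <- names(genes)
  } else if (is.list(X) && all(vapply(X, inherits, TRUE, "fpc_basis"))) {
    bases <- X
    names(bases) <- vapply(bases, `[[`, "", "gene_id")
    ns <- vapply(bases, function(b) nrow(b$scores), 1L)
    if (length(unique(ns)) > 1) {
      stop("score matrices do not share sample alignment", call. = FALSE)
    }
  } else {
    stop("X must be a genotype_data with gene metadata or a list of ",
         "fpc_basis objects", call. = FALSE)
  }
  scores <- do.call(cbind, lapply(bases, `[[`, "scores"))
  columns <- dplyr::bind_rows(lapply(bases, function(b) {
    tibble::tibble(id = colnames(b$scores), gene = b$gene_id,
                   component = seq_along(b$eigenvalues))
  }))
  out <- genotype_data(scores, columns = columns,
                       sample_ids = rownames(scores))
  attr(out, "bases") <- bases
  out
}
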