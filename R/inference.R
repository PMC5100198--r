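# Hypothesis tests for path coefficients, multiplicity adjustment, and
# stability selection.
#
# Tests are computed from an unpenalized two-stage least squares refit on
# the selected support of each equation (plus, for gene tests, the full gene
# block): the classical covariance
#   Sigma_i = sigma_ii [W_i' X (X'X)^-1 X' W_i]^-1,
#   sigma_ii = ||y_i - W_i Delta_hat||^2 / n
# presumes no shrinkage, so the lasso solution only chooses the columns.

# Unpenalized GLS refit of equation i on a chosen set of W_i columns.
refit_equation <- function(fit, i, cols) {
  design <- build_design(fit$data$Y, fit$data$X, i,
                         instrument = fit$data$instrument)
  if (length(cols) == 0) {
    return(list(design = design, cols = integer(0),
                delta = numeric(0), sigma_ii = mean(design$y^2),
                Sigma = matrix(0, 0, 0)))
  }
  A <- design$A[, cols, drop = FALSE]
  Minst <- design$instrument$M
  H <- crossprod(A, Minst %*% A)
  q <- drop(crossprod(A, Minst %*% design$b))
  Hinv <- tryCatch(solve(H), error = function(e) {
    stop("singular restricted system for equation ", fit$phenotypes[i],
         ": reduce the support or increase the sample size", call. = FALSE)
  })
  delta <- drop(Hinv %*% q)
  resid <- design$y - drop(design$W[, cols, drop = FALSE] %*% delta)
  sigma_ii <- sum(resid^2) / length(resid)
  Sigma <- sigma_ii * Hinv
  dimnames(Sigma) <- list(design$labels[cols], design$labels[cols])
  list(design = design, cols = cols,
       delta = stats::setNames(delta, design$labels[cols]),
       sigma_ii = sigma_ii, Sigma = Sigma)
}

support_cols <- function(fit, i) {
  M <- length(fit$phenotypes)
  gam <- if (M > 1) fit$support_Gamma[-i, i] else logical(0)
  c(which(gam), M - 1 + which(fit$support_B[, i]))
}

# Support columns for a testing refit, capped at the instrument rank: the
# restricted system [W_S' X (X'X)^-1 X' W_S] is singular once |S| exceeds
# the number of instrument columns, so when an aggressively small penalty
# leaves a larger support the smallest-magnitude coefficients are dropped
# from the conditioning set (columns in `keep` are never dropped).
capped_support_cols <- function(fit, i, keep = integer(0)) {
  cols <- setdiff(support_cols(fit, i), keep)
  cap <- ncol(fit$data$instrument$X) - length(keep)
  if (length(cols) > cap) {
    M <- length(fit$phenotypes)
    delta <- c(if (M > 1) fit$Gamma[-i, i], fit$B[, i])
    cols <- cols[order(abs(delta[cols]), decreasing = TRUE)][seq_len(max(cap, 0))]
  }
  sort(union(cols, keep))
}

#' Covariance of the path-coefficient estimates for one equation
#'
#' Refits equation `i` without penalty on the selected support (or a caller
#' supplied column set) and returns the estimated coefficient covariance.
#'
#' @param fit a `sem_fit`.
#' @param i equation index or phenotype name.
#' @param cols optional integer indices into the columns of `W_i`
#'   (phenotypes except `i` first, then exogenous columns); defaults to the
#'   fit's support for that equation.
#' @return symmetric covariance matrix with coefficient names.
#' @export
coef_covariance <- function(fit, i, cols = NULL) {
  i <- resolve_equation(fit, i)
  cols <- cols %||% support_cols(fit, i)
  if (length(cols) == 0) {
    stop("equation ", fit$phenotypes[i], " has an empty support",
         call. = FALSE)
  }
  refit_equation(fit, i, cols)$Sigma
}

resolve_equation <- function(fit, i) {
  if (is.character(i)) {
    idx <- match(i, fit$phenotypes)
    if (is.na(idx)) stop("unknown phenotype ", i, call. = FALSE)
    return(idx)
  }
  as.integer(i)
}

#' Gene-level path test
#'
#' Tests whether the genetic effect function of gene `j` on phenotype `i` is
#' identically zero, which is equivalent to all its FPC block coefficients
#' vanishing. The statistic `T_g = b' Lambda^-1 b`, with `Lambda` the gene
#' block of the refit covariance, is compared to a chi-square with `G`
#' (block size) degrees of freedom. The refit always includes the full gene
#' block (on top of the equation's selected support), so genes shrunk out of
#' the support are still testable.
#'
#' @param fit a `sem_fit` or `fsem_fit` with gene block structure.
#' @param gene gene identifier.
#' @param phenotype equation index or phenotype name.
#' @return one-row tibble: `outcome`, `causal`, `statistic`, `df`,
#'   `p_value`.
#' @export
test_gene <- function(fit, gene, phenotype) {
  i <- resolve_equation(fit, phenotype)
  if (is.null(fit$gene_blocks) || is.null(fit$gene_blocks[[gene]])) {
    stop("gene ", gene, " has no block in this fit", call. = FALSE)
  }
  M <- length(fit$phenotypes)
  block <- M - 1 + fit$gene_blocks[[gene]]
  cols <- capped_support_cols(fit, i, keep = block)
  ref <- refit_equation(fit, i, cols)
  pos <- match(block, ref$cols)
  b <- ref$delta[pos]
  Lambda <- ref$Sigma[pos, pos, drop = FALSE]
  stat <- tryCatch(drop(crossprod(b, solve(Lambda, b))),
                   error = function(e) NA_real_)
  G <- length(b)
  tibble::tibble(outcome = fit$phenotypes[i], causal = gene,
                 statistic = stat, df = G,
                 p_value = stats::pchisq(stat, df = G, lower.tail = FALSE))
}

#' Single-coefficient path test
#'
#' Wald chi-square(1) test `T_c = Delta_hat^2 / var(Delta_hat)` for one
#' column of equation `i`, with the variance taken from the unpenalized
#' refit on the support (augmented with the tested column when it was
#' shrunk out).
#'
#' @param fit a `sem_fit`.
#' @param column a `W_i` column label (a phenotype or exogenous name) or
#'   index.
#' @param phenotype equation index or phenotype name.
#' @return one-row tibble: `outcome`, `causal`, `statistic`, `df`,
#'   `p_value`.
#' @export
test_single <- function(fit, column, phenotype) {
  i <- resolve_equation(fit, phenotype)
  M <- length(fit$phenotypes)
  labels <- c(if (M > 1) fit$phenotypes[-i], fit$exogenous)
  if (is.character(column)) {
    idx <- match(column, labels)
    if (is.na(idx)) stop("unknown column ", column, " for equation ",
                         fit$phenotypes[i], call. = FALSE)
  } else idx <- as.integer(column)
  cols <- capped_support_cols(fit, i, keep = idx)
  ref <- refit_equation(fit, i, cols)
  pos <- match(idx, ref$cols)
  v <- ref$Sigma[pos, pos]
  if (!is.finite(v) || v <= 0) {
    stop("zero variance for coefficient ", labels[idx], call. = FALSE)
  }
  stat <- unname(ref$delta[pos]^2 / v)
  tibble::tibble(outcome = fit$phenotypes[i], causal = labels[idx],
                 statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Test every edge in the support of a fit
#'
#' Runs [test_single()] for each phenotype-phenotype and exogenous edge in
#' the support, or, at `level = "gene"`, [test_gene()] for every gene block
#' (support phenotype edges are still tested singly).
#'
#' @param fit a `sem_fit`.
#' @param level `"column"` or `"gene"`.
#' @param genes genes to test at gene level (default: all blocks).
#' @return tibble of test rows (`outcome`, `causal`, `statistic`, `df`,
#'   `p_value`) with an `edge_type` column.
#' @export
test_all_paths <- function(fit, level = c("column", "gene"), genes = NULL) {
  level <- match.arg(level)
  out <- list()
  M <- length(fit$phenotypes)
  for (i in seq_len(M)) {
    sup <- support_cols(fit, i)
    labels <- c(if (M > 1) fit$phenotypes[-i], fit$exogenous)
    phen_idx <- sup[sup <= M - 1]
    for (idx in phen_idx) {
      out[[length(out) + 1]] <- test_single(fit, idx, i) |>
        dplyr::mutate(edge_type = "phenotype")
    }
    if (level == "column") {
      for (idx in sup[sup > M - 1]) {
        out[[length(out) + 1]] <- test_single(fit, idx, i) |>
          dplyr::mutate(edge_type = "genotype")
      }
    } else {
      test_genes <- genes %||% names(fit$gene_blocks)
      for (g in test_genes) {
        out[[length(out) + 1]] <- test_gene(fit, g, i) |>
          dplyr::mutate(edge_type = "genotype")
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Adjust path-test p-values for multiplicity
#'
#' @param tests tibble with a `p_value` column (from [test_all_paths()]).
#' @param method `"bonferroni"` (`min(1, m p)`) or `"bh"`
#'   (Benjamini-Hochberg step-up false discovery rate).
#' @return `tests` with an `adjusted_p` column appended.
#' @export
adjust_pvalues <- function(tests, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  tests$adjusted_p <- stats::p.adjust(
    tests$p_value, method = if (method == "bh") "BH" else "bonferroni")
  tests
}

#' Stability selection for network edges
#'
#' Refits the sparse model on `n_resamples` resampled datasets (bootstrap
#' with replacement of size n by default, or half-sample subsampling) and
#' records, for every edge of the full-data fit, the fraction of resamples
#' in which it stays in the support. An edge is kept when its full-data
#' p-value is below `p_thresh` and its selection frequency is at least
#' `freq_thresh`.
#'
#' @param Y,X data as for [fit_s2sem()] / [fit_fsem()].
#' @param fitter function `(Y, X)` returning a `sem_fit`; it should use a
#'   fixed penalty (re-running CV inside every resample is supported but
#'   slow).
#' @param n_resamples number of resampled fits.
#' @param p_thresh p-value threshold applied to the full-data tests.
#' @param freq_thresh minimum selection frequency.
#' @param scheme `"bootstrap"` or `"subsample"` (n/2 without replacement).
#' @param level `"column"` or `"gene"` edges.
#' @param seed integer seed for the resampling.
#' @return tibble with `from`, `to`, `type`, `coefficient`, `p_value`,
#'   `stability`, `kept`.
#' @export
stability_selection <- function(Y, X, fitter, n_resamples = 100,
                                p_thresh = 0.05, freq_thresh = 0.8,
                                scheme = c("bootstrap", "subsample"),
                                level = c("column", "gene"), seed = 1) {
  scheme <- match.arg(scheme)
  level <- match.arg(level)
  stopifnot(p_thresh > 0, p_thresh <= 1, freq_thresh > 0, freq_thresh <= 1)
  Yv <- phenotype_values(Y)
  full_fit <- fitter(Y, X)
  full_edges <- support_edges(full_fit, level = level)
  tests <- test_all_paths(full_fit, level = level)
  n <- nrow(Yv)
  counts <- stats::setNames(numeric(nrow(full_edges)),
                            edge_keys_rows(full_edges))
  for (r in seq_len(n_resamples)) {
    idx <- with_seed(seed + r, {
      if (scheme == "bootstrap") sample.int(n, n, replace = TRUE)
      else sample.int(n, floor(n / 2))
    })
    fit_r <- tryCatch(fitter(subset_samples(Y, idx), subset_samples(X, idx)),
                      error = function(e) NULL)
    if (is.null(fit_r)) next
    keys_r <- edge_keys_rows(support_edges(fit_r, level = level))
    hit <- names(counts) %in% keys_r
    counts[hit] <- counts[hit] + 1
  }
  stability <- counts / n_resamples
  full_edges |>
    dplyr::left_join(
      tests |> dplyr::select("outcome", "causal", "p_value"),
      by = c(to = "outcome", from = "causal")) |>
    dplyr::mutate(stability = unname(stability),
                  kept = .data$p_value < p_thresh &
                    .data$stability >= freq_thresh)
}

edge_keys_rows <- function(edges) paste(edges$from, edges$to, sep = "\r")

subset_samples <- function(x, idx) {
  if (inherits(x, "genotype_data")) {
    genotype_data(x$values[idx, , drop = FALSE], columns = x$columns)
  } else if (is.matrix(x)) {
    x[idx, , drop = FALSE]
  } else {
    x[idx, , drop = FALSE]
  }
}
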