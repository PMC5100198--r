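# Instrumented (generalized least squares) machinery shared by the SNP-based
# and FPC-score-based solvers.

#' Precompute the instrument projection for a set of exogenous columns
#'
#' The two-stage least squares criterion repeatedly needs `(X'X)^-1` where
#' `X` holds the exogenous (instrument) columns: coded genotypes for the
#' SNP-based model or functional principal component scores for the
#' gene-based model. The inverse is computed once per fit through an
#' eigendecomposition with an eigenvalue floor, so nearly collinear
#' instruments degrade gracefully instead of failing outright.
#'
#' @param X numeric matrix of instruments (samples by columns), already
#'   centered.
#' @param ridge nonnegative ridge added to the diagonal of `X'X` before
#'   inversion; useful when the number of columns approaches the sample size.
#' @param eig_floor_ratio eigenvalues below this fraction of `trace(X'X)` are
#'   clamped to the floor.
#' @return list with the instrument matrix `X`, the (floored) inverse `M`,
#'   a factor `L` with `M = L L'`, and a flag `rank_deficient`.
#' @keywords internal
prep_instrument <- function(X, ridge = 0, eig_floor_ratio = 1e-10) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  S <- crossprod(X)
  if (ridge > 0) S <- S + diag(ridge, ncol(S))
  ee <- eigen(S, symmetric = TRUE)
  floor_val <- eig_floor_ratio * max(sum(diag(S)), .Machine$double.xmin)
  vals <- pmax(ee$values, floor_val)
  M <- ee$vectors %*% (t(ee$vectors) / vals)
  L <- ee$vectors %*% diag(1 / sqrt(vals), length(vals))
  list(X = X, M = M, L = L,
       rank_deficient = any(ee$values < floor_val))
}

# Quadratic pieces of the GLS criterion for one structural equation:
# f(Delta) = (b - A Delta)' M (b - A Delta) with A = X'W, b = X'y.
design_quadratic <- function(design) {
  A <- design$A
  MA <- design$instrument$M %*% A
  Mb <- drop(design$instrument$M %*% design$b)
  list(H = crossprod(A, MA),          # A' M A
       q = drop(crossprod(A, Mb)),    # A' M b
       c0 = sum(design$b * Mb))       # b' M b
}

# Evaluate f(Delta) from the precomputed quadratic.
gls_objective <- function(quad, delta) {
  drop(quad$c0 - 2 * sum(quad$q * delta) +
         crossprod(delta, quad$H %*% delta))
}
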