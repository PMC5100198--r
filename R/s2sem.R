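# Sparse two-stage least squares estimation of structural equation models
# (S2SEM). The system is Y Gamma + X B + E = 0 with the diagonal of Gamma
# normalized to -1, so each equation reads
#   y_i = Y_{-i} gamma_{-i} + X B_i + e_i = W_i Delta_i + e_i.
# Each equation is estimated independently by minimizing the instrumented
# (generalized least squares) criterion
#   f(Delta) = (X'y_i - X'W_i Delta)' (X'X)^{-1} (X'y_i - X'W_i Delta)
# plus an L1 penalty lambda * ||Delta||_1, solved by ADMM.

#' Build the per-equation design for two-stage least squares
#'
#' For equation `i` the regressor matrix is `W_i = [Y_{-i} X]`: all phenotype
#' columns except the response itself, followed by the exogenous columns. The
#' exogenous matrix also serves as the instrument set.
#'
#' @param Y numeric matrix or data frame of phenotypes (samples by M).
#' @param X numeric matrix, data frame, or [genotype_data] of exogenous
#'   columns (coded genotypes or FPC scores).
#' @param i equation index (which phenotype is the response), `1 <= i <= M`.
#' @param instrument optional precomputed instrument (from
#'   `prep_instrument`); built from `X` when missing.
#' @param ridge nonnegative ridge for the instrument Gram matrix.
#' @return list of class `equation_design` with elements `y`, `W`,
#'   `instrument`, the cross-products `A = X'W`, `b = X'y`, the response
#'   index `i` and column labels.
#' @examples
#' Y <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("P1", "P2", "P3")))
#' X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("S1", "S2")))
#' d <- build_design(Y, X, i = 2)
#' colnames(d$W)  # P1 P3 S1 S2
#' @export
build_design <- function(Y, X, i, instrument = NULL, ridge = 0) {
  Y <- phenotype_values(Y)
  Xv <- exogenous_values(X)
  M <- ncol(Y)
  stopifnot(i >= 1, i <= M, nrow(Y) == nrow(Xv), nrow(Y) > 0)
  if (is.null(instrument)) instrument <- prep_instrument(Xv, ridge = ridge)
  W <- if (M > 1) cbind(Y[, -i, drop = FALSE], Xv) else Xv
  phen_names <- colnames(Y) %||% paste0("P", seq_len(M))
  exo_names <- colnames(Xv) %||% paste0("X", seq_len(ncol(Xv)))
  w_names <- if (M > 1) c(phen_names[-i], exo_names) else exo_names
  colnames(W) <- w_names
  structure(
    list(y = Y[, i], W = W, instrument = instrument,
         A = crossprod(instrument$X, W),
         b = drop(crossprod(instrument$X, Y[, i])),
         i = i, n_phen = M, phen_cols = seq_len(max(M - 1, 0)),
         exo_cols = max(M - 1, 0) + seq_len(ncol(Xv)),
         labels = w_names),
    class = "equation_design")
}

#' Generalized least squares (two-stage least squares) estimate
#'
#' Solves the unpenalized instrumented criterion for one equation:
#' `Delta_hat = [W'X (X'X)^-1 X'W]^-1 W'X (X'X)^-1 X'y`. This equals the
#' explicit two-stage procedure: regress `Y_{-i}` on `X`, then regress `y_i`
#' on the fitted values and `X`.
#'
#' @param design an `equation_design` from [build_design()].
#' @param ridge nonnegative ridge added to `X'X` (rebuilds the instrument
#'   when positive); use when the bracketed matrix is singular.
#' @return named numeric vector of coefficients (phenotype block first).
#' @export
gls_estimate <- function(design, ridge = 0) {
  if (ridge > 0) {
    design <- build_design_refresh(design, ridge)
  }
  quad <- design_quadratic(design)
  est <- tryCatch(
    solve(quad$H, quad$q),
    error = function(e) {
      stop("singular two-stage system for equation ", design$i,
           ": add a ridge (ridge > 0) or reduce dimension with the ",
           "gene-based functional model (FPC scores)", call. = FALSE)
    })
  stats::setNames(drop(est), design$labels)
}

build_design_refresh <- function(design, ridge) {
  design$instrument <- prep_instrument(design$instrument$X, ridge = ridge)
  design
}

#' ADMM solver for the L1-penalized two-stage least squares criterion
#'
#' Minimizes `f(Delta) + lambda * ||Delta||_1` where `f` is the instrumented
#' quadratic criterion. Standard scaled-form lasso ADMM: the quadratic update
#' solves `(A'MA + rho I) Delta = A'Mb + rho (z - u)` with a Cholesky factor
#' computed once and reused; the `z` update is elementwise soft-thresholding
#' at `lambda / rho`; the returned solution is `z`, whose zeros are exact.
#'
#' @param design an `equation_design`.
#' @param lambda nonnegative L1 penalty.
#' @param control list from [admm_control()].
#' @param init optional warm-start list with elements `z` and `u`.
#' @return list with `coef` (named sparse solution), `iterations`,
#'   `converged`, and `objective` (penalized criterion at the solution).
#' @export
admm_lasso <- function(design, lambda, control = admm_control(),
                       init = NULL) {
  stopifnot(lambda >= 0)
  quad <- design_quadratic(design)
  rho <- resolve_rho(control, quad)
  fac <- chol(quad$H + diag(rho, nrow(quad$H)))
  out <- admm_lasso_quad(quad, fac, rho, lambda, control, init = init)
  out$coef <- stats::setNames(out$coef, design$labels)
  out
}

#' @rdname admm_lasso
#' @param rho positive augmented-Lagrangian parameter; `NULL` (default)
#'   matches it to the scale of the quadratic (`mean(diag(A'MA))`), which
#'   keeps the iteration count low across sample sizes.
#' @param max_iter iteration cap; non-convergence returns the best iterate
#'   with a warning.
#' @param tol_abs,tol_rel absolute and relative stopping tolerances on the
#'   primal and dual residuals.
#' @export
admm_control <- function(rho = NULL, max_iter = 2000, tol_abs = 1e-6,
                         tol_rel = 1e-4) {
  stopifnot(is.null(rho) || rho > 0, max_iter >= 1, tol_abs > 0,
            tol_rel > 0)
  list(rho = rho, max_iter = max_iter, tol_abs = tol_abs, tol_rel = tol_rel)
}

resolve_rho <- function(control, quad) {
  control$rho %||% max(mean(diag(quad$H)), .Machine$double.eps)
}

# Core ADMM loop on precomputed quadratic pieces; `fac` is chol(H + rho I).
# Kept separate so cross-validation can reuse one factorization across the
# whole lambda grid.
admm_lasso_quad <- function(quad, fac, rho, lambda, control, init = NULL,
                            warn = TRUE) {
  p <- length(quad$q)
  z <- if (!is.null(init)) init$z else numeric(p)
  u <- if (!is.null(init)) init$u else numeric(p)
  kappa <- lambda / (2 * rho)  # f has leading coefficient 1, penalty lambda
  converged <- FALSE
  iter <- 0L
  sqp <- sqrt(p)
  for (iter in seq_len(control$max_iter)) {
    x <- backsolve(fac, forwardsolve(t(fac), quad$q + rho * (z - u)))
    z_old <- z
    z <- soft_threshold(x + u, kappa)
    u <- u + x - z
    r_norm <- sqrt(sum((x - z)^2))
    s_norm <- rho * sqrt(sum((z - z_old)^2))
    eps_pri <- sqp * control$tol_abs +
      control$tol_rel * max(sqrt(sum(x^2)), sqrt(sum(z^2)))
    eps_dual <- sqp * control$tol_abs + control$tol_rel * rho * sqrt(sum(u^2))
    if (r_norm < eps_pri && s_norm < eps_dual) {
      converged <- TRUE
      break
    }
  }
  if (!converged && warn) {
    warning("ADMM did not converge within ", control$max_iter,
            " iterations (lambda = ", signif(lambda, 3), ")", call. = FALSE)
  }
  obj <- gls_objective(quad, z) + lambda * sum(abs(z))
  list(coef = z, iterations = iter, converged = converged, objective = obj,
       state = list(z = z, u = u))
}

soft_threshold <- function(x, kappa) {
  sign(x) * pmax(abs(x) - kappa, 0)
}

# Smallest lambda at which the penalized solution is exactly zero:
# the gradient of f at 0 is -2 A'Mb, so lambda_max = 2 * max|A'Mb|.
lambda_zero_threshold <- function(quad) 2 * max(abs(quad$q))

#' Fit a sparse structural equation model by penalized two-stage least squares
#'
#' Estimates the phenotype path-coefficient matrix `Gamma` (M by M, diagonal
#' fixed at -1) and the exogenous coefficient matrix `B` (K by M) equation by
#' equation. Columns of `Y` and `X` are mean-centered before fitting (the
#' structural system carries no intercept). With `lambda = NULL` the penalty
#' is chosen per equation by five-fold cross-validation on the instrumented
#' criterion.
#'
#' @param Y phenotype matrix or data frame (samples by M); a `sample_id`
#'   column in a data frame is used for alignment checks and dropped.
#' @param X exogenous matrix, data frame, or [genotype_data].
#' @param lambda scalar or length-M penalty; `NULL` selects by CV.
#' @param lambda_grid candidate penalties for CV (fractions of the
#'   per-equation zero threshold are used when `NULL`).
#' @param cv_folds folds for cross-validation.
#' @param ridge nonnegative ridge for the instrument Gram matrix.
#' @param control ADMM settings from [admm_control()].
#' @param seed integer seed controlling CV fold assignment.
#' @return object of class `sem_fit`: list with `Gamma`, `B`, `sigma2`,
#'   `lambda`, support masks, convergence info, and the centered data
#'   (needed for the path-coefficient tests).
#' @seealso [fit_fsem()] for the gene-based functional variant,
#'   [test_all_paths()], [network_edges()], [generics::tidy()].
#' @export
fit_s2sem <- function(Y, X, lambda = NULL, lambda_grid = NULL, cv_folds = 5,
                      ridge = 0, control = admm_control(), seed = 1) {
  Yv <- phenotype_values(Y)
  Xv <- exogenous_values(X)
  check_alignment(Y, X)
  M <- ncol(Yv)
  K <- ncol(Xv)
  stopifnot(M >= 1, K >= 1)
  Yc <- scale(Yv, center = TRUE, scale = FALSE)
  Xc <- scale(Xv, center = TRUE, scale = FALSE)
  phen_names <- colnames(Yc) %||% paste0("P", seq_len(M))
  exo_names <- colnames(Xc) %||% paste0("X", seq_len(K))
  colnames(Yc) <- phen_names
  colnames(Xc) <- exo_names

  if (is.null(lambda)) {
    lambda <- cross_validate_lambda(Yc, Xc, grid = lambda_grid,
                                    folds = cv_folds, ridge = ridge,
                                    control = control, seed = seed,
                                    center = FALSE)$lambda
  }
  lambda <- rep_len(lambda, M)

  instrument <- prep_instrument(Xc, ridge = ridge)
  Gamma <- matrix(0, M, M, dimnames = list(phen_names, phen_names))
  diag(Gamma) <- -1
  B <- matrix(0, K, M, dimnames = list(exo_names, phen_names))
  sigma2 <- stats::setNames(numeric(M), phen_names)
  iterations <- integer(M)
  converged <- logical(M)
  for (i in seq_len(M)) {
    design <- build_design(Yc, Xc, i, instrument = instrument)
    sol <- tryCatch(
      admm_lasso(design, lambda[i], control = control),
      error = function(e) {
        warning("equation ", phen_names[i], " failed: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(sol)) {
      converged[i] <- NA
      next
    }
    delta <- sol$coef
    if (M > 1) Gamma[-i, i] <- delta[design$phen_cols]
    B[, i] <- delta[design$exo_cols]
    resid <- design$y - drop(design$W %*% delta)
    sigma2[i] <- max(mean(resid^2), .Machine$double.eps)
    iterations[i] <- sol$iterations
    converged[i] <- sol$converged
  }
  structure(
    list(Gamma = Gamma, B = B, sigma2 = sigma2,
         lambda = stats::setNames(lambda, phen_names),
         support_Gamma = Gamma != 0 & !diag_mask(M),
         support_B = B != 0,
         phenotypes = phen_names, exogenous = exo_names,
         gene_blocks = exogenous_blocks(X, exo_names),
         iterations = iterations, converged = converged,
         centers = list(Y = attr(Yc, "scaled:center"),
                        X = attr(Xc, "scaled:center")),
         data = list(Y = strip_scaled(Yc), X = strip_scaled(Xc),
                     instrument = instrument),
         ridge = ridge, control = control, n = nrow(Yc)),
    class = "sem_fit")
}

diag_mask <- function(M) diag(TRUE, M) == 1

strip_scaled <- function(x) {
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  x
}

#' Select per-equation penalties by k-fold cross-validation
#'
#' For each equation the candidate penalty minimizing the mean held-out
#' instrumented criterion `f(Delta_hat)` across folds is selected. Fold
#' assignment is deterministic given `seed`. The held-out criterion is
#' computed with the held-out fold's own instrument Gram matrix.
#'
#' @inheritParams fit_s2sem
#' @param grid positive candidate penalties, shared across equations; when
#'   `NULL`, 8 log-spaced fractions (1 down to 1e-3) of each equation's
#'   zero-solution threshold are used.
#' @param folds number of folds; `n >= folds` is required.
#' @param center center columns first (disable when the caller already has).
#' @return list with `lambda` (named length-M vector) and `cv` (tibble of
#'   fold-mean scores per equation and candidate).
#' @export
cross_validate_lambda <- function(Y, X, grid = NULL, folds = 5, ridge = 0,
                                  control = admm_control(), seed = 1,
                                  center = TRUE) {
  Yv <- phenotype_values(Y)
  Xv <- exogenous_values(X)
  if (center) {
    Yv <- strip_scaled(scale(Yv, center = TRUE, scale = FALSE))
    Xv <- strip_scaled(scale(Xv, center = TRUE, scale = FALSE))
  }
  n <- nrow(Yv)
  M <- ncol(Yv)
  if (n < folds) stop("need at least as many samples as folds", call. = FALSE)
  phen_names <- colnames(Yv) %||% paste0("P", seq_len(M))

  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))

  # The instrumented quadratic has rank at most K < M - 1 + K, so the
  # problem is underdetermined like a p > n lasso; the grid floor follows
  # the coordinate-descent lasso convention for that case (1% of the
  # zero-solution threshold).
  relative_grid <- is.null(grid)
  if (relative_grid) {
    fractions <- 10^seq(0, -2, length.out = 10)
  } else {
    stopifnot(length(grid) >= 1, all(grid > 0))
    grid <- sort(grid, decreasing = TRUE)
  }

  # Per-fold cross-products shared by all equations.
  folds_pre <- lapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    Xtr <- Xv[tr, , drop = FALSE]
    Xte <- Xv[!tr, , drop = FALSE]
    list(
      train = list(inst = prep_instrument(Xtr, ridge = ridge),
                   GY = crossprod(Xtr, Yv[tr, , drop = FALSE]),
                   GX = crossprod(Xtr)),
      test = list(inst = prep_instrument(Xte, ridge = ridge),
                  GY = crossprod(Xte, Yv[!tr, , drop = FALSE]),
                  GX = crossprod(Xte)))
  })

  scores <- vector("list", M)
  lambda_sel <- stats::setNames(numeric(M), phen_names)
  full_inst <- prep_instrument(Xv, ridge = ridge)
  full_GY <- crossprod(Xv, Yv)
  full_GX <- crossprod(Xv)
  for (i in seq_len(M)) {
    grid_i <- if (relative_grid) {
      quad_full <- quad_from_cross(full_inst, full_GY, full_GX, i, M)
      lambda_zero_threshold(quad_full) * fractions
    } else grid
    fold_scores <- matrix(NA_real_, folds, length(grid_i))
    for (f in seq_len(folds)) {
      pre <- folds_pre[[f]]
      quad_tr <- quad_from_cross(pre$train$inst, pre$train$GY, pre$train$GX,
                                 i, M)
      quad_te <- quad_from_cross(pre$test$inst, pre$test$GY, pre$test$GX,
                                 i, M)
      rho <- resolve_rho(control, quad_tr)
      fac <- chol(quad_tr$H + diag(rho, nrow(quad_tr$H)))
      state <- NULL
      for (g in seq_along(grid_i)) {
        sol <- admm_lasso_quad(quad_tr, fac, rho, grid_i[g], control,
                               init = state, warn = FALSE)
        state <- sol$state
        fold_scores[f, g] <- gls_objective(quad_te, sol$coef)
      }
    }
    mean_scores <- colMeans(fold_scores)
    best <- which.min(mean_scores)
    lambda_sel[i] <- grid_i[best]
    scores[[i]] <- tibble::tibble(
      phenotype = phen_names[i], lambda = grid_i, cv_score = mean_scores,
      selected = seq_along(grid_i) == best)
  }
  list(lambda = lambda_sel, cv = dplyr::bind_rows(scores))
}

# Quadratic pieces for equation i assembled from shared cross-products
# GY = X'Y, GX = X'X (avoids touching the n-row data per equation).
quad_from_cross <- function(inst, GY, GX, i, M) {
  A <- if (M > 1) cbind(GY[, -i, drop = FALSE], GX) else GX
  b <- GY[, i]
  MA <- inst$M %*% A
  Mb <- drop(inst$M %*% b)
  list(H = crossprod(A, MA), q = drop(crossprod(A, Mb)), c0 = sum(b * Mb))
}
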