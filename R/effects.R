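# Decomposition of effects in the fitted linear system: the direct effect of
# X on Y is the path coefficient of the edge X -> Y; the indirect effect is
# the sum over directed paths of length >= 2 of the products of the path
# coefficients; the total effect is their sum, and equals the derivative of
# E[Y | do(X = x)] in the linear-Gaussian model. The marginal effect is the
# simple-regression slope of Y on X.

edges_to_graph <- function(edges) {
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (!"coefficient" %in% names(edges)) edges$coefficient <- NA_real_
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "coefficient")], directed = TRUE)
  if (igraph::any_multiple(g)) {
    stop("duplicate edges in the network", call. = FALSE)
  }
  g
}

#' Enumerate directed simple paths between two nodes
#'
#' Lists every simple (no repeated node) directed path from `source` to
#' `target` up to `max_len` edges, in lexicographic node-sequence order,
#' with the product of the path coefficients along each path. Networks
#' containing a two-node cycle (an edge fitted in both directions, which the
#' estimator can produce) are flagged with a warning; the simple-path
#' restriction still applies.
#'
#' @param edges data frame with columns `from`, `to`, `coefficient`.
#' @param source,target node names, `source != target`.
#' @param max_len maximum number of edges per path (default: number of
#'   nodes, the simple-path bound).
#' @return tibble with `path` (node sequence collapsed with `" -> "`),
#'   `length`, and `product`.
#' @examples
#' net <- tibble::tibble(from = c("A", "B"), to = c("B", "C"),
#'                       coefficient = c(2, 3))
#' enumerate_paths(net, "A", "C")
#' @export
enumerate_paths <- function(edges, source, target, max_len = NULL) {
  stopifnot(source != target)
  g <- edges_to_graph(edges)
  flag_two_cycles(g)
  max_len <- max_len %||% igraph::vcount(g)
  if (!source %in% igraph::V(g)$name || !target %in% igraph::V(g)$name) {
    return(tibble::tibble(path = character(0), length = integer(0),
                          product = numeric(0)))
  }
  paths <- igraph::all_simple_paths(g, from = source, to = target,
                                    mode = "out", cutoff = max_len)
  if (length(paths) == 0) {
    return(tibble::tibble(path = character(0), length = integer(0),
                          product = numeric(0)))
  }
  rows <- purrr::map(paths, function(p) {
    nodes <- igraph::V(g)$name[p]
    eids <- igraph::get_edge_ids(
      g, rbind(utils::head(nodes, -1), nodes[-1]))
    tibble::tibble(path = paste(nodes, collapse = " -> "),
                   length = length(nodes) - 1L,
                   product = prod(igraph::E(g)$coefficient[eids]))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$path)
}

flag_two_cycles <- function(g) {
  el <- igraph::as_edgelist(g)
  fwd <- paste(el[, 1], el[, 2], sep = "\r")
  rev <- paste(el[, 2], el[, 1], sep = "\r")
  if (any(fwd %in% rev)) {
    warning("network contains two-directional edges; effects along cyclic ",
            "routes are not defined", call. = FALSE)
  }
  invisible(any(fwd %in% rev))
}

# Error when the subgraph on nodes lying on any source->target route has a
# cycle: path-product totals are undefined without an acyclic model.
check_acyclic_between <- function(g, source, target) {
  reach_fwd <- igraph::subcomponent(g, source, mode = "out")
  reach_bwd <- igraph::subcomponent(g, target, mode = "in")
  nodes <- intersect(reach_fwd, reach_bwd)
  if (length(nodes) < 2) return(invisible(TRUE))
  sub <- igraph::induced_subgraph(g, nodes)
  if (!igraph::is_dag(sub)) {
    stop("cycle on a path between ", source, " and ", target,
         "; total effect undefined without an acyclic model", call. = FALSE)
  }
  invisible(TRUE)
}

#' Total effect along directed paths
#'
#' Sum over all directed simple paths from `source` to `target` of the
#' products of their path coefficients. Requires the connecting subgraph to
#' be acyclic.
#'
#' @inheritParams enumerate_paths
#' @return a single number (0 when no path connects the pair).
#' @export
total_effect_paths <- function(edges, source, target, max_len = NULL) {
  g <- edges_to_graph(edges)
  if (source %in% igraph::V(g)$name && target %in% igraph::V(g)$name) {
    check_acyclic_between(g, source, target)
  }
  ps <- suppressWarnings(enumerate_paths(edges, source, target, max_len))
  sum(ps$product)
}

#' Decompose an effect into direct, indirect, and total components
#'
#' Direct effect: the coefficient of the edge `source -> target` (0 when
#' absent). Indirect effect: the sum of path products over directed paths of
#' length at least two. Total: their sum.
#'
#' @inheritParams enumerate_paths
#' @return one-row tibble: `outcome`, `causal`, `direct`, `indirect`,
#'   `total`.
#' @export
decompose_effects <- function(edges, source, target, max_len = NULL) {
  g <- edges_to_graph(edges)
  if (source %in% igraph::V(g)$name && target %in% igraph::V(g)$name) {
    check_acyclic_between(g, source, target)
  }
  ps <- suppressWarnings(enumerate_paths(edges, source, target, max_len))
  direct <- sum(ps$product[ps$length == 1])
  indirect <- sum(ps$product[ps$length >= 2])
  tibble::tibble(outcome = target, causal = source, direct = direct,
                 indirect = indirect, total = direct + indirect)
}

#' Total effect by intervention regression
#'
#' In the linear-Gaussian model the derivative of `E[Y | do(X = x)]` equals
#' the coefficient of `X` in the least-squares regression of the outcome on
#' `X` and the parents of `X` in the network. Sources without parents (SNPs
#' and genes, which have no incoming edges) reduce to the simple marginal
#' regression.
#'
#' @param data data frame or matrix of observations containing `source`,
#'   `outcome`, and any `parents` columns.
#' @param source,outcome column names.
#' @param parents character vector of the source's parents in the network
#'   (empty for genotype sources).
#' @return the estimated total effect (a single number).
#' @export
total_effect_intervention <- function(data, source, outcome,
                                      parents = character(0)) {
  df <- as.data.frame(data)
  vars <- c(source, parents)
  Xm <- cbind(1, as.matrix(df[vars]))
  qr_x <- qr(Xm)
  if (qr_x$rank < ncol(Xm)) {
    stop("collinear parent set for ", source, call. = FALSE)
  }
  coefs <- qr.coef(qr_x, df[[outcome]])
  unname(coefs[2])
}

#' Marginal effect (simple-regression slope)
#'
#' @param data data frame or matrix of observations.
#' @param source,outcome column names.
#' @return slope of the least-squares regression of `outcome` on `source`.
#' @export
marginal_effect <- function(data, source, outcome) {
  df <- as.data.frame(data)
  x <- df[[source]]
  y <- df[[outcome]]
  vx <- stats::var(x)
  if (!is.finite(vx) || vx <= 0) {
    stop("source ", source, " has zero variance", call. = FALSE)
  }
  stats::cov(x, y) / vx
}

#' Adjusted regression coefficient from pairwise correlations
#'
#' Expresses the coefficient of `X` in the regression of `Y` on `X` and a
#' single adjustment variable `Z` through the pairwise correlations:
#' `beta_YX.Z = beta_YX * (1 - rho_YZ rho_ZX / rho_YX) / (1 - rho_XZ^2)`.
#' With `rho_XZ = 0` (or no `Z`) this reduces to the marginal slope.
#'
#' @param data data frame or matrix of observations.
#' @param source,outcome,z column names (`z` may be `NULL`).
#' @return the adjusted coefficient.
#' @export
beta_adjusted <- function(data, source, outcome, z = NULL) {
  if (is.null(z)) return(marginal_effect(data, source, outcome))
  df <- as.data.frame(data)
  x <- df[[source]]; y <- df[[outcome]]; zz <- df[[z]]
  b_yx <- marginal_effect(data, source, outcome)
  r_yz <- stats::cor(y, zz)
  r_zx <- stats::cor(zz, x)
  r_yx <- stats::cor(y, x)
  b_yx * (1 - r_yz * r_zx / r_yx) / (1 - r_zx^2)
}

#' Effect table over causal-outcome pairs
#'
#' Builds the standard report with one row per (causal, outcome) pair:
#' direct, indirect and total effects from the network's path algebra, plus
#' the marginal (simple-regression) effect when observation data are
#' supplied. Pairs connected through a cyclic route are flagged in the
#' `cyclic` column and get `NA` effects rather than a guess.
#'
#' @param edges network edge tibble (`from`, `to`, `coefficient`).
#' @param data optional observations for the marginal effects.
#' @param pairs optional two-column data frame (`causal`, `outcome`)
#'   restricting the table; defaults to every ordered pair connected by at
#'   least one directed path.
#' @param digits rounding applied to the report columns (`NULL` for none).
#' @return tibble: `outcome`, `causal`, `direct`, `indirect`, `total`,
#'   `marginal`, `cyclic`.
#' @export
effect_table <- function(edges, data = NULL, pairs = NULL, digits = 4) {
  g <- edges_to_graph(edges)
  nodes <- igraph::V(g)$name
  if (is.null(pairs)) {
    dmat <- igraph::distances(g, mode = "out")
    idx <- which(is.finite(dmat) & dmat > 0, arr.ind = TRUE)
    pairs <- tibble::tibble(causal = nodes[idx[, 1]],
                            outcome = nodes[idx[, 2]])
  }
  rows <- purrr::pmap(pairs[, c("causal", "outcome")], function(causal,
                                                               outcome) {
    dec <- tryCatch(
      suppressWarnings(decompose_effects(edges, causal, outcome)),
      error = function(e) {
        tibble::tibble(outcome = outcome, causal = causal,
                       direct = NA_real_, indirect = NA_real_,
                       total = NA_real_)
      })
    dec$cyclic <- is.na(dec$total)
    dec$marginal <- if (!is.null(data) && causal %in% colnames(data) &&
                        outcome %in% colnames(data)) {
      marginal_effect(data, causal, outcome)
    } else NA_real_
    dec
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::select("outcome", "causal", "direct", "indirect", "total",
                  "marginal", "cyclic")
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(
      c("direct", "indirect", "total", "marginal"), ~ round(.x, digits)))
  }
  out
}

#' Closed-form total effects among phenotypes
#'
#' On an acyclic phenotype coefficient matrix (diagonal -1) the matrix of
#' total effects is the convergent Neumann series of path products; entry
#' (j, i) is the total effect of phenotype j on phenotype i. Used as an
#' independent cross-check of the path enumeration.
#'
#' @param Gamma M x M phenotype coefficient matrix with diagonal -1.
#' @return M x M matrix of total effects (zero diagonal).
#' @export
total_effect_matrix <- function(Gamma) {
  M <- ncol(Gamma)
  A <- Gamma
  diag(A) <- 0  # adjacency of path coefficients, edge j -> i at [j, i]
  tot <- solve(diag(M) - A) - diag(M)
  dimnames(tot) <- dimnames(Gamma)
  tot
}
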