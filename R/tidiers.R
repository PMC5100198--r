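# broom-style methods and ggplot2 displays for fitted objects.

#' Tidy a fitted sparse SEM
#'
#' One row per nonzero path coefficient: phenotype-to-phenotype edges first,
#' then exogenous (genotype or FPC score) edges.
#'
#' @param x a `sem_fit`.
#' @param ... unused.
#' @return tibble with `from`, `to`, `type`, `estimate`.
#' @export
tidy.sem_fit <- function(x, ...) {
  support_edges(x) |>
    dplyr::rename(estimate = "coefficient")
}

#' One-row summary of a fitted sparse SEM
#'
#' @param x a `sem_fit`.
#' @param ... unused.
#' @return tibble with sample size, dimensions, edge counts, the penalty
#'   range, and the convergence status of the per-equation ADMM runs.
#' @export
glance.sem_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_phenotypes = length(x$phenotypes),
    n_exogenous = length(x$exogenous),
    n_phenotype_edges = sum(x$support_Gamma),
    n_genotype_edges = sum(x$support_B),
    lambda_min = min(x$lambda), lambda_max = max(x$lambda),
    all_converged = all(x$converged, na.rm = TRUE),
    mean_sigma2 = mean(x$sigma2))
}

#' @export
print.sem_fit <- function(x, ...) {
  g <- glance(x)
  cat("<", class(x)[1], "> ", g$n_phenotypes, " phenotypes, ",
      g$n_exogenous, " exogenous columns, n = ", g$n, "\n",
      "  edges: ", g$n_phenotype_edges, " phenotype -> phenotype, ",
      g$n_genotype_edges, " genotype -> phenotype\n",
      "  lambda in [", signif(g$lambda_min, 3), ", ",
      signif(g$lambda_max, 3), "]",
      if (!g$all_converged) "  (some equations not converged)", "\n",
      sep = "")
  invisible(x)
}

#' Plot a fitted genotype-phenotype network
#'
#' Phenotype nodes are placed on an inner circle and exogenous nodes on an
#' outer circle; edge width scales with the path-coefficient magnitude and
#' colour with its sign.
#'
#' @param object a `sem_fit`.
#' @param level `"column"` or `"gene"` edges.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sem_fit <- function(object, level = "column", ...) {
  edges <- support_edges(object, level = level)
  exo <- unique(edges$from[edges$type == "genotype"])
  phen <- object$phenotypes
  layout <- dplyr::bind_rows(
    tibble::tibble(node = phen,
                   angle = 2 * pi * seq_along(phen) / max(length(phen), 1),
                   r = 1),
    tibble::tibble(node = exo,
                   angle = 2 * pi * seq_along(exo) / max(length(exo), 1),
                   r = 2)) |>
    dplyr::mutate(x = .data$r * cos(.data$angle),
                  y = .data$r * sin(.data$angle))
  seg <- edges |>
    dplyr::left_join(layout, by = c(from = "node")) |>
    dplyr::left_join(layout, by = c(to = "node"),
                     suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to,
                   yend = .data$y_to, linewidth = abs(.data$coefficient),
                   colour = .data$coefficient > 0),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      alpha = 0.7) +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(.data$x, .data$y), size = 2) +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(.data$x, .data$y, label = .data$node),
                       vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                            `FALSE` = "#b2182b"),
                                 labels = c(`TRUE` = "positive",
                                            `FALSE` = "negative"),
                                 name = "sign") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot the eigenfunctions of a gene's FPC basis
#'
#' @param object an `fpc_basis`.
#' @param ... unused.
#' @return a ggplot object: one line per retained component over the
#'   rescaled position grid.
#' @export
autoplot.fpc_basis <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(grid = object$grid),
                     tibble::as_tibble(object$eigenfunctions,
                                       .name_repair = ~ paste0(
                                         "FPC", seq_along(.x)))),
    -"grid", names_to = "component", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$grid, .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "rescaled position", y = "eigenfunction",
                  title = paste("Gene", object$gene_id)) +
    ggplot2::theme_minimal()
}

#' Plot an effect decomposition table
#'
#' @param effects tibble from [effect_table()].
#' @return a ggplot bar chart of direct/indirect/total per pair.
#' @export
plot_effects <- function(effects) {
  df <- effects |>
    dplyr::mutate(pair = paste(.data$causal, "→", .data$outcome)) |>
    tidyr::pivot_longer(c("direct", "indirect", "total"),
                        names_to = "component", values_to = "effect")
  ggplot2::ggplot(df, ggplot2::aes(.data$pair, .data$effect,
                                   fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "effect") +
    ggplot2::theme_minimal()
}
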