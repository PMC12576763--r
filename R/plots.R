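# ggplot2 views of the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.mcl_partition <- function(object, ...) {
  sizes <- tibble(module = as.integer(names(attr(object, "sizes"))),
                  size = as.integer(attr(object, "sizes")))
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$module, y = .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "module (size rank)", y = "genes",
                  title = "Co-expression module sizes") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.coex_screen <- function(object, ...) {
  d <- dplyr::mutate(as_tibble(object),
                     label = dplyr::if_else(.data$selected, "*", ""))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$variable, y = .data$module,
                                  fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 5) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  limits = c(-1, 1), na.value = "grey80") +
    ggplot2::labs(x = NULL, y = "module", fill = "Spearman rho",
                  title = "Module-trait screen (* selected)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.null_model_comparison <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$model, y = .data$kl,
                               fill = .data$best)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "KL divergence (observed || model)",
                  title = "Null-model spectral fit") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.set_intersection <- function(object, ...) {
  d <- dplyr::mutate(as_tibble(object),
                     combination = factor(.data$combination,
                                          levels = rev(.data$combination)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size, y = .data$combination)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "genes", y = NULL,
                  title = "Exclusive DEG-set intersections") +
    ggplot2::theme_minimal()
}

#' Degree distribution of a graph
#' @param g An igraph graph.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(g) {
  d <- tibble(degree = igraph::degree(g))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "degree", y = "nodes", title = "Degree distribution") +
    ggplot2::theme_minimal()
}

#' Spectral densities of an observed graph and a fitted model
#' @param obs,model Tibbles from [spectral_density()].
#' @return A ggplot object.
#' @export
plot_spectral_densities <- function(obs, model) {
  d <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(obs), which = "observed"),
    dplyr::mutate(as_tibble(model), which = "model")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$density,
                                  colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "scaled adjacency eigenvalue", y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
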