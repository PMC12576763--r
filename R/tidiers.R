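# broom-style tidiers for the pipeline's result objects.

#' @exportS3Method generics::tidy
tidy.mcl_partition <- function(x, ...) {
  tibble(gene_id = x$gene_id, module = x$module)
}

#' @exportS3Method generics::glance
glance.mcl_partition <- function(x, ...) {
  dplyr::mutate(module_size_stats(x),
                inflation = attr(x, "inflation"),
                iterations = attr(x, "iterations"))
}

#' @exportS3Method generics::tidy
tidy.coex_screen <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.coex_screen <- function(x, ...) {
  tibble(
    n_modules = length(unique(x$module)),
    n_variables = length(unique(x$variable)),
    m = attr(x, "m"),
    rho_cut = attr(x, "rho_cut"),
    alpha = attr(x, "alpha"),
    n_selected = sum(x$selected)
  )
}

#' @exportS3Method generics::tidy
tidy.set_intersection <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.set_intersection <- function(x, ...) {
  tibble(n_sets = length(attr(x, "sets")),
         n_classes = nrow(x),
         union_size = sum(x$size),
         core_size = length(attr(x, "core")))
}

#' @exportS3Method generics::tidy
tidy.graph_model_fit <- function(x, ...) attr(x, "grid_fits")

#' @exportS3Method generics::glance
glance.graph_model_fit <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::tidy
tidy.null_model_comparison <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.null_model_comparison <- function(x, ...) {
  best <- x[x$best, ]
  tibble(best_model = best$model, best_param = best$best_param,
         kl = best$kl)
}

#' @exportS3Method generics::tidy
tidy.enrichment_result <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.enrichment_result <- function(x, ...) {
  tibble(n_terms = nrow(x), n_enriched = sum(x$enriched),
         universe_size = attr(x, "universe_size"),
         set_size = attr(x, "set_size"))
}

#' @exportS3Method generics::tidy
tidy.eigengene <- function(x, ...) {
  tibble(sample_id = names(x$scores), score = as.numeric(x$scores))
}

#' @exportS3Method generics::glance
glance.eigengene <- function(x, ...) {
  tibble(module = x$module_label, n_genes = length(x$members),
         var_explained = x$var_explained, sign = x$sign)
}
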