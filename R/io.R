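# TSV readers/writers for the pipeline's tabular artifacts. All tables are
# written with headers; the expression matrix has gene rows and sample
# columns with a leading gene_id column.

#' Write / read an expression matrix TSV
#' @param x Genes x samples numeric matrix.
#' @param path Output file.
#' @return `path`, invisibly (writer); the matrix (reader).
#' @export
write_expression_tsv <- function(x, path) {
  assert_expression(x)
  df <- dplyr::bind_cols(tibble(gene_id = rownames(x)), as_tibble(x))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$gene_id
  m
}

#' Write / read a design, trait or annotation table TSV
#' @param x A tibble.
#' @param path File path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_design_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    genotype = readr::col_factor(c("R", "NR")),
                    nitrogen = readr::col_factor(c("10", "270")),
                    segment = readr::col_factor(c("B0", "B", "M", "P")),
                    .default = readr::col_guess()
                  ))
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a co-expression graph as edge-list TSV and GraphML
#' @param g igraph graph.
#' @param path Edge-list TSV path.
#' @return `path` invisibly.
#' @export
write_edges_tsv <- function(g, path) {
  readr::write_tsv(as_edge_tibble(g), path)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path) {
  e <- readr::read_tsv(path, show_col_types = FALSE)
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  igraph::E(g)$weight <- abs(igraph::E(g)$r)
  g
}

#' @rdname write_edges_tsv
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
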