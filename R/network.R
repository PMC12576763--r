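#' Gene-gene Pearson correlation matrix
#'
#' Correlation of every gene pair across samples, the basis of the hard-
#' thresholded co-expression network. Missing values are handled by
#' pairwise-complete observations. Zero-variance genes must be removed
#' upstream ([filter_genes()]); encountering one is an error that names the
#' gene. The computation may be carried out in row blocks (`block_size`) to
#' bound memory; the result is independent of the block size.
#'
#' @param x Expression matrix (genes x samples), >= 3 samples.
#' @param block_size Optional number of genes per block.
#' @return A symmetric genes x genes correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(x, block_size = NULL) {
  assert_expression(x)
  if (ncol(x) < 3) abort("need at least 3 samples for correlation")
  v <- apply(x, 1, function(r) var(r[!is.na(r)]))
  if (any(bad <- (is.na(v) | v == 0))) {
    abort(paste0("zero-variance gene(s) in correlation input: ",
                 paste(head(rownames(x)[bad], 5), collapse = ", ")))
  }
  use <- if (anyNA(x)) "pairwise.complete.obs" else "everything"
  if (is.null(block_size) || block_size >= nrow(x)) {
    r <- cor(t(x), use = use)
  } else {
    n <- nrow(x)
    r <- matrix(NA_real_, n, n, dimnames = list(rownames(x), rownames(x)))
    starts <- seq(1, n, by = block_size)
    for (s in starts) {
      idx <- s:min(s + block_size - 1, n)
      r[idx, ] <- cor(t(x[idx, , drop = FALSE]), t(x), use = use)
    }
  }
  diag(r) <- 1
  r
}

#' Hard-threshold a correlation matrix into a co-expression graph
#'
#' Keeps an edge between genes i and j iff `|r_ij| > threshold` (strict
#' inequality; a correlation exactly at the threshold is excluded). The
#' signed correlation is stored as edge attribute `r` and its absolute value
#' as `weight`. Genes left without any edge are dropped by default, so the
#' node count reports connected genes.
#'
#' @param r Symmetric correlation matrix with dimnames.
#' @param threshold Absolute-correlation threshold in \[0, 1) (default 0.90).
#' @param drop_isolated Drop isolated nodes (default `TRUE`).
#' @return An undirected [igraph::igraph] graph with graph attribute
#'   `threshold`.
#' @export
threshold_graph <- function(r, threshold = 0.90, drop_isolated = TRUE) {
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8))) {
    abort("`r` must be a symmetric correlation matrix")
  }
  if (threshold < 0 || threshold >= 1) abort("`threshold` must be in [0, 1)")
  idx <- which(upper.tri(r) & abs(r) > threshold & is.finite(r),
               arr.ind = TRUE)
  vals <- r[idx]
  edges <- tibble(
    from = rownames(r)[idx[, 1]],
    to = colnames(r)[idx[, 2]],
    r = vals,
    weight = abs(vals)
  )
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = tibble(name = rownames(r))
  )
  if (drop_isolated) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  }
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Basic topology of a co-expression graph
#'
#' @param g An igraph graph.
#' @return A one-row tibble: `n_nodes`, `n_edges`, `n_components`,
#'   `giant_pct` (largest-component node share, percent), and `degrees`
#'   (list column with the named degree sequence). An empty graph yields
#'   zeros.
#' @export
topology_summary <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) {
    return(tibble(n_nodes = 0L, n_edges = 0L, n_components = 0L,
                  giant_pct = 0, degrees = list(integer())))
  }
  comp <- igraph::components(g)
  tibble(
    n_nodes = n,
    n_edges = igraph::ecount(g),
    n_components = comp$no,
    giant_pct = share_pct(max(comp$csize), n, digits = 2),
    degrees = list(igraph::degree(g))
  )
}

#' Edge list of a co-expression graph as a tibble
#'
#' @param g An igraph graph with an `r` edge attribute (as produced by
#'   [threshold_graph()]); plain graphs get `r = 1`.
#' @return A tibble `from`, `to`, `r` with `from < to` lexicographically.
#' @export
as_edge_tibble <- function(g) {
  if (igraph::ecount(g) == 0) {
    return(tibble(from = character(), to = character(), r = numeric()))
  }
  e <- igraph::as_data_frame(g, what = "edges")
  if (is.null(e$r)) e$r <- 1
  tibble(
    from = pmin(e$from, e$to),
    to = pmax(e$from, e$to),
    r = e$r
  ) |>
    dplyr::arrange(.data$from, .data$to)
}
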