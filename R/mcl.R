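#' Markov clustering of a co-expression graph
#'
#' From-scratch implementation of the Markov Cluster Algorithm (MCL). The
#' graph's nonnegative edge weights (absolute correlations for a
#' co-expression network) plus a self-loop of weight `self_loop_weight` on
#' every node form a column-stochastic flow matrix, which is alternately
#' expanded (matrix power `expansion`), inflated (entrywise power `inflation`
#' followed by column renormalization) and pruned (entries below
#' `prune_threshold` removed, columns renormalized) until the largest
#' entrywise change falls below `tol`. Clusters are read off the limit
#' matrix: attractor nodes (positive diagonal mass) are grouped into
#' attractor systems; every node is assigned to the system holding most of
#' its limiting flow, ties resolved deterministically toward the attractor
#' system containing the lexicographically smallest gene id.
#' Larger inflation gives finer clusters; 1.8 is the
#' default used for the nitrogen-response network.
#'
#' Module labels are positive integers ordered by decreasing module size,
#' ties broken by the lexicographically smallest member gene id, so the
#' numbering is reproducible.
#'
#' @param g An igraph graph; edge attribute `weight` is used when present
#'   (must be nonnegative), otherwise unit weights.
#' @param inflation Inflation exponent (> 1; default 1.8).
#' @param expansion Expansion power (integer >= 2; default 2).
#' @param self_loop_weight Self-loop weight added to every node (default 1).
#' @param prune_threshold Entries below this are dropped after each
#'   inflation (default 1e-5).
#' @param tol Convergence tolerance on the max entrywise change
#'   (default 1e-6).
#' @param max_iter Maximum iterations (default 200); non-convergence is an
#'   error carrying the residual.
#' @return An object of class `mcl_partition`: a tibble `gene_id`, `module`
#'   with attributes `sizes` (named integer vector), `inflation`,
#'   `iterations`.
#' @export
mcl_cluster <- function(g, inflation = 1.8, expansion = 2,
                        self_loop_weight = 1.0, prune_threshold = 1e-5,
                        tol = 1e-6, max_iter = 200) {
  if (inflation <= 1) abort("`inflation` must be > 1")
  if (expansion < 2 || expansion != as.integer(expansion)) {
    abort("`expansion` must be an integer >= 2")
  }
  n <- igraph::vcount(g)
  if (n == 0) abort("empty graph")
  nodes <- igraph::V(g)$name %||% as.character(seq_len(n))
  w <- igraph::E(g)$weight
  if (!is.null(w) && any(w < 0)) abort("negative edge weight in MCL input")
  A <- igraph::as_adjacency_matrix(
    g, attr = if (!is.null(w)) "weight" else NULL, sparse = TRUE)
  A <- methods::as(A, "CsparseMatrix") * 1.0
  Matrix::diag(A) <- Matrix::diag(A) + self_loop_weight

  col_normalize <- function(m) {
    cs <- Matrix::colSums(m)
    if (any(cs == 0)) abort("zero column sum during MCL normalization")
    m %*% Matrix::Diagonal(x = 1 / cs)
  }
  prune <- function(m) {
    m <- Matrix::drop0(m * (abs(m) >= prune_threshold))
    # keep at least the column maximum so no column empties out
    cs <- Matrix::colSums(m)
    if (any(cs == 0)) abort("pruning emptied a column; lower prune_threshold")
    m
  }

  M <- col_normalize(A)
  it <- 0L
  repeat {
    it <- it + 1L
    Mexp <- M
    for (k in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp
    Minf@x <- Minf@x^inflation
    Minf <- col_normalize(prune(col_normalize(Minf)))
    resid <- max(abs(Minf - M))
    M <- Minf
    if (resid < tol) break
    if (it >= max_iter) {
      abort(sprintf("MCL did not converge in %d iterations (residual %.3g)",
                    max_iter, resid))
    }
  }

  Md <- as.matrix(M)
  attractors <- which(diag(Md) > prune_threshold)
  if (length(attractors) == 0) attractors <- seq_len(n)
  # attractor systems: connected components of the limit matrix restricted
  # to attractor nodes (symmetrized support)
  sub <- Md[attractors, attractors, drop = FALSE]
  supp <- ((sub > 0) | (t(sub) > 0)) * 1
  ag <- igraph::graph_from_adjacency_matrix(supp, mode = "max", diag = FALSE)
  sys_of_attr <- igraph::components(ag)$membership
  n_sys <- max(sys_of_attr)
  # limiting mass of each node in each attractor system
  mass <- matrix(0, nrow = n_sys, ncol = n)
  for (s in seq_len(n_sys)) {
    rows <- attractors[sys_of_attr == s]
    mass[s, ] <- colSums(Md[rows, , drop = FALSE])
  }
  # deterministic tie-break: larger eventual module first, then smallest
  # member gene id of the system's attractors
  sys_key <- vapply(seq_len(n_sys), function(s) {
    min(nodes[attractors[sys_of_attr == s]])
  }, character(1))
  assign_sys <- apply(mass, 2, function(col) {
    top <- which(col == max(col))
    if (length(top) > 1) top <- top[order(sys_key[top])][1]
    top
  })

  membership <- tibble(gene_id = nodes, sys = as.integer(assign_sys))
  size_tbl <- membership |>
    dplyr::group_by(.data$sys) |>
    dplyr::summarise(size = dplyr::n(), min_gene = min(.data$gene_id),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$min_gene) |>
    dplyr::mutate(module = dplyr::row_number())
  out <- membership |>
    dplyr::left_join(size_tbl[, c("sys", "module")], by = "sys") |>
    dplyr::select("gene_id", "module") |>
    dplyr::arrange(.data$module, .data$gene_id)
  sizes <- table(out$module)
  attr(out, "sizes") <- stats::setNames(as.integer(sizes), names(sizes))
  attr(out, "inflation") <- inflation
  attr(out, "iterations") <- it
  class(out) <- c("mcl_partition", class(out))
  out
}

#' Module size statistics
#'
#' Summary arithmetic over a module partition: module count, size range, the
#' node share of the largest and second-largest modules (percent of all
#' network nodes), and how many modules exceed 10 nodes.
#'
#' @param partition An `mcl_partition` (or any tibble with `gene_id`,
#'   `module`).
#' @param n_network_nodes Node count used as the share denominator; defaults
#'   to the number of clustered genes.
#' @return A one-row tibble: `n_modules`, `min_size`, `max_size`,
#'   `largest_share_pct`, `second_share_pct`, `n_over_10`, `pct_over_10`.
#' @export
#' @examples
#' p <- tibble::tibble(gene_id = as.character(1:5),
#'                     module = c(1L, 1L, 1L, 2L, 2L))
#' module_size_stats(p)
module_size_stats <- function(partition, n_network_nodes = NULL) {
  if (nrow(partition) == 0) abort("empty partition")
  sizes <- sort(as.integer(table(partition$module)), decreasing = TRUE)
  n_nodes <- n_network_nodes %||% nrow(partition)
  tibble(
    n_modules = length(sizes),
    min_size = min(sizes),
    max_size = max(sizes),
    largest_share_pct = share_pct(sizes[1], n_nodes),
    second_share_pct = if (length(sizes) >= 2) share_pct(sizes[2], n_nodes)
                       else NA_real_,
    n_over_10 = sum(sizes > 10),
    pct_over_10 = share_pct(sum(sizes > 10), length(sizes))
  )
}

#' Convert a partition to a named membership vector
#' @param partition An `mcl_partition`.
#' @return Named integer vector gene_id -> module.
#' @export
partition_membership <- function(partition) {
  stats::setNames(partition$module, partition$gene_id)
}

#' @export
print.mcl_partition <- function(x, ...) {
  cat("<mcl_partition> ", nrow(x), " genes in ",
      length(attr(x, "sizes")), " modules (inflation ",
      attr(x, "inflation"), ")\n", sep = "")
  NextMethod()
}
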