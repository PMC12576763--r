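# Top-fraction score cutoff: the floor(f*n)-th largest value (>= 1st), so
# exactly the top decile qualifies on tie-free scores while boundary ties
# are all kept.
top_cutoff <- function(x, f) {
  k <- max(1L, floor(f * length(x)))
  sort(x, decreasing = TRUE)[k]
}

# Centrality table for one (sub)graph.
centrality_one <- function(g, top_fraction) {
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA)  # unweighted shortest paths
  qd <- top_cutoff(deg, top_fraction)
  qb <- top_cutoff(btw, top_fraction)
  tibble(
    gene_id = igraph::V(g)$name %||% as.character(seq_len(n)),
    degree = as.integer(deg),
    betweenness = as.numeric(btw),
    degree_rank_pct = 100 * rank(deg, ties.method = "max") / n,
    betweenness_rank_pct = 100 * rank(btw, ties.method = "max") / n,
    hub = deg >= qd & btw >= qb
  )
}

#' Degree/betweenness centrality and hub calling
#'
#' Hubs are nodes in the top `top_fraction` (default 10 percent) of both
#' degree (connectivity) and unweighted shortest-path betweenness
#' (centrality). The cutoff for each score is its `floor(f * n)`-th largest
#' value (at least the largest); a node qualifies with `>=`, and all ties at
#' the cutoff are kept,
#' so on degenerate graphs (e.g. a regular ring where every node ties) the
#' hub set can exceed the nominal fraction. With `scope = "per_module"` the
#' scores and cutoffs are computed within each module's induced subgraph,
#' which is the default whenever a partition is supplied (hubs of a module
#' are its locally central genes); `scope = "global"` ranks in the full
#' graph. Betweenness is unnormalized (sum over unordered pairs of the
#' fraction of shortest paths through the node); hub calls are invariant to
#' the normalization convention.
#'
#' @param g An igraph graph.
#' @param partition Optional `mcl_partition`; required for
#'   `scope = "per_module"`.
#' @param top_fraction Fraction defining "top" for both scores, in (0, 1).
#' @param scope `"global"` or `"per_module"`; default per-module when a
#'   partition is given.
#' @return A tibble of class `centrality_table`: `gene_id`, (`module`,)
#'   `degree`, `betweenness`, `degree_rank_pct`, `betweenness_rank_pct`,
#'   `hub`.
#' @export
call_hubs <- function(g, partition = NULL, top_fraction = 0.10,
                      scope = NULL) {
  if (igraph::vcount(g) == 0) abort("empty graph")
  if (top_fraction <= 0 || top_fraction >= 1) {
    abort("`top_fraction` must be in (0, 1)")
  }
  scope <- scope %||% if (!is.null(partition)) "per_module" else "global"
  scope <- match.arg(scope, c("global", "per_module"))
  if (scope == "global") {
    out <- centrality_one(g, top_fraction)
    if (!is.null(partition)) {
      out <- dplyr::left_join(out, tibble(gene_id = partition$gene_id,
                                          module = partition$module),
                              by = "gene_id")
    }
  } else {
    if (is.null(partition)) abort("per-module scope needs a `partition`")
    mods <- sort(unique(partition$module))
    out <- purrr::map(mods, function(m) {
      members <- partition$gene_id[partition$module == m]
      sub <- igraph::induced_subgraph(g, members)
      centrality_one(sub, top_fraction) |>
        dplyr::mutate(module = m, .after = "gene_id")
    }) |>
      dplyr::bind_rows()
  }
  class(out) <- c("centrality_table", class(out))
  out
}
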