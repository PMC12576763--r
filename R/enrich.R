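#' Fisher's-exact overrepresentation test
#'
#' One-sided hypergeometric upper-tail test per annotation term: for a gene
#' set of size n drawn from a universe of size N in which K genes carry the
#' term and a of them fall in the set, the p-value is
#' `P(X >= a)` for `X ~ Hypergeom(N, K, n)` — the one-sided Fisher exact
#' test of the 2x2 table. P-values are Benjamini-Hochberg adjusted across
#' terms within the gene set; a term is enriched iff `padj < alpha`.
#'
#' @param gene_set Character vector of gene ids (must be inside `universe`).
#' @param annotations Tibble `gene_id`, `term_id` (and optionally
#'   `term_type`); pairs are deduplicated.
#' @param universe Character vector of background gene ids; default the
#'   union of annotated genes and the gene set.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return A tibble of class `enrichment_result`: `term_id`, `a`, `b`, `c`,
#'   `d` (the 2x2 table: set/term, set/no-term, term/no-set, neither), `p`,
#'   `padj`, `enriched`, sorted by p.
#' @export
fisher_enrichment <- function(gene_set, annotations, universe = NULL,
                              alpha = 0.05) {
  ann <- dplyr::distinct(as_tibble(annotations)[, c("gene_id", "term_id")])
  universe <- universe %||% union(unique(ann$gene_id), gene_set)
  if (length(universe) == 0) abort("empty universe")
  if (!all(gene_set %in% universe)) abort("gene_set must be within the universe")
  gene_set <- unique(gene_set)
  ann <- ann[ann$gene_id %in% universe, ]
  N <- length(universe)
  n <- length(gene_set)
  out <- ann |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(K = dplyr::n(),
                     a = sum(.data$gene_id %in% gene_set),
                     .groups = "drop") |>
    dplyr::mutate(
      b = n - .data$a,
      c = .data$K - .data$a,
      d = N - .data$K - .data$b,
      p = phyper(.data$a - 1, .data$K, N - .data$K, n, lower.tail = FALSE)
    ) |>
    dplyr::mutate(padj = p.adjust(.data$p, method = "BH"),
                  enriched = .data$padj < alpha) |>
    dplyr::select("term_id", "a", "b", "c", "d", "p", "padj", "enriched") |>
    dplyr::arrange(.data$p, .data$term_id)
  attr(out, "universe_size") <- N
  attr(out, "set_size") <- n
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Family composition test for transcription-associated proteins
#'
#' Tests whether a TAP family is overrepresented among a set of TAP genes
#' relative to background family frequencies: per family, an exact binomial
#' upper-tail test of the observed count at the background frequency. The
#' observed proportion is reported exactly (observed / total).
#'
#' @param tap_genes Tibble `gene_id`, `family`.
#' @param background_freqs Named numeric vector of family frequencies
#'   summing to 1; every observed family must be present.
#' @param alpha Significance level used for the `overrepresented` flag
#'   (default 0.01).
#' @return A tibble: `family`, `observed`, `total`, `proportion`,
#'   `background`, `p`, `overrepresented`, sorted by p.
#' @export
tap_composition_test <- function(tap_genes, background_freqs, alpha = 0.01) {
  if (abs(sum(background_freqs) - 1) > 1e-8) {
    abort("background frequencies must sum to 1")
  }
  tab <- table(tap_genes$family)
  missing <- setdiff(names(tab), names(background_freqs))
  if (length(missing) > 0) {
    abort(paste0("family missing from background: ",
                 paste(missing, collapse = ", ")))
  }
  total <- nrow(tap_genes)
  purrr::map(names(tab), function(fam) {
    k <- as.integer(tab[[fam]])
    p0 <- background_freqs[[fam]]
    tibble(
      family = fam, observed = k, total = total,
      proportion = k / total, background = p0,
      p = binom.test(k, total, p0, alternative = "greater")$p.value
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(overrepresented = .data$p < alpha) |>
    dplyr::arrange(.data$p, .data$family)
}
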