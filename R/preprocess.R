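#' Filter genes by missingness and variance
#'
#' Removes genes with more than `max_missing_fraction` missing entries or
#' zero variance over their non-missing entries, mirroring the
#' good-samples-genes pre-filter applied before correlation-network
#' inference. The sample set is unchanged; the operation is idempotent.
#'
#' @param x Expression matrix (genes x samples) with gene rownames.
#' @param max_missing_fraction Maximum tolerated missing fraction per gene
#'   (default 0.5: a gene with more than half of its entries missing is
#'   dropped).
#' @return The filtered matrix. Errors if every gene would be removed.
#' @export
filter_genes <- function(x, max_missing_fraction = 0.5) {
  assert_expression(x)
  if (nrow(x) == 0) abort("expression matrix has no genes")
  miss <- rowMeans(is.na(x))
  v <- apply(x, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2) 0 else var(r)
  })
  keep <- miss <= max_missing_fraction & v > 0
  if (!any(keep)) abort("all genes removed by the missingness/variance filter")
  x[keep, , drop = FALSE]
}

#' The eight nitrogen contrasts of the factorial design
#'
#' Every genotype x leaf-segment cell is contrasted across nitrogen levels
#' (10 vs 270 mg N per kg sand), holding genotype and segment fixed — eight
#' contrasts in the 2 x 4 layout.
#'
#' @param design Design tibble.
#' @return A tibble with columns `genotype`, `segment`, `contrast_id`.
#' @export
deg_contrasts <- function(design) {
  assert_design(design)
  design |>
    dplyr::distinct(.data$genotype, .data$segment) |>
    dplyr::arrange(.data$genotype, .data$segment) |>
    dplyr::mutate(contrast_id = paste0(.data$genotype, "-", .data$segment,
                                       "-10 vs ", .data$genotype, "-",
                                       .data$segment, "-270"))
}

#' Differential expression for one nitrogen contrast
#'
#' A transparent surrogate differential-expression test operating directly on
#' the variance-stabilized matrix: per gene, a Welch two-sample t-test of the
#' high-nitrogen (270) against the low-nitrogen (10) samples within one
#' genotype x segment cell, Benjamini-Hochberg adjustment across genes, and a
#' gene is flagged as differential iff `padj < alpha` AND
#' `|effect| > lfc_threshold` (strict), where `effect` is the mean difference
#' (270 minus 10) on the transformed scale. Direction `"up"` means higher
#' expression at 270, `"down"` higher at 10. This deliberately replaces a
#' negative-binomial count model: it consumes the same matrix the network
#' stage uses, and its outputs are gene sets, not effect estimates.
#'
#' @param x Expression matrix (genes x samples).
#' @param design Design tibble covering the matrix columns.
#' @param genotype,segment The cell defining the contrast.
#' @param lfc_threshold Minimum absolute mean difference (default 1).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return A tibble `gene_id`, `effect`, `p`, `padj`, `deg`, `direction` with
#'   attribute `contrast_id`.
#' @export
select_degs <- function(x, design, genotype, segment,
                        lfc_threshold = 1, alpha = 0.05) {
  assert_expression(x)
  assert_design(design)
  cell <- design[design$genotype == genotype & design$segment == segment, ]
  lo <- cell$sample_id[cell$nitrogen == "10"]
  hi <- cell$sample_id[cell$nitrogen == "270"]
  if (length(lo) < 2 || length(hi) < 2) {
    abort("fewer than 2 samples per nitrogen level in this contrast")
  }
  xl <- x[, lo, drop = FALSE]
  xh <- x[, hi, drop = FALSE]
  res <- purrr::map(seq_len(nrow(x)), function(i) {
    a <- xh[i, ][!is.na(xh[i, ])]
    b <- xl[i, ][!is.na(xl[i, ])]
    if (length(a) < 2 || length(b) < 2) {
      return(c(effect = NA_real_, p = NA_real_))
    }
    eff <- mean(a) - mean(b)
    p <- tryCatch(t.test(a, b, var.equal = FALSE)$p.value,
                  error = function(e) NA_real_)
    c(effect = eff, p = p)
  })
  res <- do.call(rbind, res)
  out <- tibble(
    gene_id = rownames(x),
    effect = res[, "effect"],
    p = res[, "p"],
    padj = p.adjust(res[, "p"], method = "BH")
  ) |>
    dplyr::mutate(
      deg = !is.na(.data$padj) & .data$padj < alpha &
        abs(.data$effect) > lfc_threshold,
      direction = dplyr::if_else(.data$effect >= 0, "up", "down")
    )
  attr(out, "contrast_id") <- paste0(genotype, "-", segment, "-10 vs ",
                                     genotype, "-", segment, "-270")
  out
}

#' Run all eight nitrogen contrasts
#'
#' Applies [select_degs()] to every genotype x segment cell and returns the
#' stacked results.
#'
#' @inheritParams select_degs
#' @return A tibble with an additional `contrast_id` column.
#' @export
select_degs_all <- function(x, design, lfc_threshold = 1, alpha = 0.05) {
  cons <- deg_contrasts(design)
  purrr::pmap(cons, function(genotype, segment, contrast_id) {
    select_degs(x, design, genotype, segment, lfc_threshold, alpha) |>
      dplyr::mutate(contrast_id = contrast_id, .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' Exclusive (UpSet-style) set intersections
#'
#' Partitions the union of the input gene sets into exclusive intersection
#' classes: each gene is assigned to the unique combination of sets that
#' contain it, so the class sizes always sum to the union size. Also records
#' the core (genes present in every set).
#'
#' @param sets A named list of character vectors (>= 1 set).
#' @return An object of class `set_intersection`: a tibble with columns
#'   `combination` (set names joined by `&`), `degree`, `size` and `genes`
#'   (list column), sorted by size; attribute `core` holds the all-set
#'   intersection and `sets` the input names.
#' @export
#' @examples
#' intersect_sets(list(A = c("g1", "g2"), B = c("g2", "g3")))
intersect_sets <- function(sets) {
  if (!is.list(sets) || length(sets) == 0 || is.null(names(sets)) ||
      any(names(sets) == "")) {
    abort("`sets` must be a non-empty named list of gene id vectors")
  }
  sets <- purrr::map(sets, unique)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  combo <- apply(member, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  out <- tibble(gene_id = universe, combination = combo) |>
    dplyr::group_by(.data$combination) |>
    dplyr::summarise(degree = lengths(strsplit(dplyr::first(.data$combination),
                                               "&", fixed = TRUE)),
                     size = dplyr::n(),
                     genes = list(.data$gene_id), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$combination)
  attr(out, "core") <- Reduce(intersect, sets)
  attr(out, "sets") <- names(sets)
  class(out) <- c("set_intersection", class(out))
  out
}
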