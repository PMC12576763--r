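# Internal helpers shared across stages.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG.
# seed = NULL means "use the current RNG state".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic per-stage seed derived from a master seed; stays inside the
# 32-bit integer range R requires.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1009 + 97 * k) %% 2147483647)
}

#' Percentage share, rounded as printed
#'
#' Utility used throughout module/network summaries: `100 * count / total`
#' rounded to `digits` decimal places (e.g. a 73-gene module in a 1109-node
#' network occupies `share_pct(73, 1109)` = 6.58 percent of the nodes).
#'
#' @param count Numerator count.
#' @param total Denominator count (> 0).
#' @param digits Decimal places to round to (default 2).
#' @return A numeric percentage.
#' @export
#' @examples
#' share_pct(73, 1109)
share_pct <- function(count, total, digits = 2) {
  stopifnot(total > 0)
  round(100 * count / total, digits)
}

# Trapezoid-rule integral on an ordered grid.
trapz_int <- function(x, y) pracma::trapz(x, y)

assert_design <- function(design) {
  need <- c("sample_id", "genotype", "nitrogen", "segment", "replicate")
  if (!is.data.frame(design) || !all(need %in% names(design))) {
    abort(paste0("`design` must be a data frame with columns ",
                 paste(need, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) abort("sample_ids must be unique")
  invisible(design)
}

assert_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("expression must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) abort("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(x))) abort("duplicate sample ids in expression matrix")
  invisible(x)
}
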