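#' Module eigengene
#'
#' The representative expression profile of a module: member genes are
#' standardized (mean 0, SD 1 per gene) and the first right singular vector
#' over samples — the first principal component of the standardized module
#' expression matrix — is taken as the eigengene. The sign is oriented so
#' that the eigengene correlates nonnegatively with the module's mean
#' standardized profile (falling back to the first member gene, then to the
#' first nonzero score, when that mean is degenerate), making the screen
#' reproducible. The score vector has unit norm.
#'
#' @param x Expression matrix (genes x samples).
#' @param members Character vector of member gene ids (>= 2, all present in
#'   `x`, none with zero variance).
#' @param module_label Optional label stored on the result.
#' @return An object of class `eigengene`: list with `scores` (named unit
#'   vector over samples), `var_explained`, `sign`, `members`,
#'   `module_label`.
#' @export
eigengene <- function(x, members, module_label = NA) {
  assert_expression(x)
  if (length(members) < 2) abort("an eigengene needs >= 2 member genes")
  missing <- setdiff(members, rownames(x))
  if (length(missing) > 0) {
    abort(paste0("member gene(s) absent from matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  xm <- x[members, , drop = FALSE]
  sds <- apply(xm, 1, sd)
  if (any(sds == 0)) abort("zero-variance member gene in eigengene input")
  xs <- (xm - rowMeans(xm)) / sds
  sv <- svd(xs)
  v <- sv$v[, 1]
  ve <- sv$d[1]^2 / sum(sv$d^2)
  mean_profile <- colMeans(xs)
  cc <- suppressWarnings(cor(v, mean_profile))
  if (is.na(cc) || cc == 0) cc <- suppressWarnings(cor(v, xs[1, ]))
  if (is.na(cc) || cc == 0) cc <- v[which(v != 0)[1]]
  sgn <- if (cc < 0) -1 else 1
  structure(
    list(scores = stats::setNames(sgn * v, colnames(x)),
         var_explained = ve, sign = sgn, members = members,
         module_label = module_label),
    class = "eigengene"
  )
}

#' Eigengenes for every module of a partition
#'
#' @param x Expression matrix.
#' @param partition An `mcl_partition` (tibble `gene_id`, `module`).
#' @param min_size Smallest module that receives an eigengene (default 2; a
#'   principal component of a single gene is not meaningful).
#' @return A named list of [eigengene()] objects, names = module labels.
#' @export
module_eigengenes <- function(x, partition, min_size = 2) {
  keep <- partition |>
    dplyr::count(.data$module) |>
    dplyr::filter(.data$n >= min_size)
  mods <- sort(keep$module)
  out <- purrr::map(mods, function(m) {
    eigengene(x, partition$gene_id[partition$module == m], module_label = m)
  })
  stats::setNames(out, as.character(mods))
}

#' Eigengene score matrix
#' @param eigengenes A list of `eigengene` objects (or a single one).
#' @return samples x modules numeric matrix.
#' @export
eigengene_matrix <- function(eigengenes) {
  if (inherits(eigengenes, "eigengene")) eigengenes <- list(eigengenes)
  scores <- purrr::map(eigengenes, "scores")
  m <- do.call(cbind, scores)
  colnames(m) <- names(eigengenes) %||%
    vapply(eigengenes, function(e) as.character(e$module_label), character(1))
  m
}

# All permutations of 1:n (n small), rows = permutations.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Spearman correlation p-value: exact permutation for n <= 9 (valid with
# ties via average ranks), t approximation otherwise. Two-sided.
spearman_p <- function(a, b) {
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3 || sd(a) == 0 || sd(b) == 0) return(list(rho = NA_real_, p = NA_real_))
  ra <- rank(a); rb <- rank(b)
  rho <- cor(ra, rb)
  if (n <= 9) {
    perms <- all_perms(n)
    rac <- ra - mean(ra)
    denom <- sqrt(sum(rac^2) * sum((rb - mean(rb))^2))
    stat <- abs(as.numeric((matrix(rb[perms], nrow = nrow(perms)) %*% rac)) / denom)
    p <- mean(stat >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = min(p, 1))
}

#' Screen module eigengenes against sample variables
#'
#' Spearman correlation (average ranks for ties; exact permutation p-value
#' for n <= 9 samples, t approximation otherwise) between every module
#' eigengene and every trait/factor variable, with Bonferroni control over
#' the full family of `m` tests (default: number of modules x number of
#' variables). A module-variable pair is selected iff
#' `|rho| > rho_cut` AND Bonferroni-adjusted p < `alpha`. Binary factors
#' (genotype, nitrogen) enter as 0/1 codes. A constant variable yields an
#' undefined correlation, reported with `flag = "constant"` and never
#' selected.
#'
#' @param eigengenes A named list of [eigengene()] objects, or a samples x
#'   modules score matrix.
#' @param traits Tibble with `sample_id` and numeric variable columns.
#' @param rho_cut Absolute Spearman threshold (default 0.7).
#' @param alpha Family-wise significance level (default 0.05).
#' @param m Bonferroni family size; default `modules * variables`.
#' @return A tibble of class `coex_screen`: `module`, `variable`, `rho`,
#'   `p`, `p_bonf`, `selected`, `flag`; attributes `m`, `rho_cut`, `alpha`.
#' @export
screen_modules <- function(eigengenes, traits, rho_cut = 0.7, alpha = 0.05,
                           m = NULL) {
  E <- if (is.matrix(eigengenes)) eigengenes else eigengene_matrix(eigengenes)
  if (!"sample_id" %in% names(traits)) abort("`traits` needs a sample_id column")
  if (!all(rownames(E) %in% traits$sample_id)) {
    abort("trait table does not cover all eigengene samples")
  }
  traits <- traits[match(rownames(E), traits$sample_id), ]
  vars <- setdiff(names(traits), "sample_id")
  if (ncol(E) < 1 || length(vars) < 1) abort("need >= 1 module and >= 1 variable")
  m <- m %||% (ncol(E) * length(vars))
  grid <- tidyr::expand_grid(module = colnames(E), variable = vars)
  out <- purrr::pmap(grid, function(module, variable) {
    v <- traits[[variable]]
    if (length(unique(v[!is.na(v)])) < 2) {
      return(tibble(module = module, variable = variable, rho = NA_real_,
                    p = NA_real_, p_bonf = NA_real_, selected = FALSE,
                    flag = "constant"))
    }
    sp <- spearman_p(E[, module], v)
    pb <- if (is.na(sp$p)) NA_real_ else min(1, sp$p * m)
    tibble(module = module, variable = variable, rho = sp$rho, p = sp$p,
           p_bonf = pb,
           selected = !is.na(sp$rho) && abs(sp$rho) > rho_cut &&
             !is.na(pb) && pb < alpha,
           flag = NA_character_)
  }) |>
    dplyr::bind_rows()
  attr(out, "m") <- m
  attr(out, "rho_cut") <- rho_cut
  attr(out, "alpha") <- alpha
  class(out) <- c("coex_screen", class(out))
  out
}

#' Per-variable selected-module sets
#'
#' The sets shown in module-trait intersection plots: for each screened
#' variable, the modules selected for it.
#'
#' @param screen A `coex_screen` result.
#' @return A named list variable -> character vector of module labels.
#' @export
screen_sets <- function(screen) {
  screen |>
    dplyr::filter(.data$selected) |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(mods = list(.data$module), .groups = "drop") |>
    (\(d) stats::setNames(d$mods, d$variable))()
}

#' Genotype-by-nitrogen interaction variable
#'
#' Product coding of the two centered binary factors: genotype (R = 1,
#' NR = 0) and nitrogen (270 = 1, 10 = 0) are centered at their sample means
#' and multiplied. In a balanced design the interaction takes values +0.25
#' for concordant cells (R at 270, NR at 10) and -0.25 for discordant ones,
#' and is exactly orthogonal to both main effects. Screen it like any other
#' variable (by default it is not part of the modules x 7 Bonferroni
#' family).
#'
#' @param design Design tibble with genotype and nitrogen columns.
#' @return A tibble `sample_id`, `genotype_nitrogen`.
#' @export
interaction_variable <- function(design) {
  assert_design(design)
  g <- as.integer(design$genotype == "R")
  n <- as.integer(design$nitrogen == "270")
  tibble(sample_id = design$sample_id,
         genotype_nitrogen = (g - mean(g)) * (n - mean(n)))
}

#' @export
print.eigengene <- function(x, ...) {
  cat("<eigengene> module ", x$module_label, ": ", length(x$members),
      " genes, variance explained ", round(x$var_explained, 3), "\n", sep = "")
  invisible(x)
}
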