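#' Generate the factorial sample design
#'
#' Builds the full factorial design of the greenhouse experiment the pipeline
#' emulates: 2 genotypes (R = nitrogen-responsive, NR = non-responsive) x
#' 2 nitrogen levels (10 and 270 mg N per kg of sand, applied as ammonium
#' nitrate) x 4 leaf developmental segments (B0 = base zero, B = base,
#' M = middle, P = tip), with `n_replicates` biological replicates per cell.
#' Three replicates give the 48-sample layout of the study design.
#'
#' @param n_replicates Number of biological replicates per factor combination
#'   (>= 1; default 3).
#' @param seed Optional integer seed (the design itself is deterministic; the
#'   seed is accepted for interface symmetry with the other generators).
#' @return A tibble with columns `sample_id`, `genotype`, `nitrogen`,
#'   `segment`, `replicate`; `16 * n_replicates` rows.
#' @export
#' @examples
#' generate_design(3) # 48 samples
generate_design <- function(n_replicates = 3, seed = NULL) {
  if (!is.numeric(n_replicates) || length(n_replicates) != 1 ||
      n_replicates < 1 || n_replicates != as.integer(n_replicates)) {
    abort("`n_replicates` must be a positive integer")
  }
  design <- tidyr::expand_grid(
    genotype  = factor(c("R", "NR"), levels = c("R", "NR")),
    nitrogen  = factor(c("10", "270"), levels = c("10", "270")),
    segment   = factor(c("B0", "B", "M", "P"), levels = c("B0", "B", "M", "P")),
    replicate = seq_len(n_replicates)
  )
  design |>
    dplyr::mutate(
      sample_id = paste(.data$genotype, .data$nitrogen, .data$segment,
                        .data$replicate, sep = "_"),
      .before = 1
    )
}

#' Declare a planted co-expression module
#'
#' A small constructor for the specification of one planted module in
#' [generate_expression()]. The `driver` decides which experimental factor
#' shapes the module's latent profile:
#' \describe{
#'   \item{genotype}{higher in one genotype (R vs NR).}
#'   \item{nitrogen}{higher under one nitrogen level (270 vs 10).}
#'   \item{segment}{monotone gradient along the leaf (B0 < B < M < P).}
#'   \item{interaction}{genotype-by-nitrogen product pattern.}
#'   \item{trait_only}{no factor structure; the latent is pure sample noise,
#'     available for trait coupling.}
#'   \item{noise}{like `trait_only`; a co-expressed module with no signal.}
#' }
#'
#' @param module_id Positive integer identifier, unique across specs.
#' @param n_genes Number of member genes (>= 2).
#' @param driver One of `"genotype"`, `"nitrogen"`, `"segment"`,
#'   `"interaction"`, `"trait_only"`, `"noise"`.
#' @param effect_size Latent-profile shift in SD units (>= 0).
#' @param within_module_cor Target population Pearson correlation between any
#'   two member genes, in (0, 1].
#' @param signed If `TRUE`, gene loadings get random signs so that roughly
#'   half of the members are anti-correlated with the latent profile.
#' @return A one-row tibble; rows from several calls can be bound together.
#' @export
module_spec <- function(module_id, n_genes, driver,
                        effect_size = 2, within_module_cor = 0.95,
                        signed = FALSE) {
  driver <- match.arg(driver, c("genotype", "nitrogen", "segment",
                                "interaction", "trait_only", "noise"))
  if (n_genes < 2) abort("`n_genes` must be >= 2")
  if (effect_size < 0) abort("`effect_size` must be >= 0")
  if (within_module_cor <= 0 || within_module_cor > 1) {
    abort("`within_module_cor` must be in (0, 1]")
  }
  tibble(module_id = as.integer(module_id), n_genes = as.integer(n_genes),
         driver = driver, effect_size = effect_size,
         within_module_cor = within_module_cor, signed = signed)
}

#' Default planted-module portfolio
#'
#' The default study conditions of the synthetic generator: eight planted
#' modules covering the module archetypes the downstream analysis must
#' recover (genotype-driven, nitrogen-driven, segment gradients, a
#' genotype-by-nitrogen interaction, a trait-coupled module with no factor
#' structure, and a null co-expressed module).
#'
#' @return A tibble of module specifications (see [module_spec()]).
#' @export
default_module_specs <- function() {
  dplyr::bind_rows(
    module_spec(1, 60, "genotype",    effect_size = 6),
    module_spec(2, 40, "genotype",    effect_size = 4),
    module_spec(3, 40, "nitrogen",    effect_size = 6),
    module_spec(4, 30, "nitrogen",    effect_size = 5),
    module_spec(5, 30, "segment",     effect_size = 4),
    module_spec(6, 25, "interaction", effect_size = 6),
    module_spec(7, 25, "trait_only",  effect_size = 0),
    module_spec(8, 20, "noise",       effect_size = 0)
  )
}

# Deterministic factor pattern (one value per sample) for a driver.
driver_pattern <- function(driver, design) {
  g <- ifelse(design$genotype == "R", 0.5, -0.5)
  n <- ifelse(design$nitrogen == "270", 0.5, -0.5)
  switch(driver,
    genotype    = g,
    nitrogen    = n,
    segment     = (as.integer(design$segment) - 2.5) / 1.5,  # B0..P -> -1..1
    interaction = 2 * g * n,                                  # +-0.5
    trait_only  = rep(0, nrow(design)),
    noise       = rep(0, nrow(design))
  )
}

#' Generate a synthetic variance-stabilized expression matrix
#'
#' Simulates a genes x samples matrix on a variance-stabilized-like scale.
#' Each planted module m has a latent sample profile
#' \eqn{L_m = \mathrm{std}(\delta_m \cdot c_m + \varepsilon)}, where
#' \eqn{c_m} is the centered factor pattern of its driver, \eqn{\delta_m}
#' the effect size in SD units, \eqn{\varepsilon \sim N(0,1)} per sample, and
#' std() standardizes to mean 0, SD 1. Member gene g is
#' \eqn{x_g = \mu + a_g L_m + e_g} with loading \eqn{a_g \sim U(0.7, 1)}
#' (random sign if the module is `signed`) and residual SD
#' \eqn{s_g = a_g\sqrt{(1-c)/c}} chosen so the population correlation between
#' any two member genes equals the target `within_module_cor` c exactly.
#' Noise genes are i.i.d. \eqn{N(\mu, \sigma^2)}.
#'
#' @param design A design tibble from [generate_design()].
#' @param modules A tibble of module specs ([module_spec()],
#'   [default_module_specs()]).
#' @param n_noise_genes Number of unstructured background genes.
#' @param noise_sd SD of the background genes (> 0).
#' @param baseline Grand mean expression level (default 8, a typical
#'   variance-stabilized magnitude).
#' @param missing_rate Fraction of entries set to `NA` uniformly at random
#'   (default 0; used to exercise the missingness filter).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list of class `coex_sim` with elements `expr` (matrix),
#'   `truth` (list: `assignments` tibble gene_id/module_id/driver, `latents`
#'   samples x modules matrix, `modules` the spec tibble, `baseline`) and
#'   `design`.
#' @export
generate_expression <- function(design, modules = default_module_specs(),
                                n_noise_genes = 500, noise_sd = 1,
                                baseline = 8, missing_rate = 0, seed = NULL) {
  assert_design(design)
  if (nrow(design) == 0) abort("`design` is empty")
  if (noise_sd <= 0) abort("`noise_sd` must be > 0")
  if ((is.null(modules) || nrow(modules) == 0) && n_noise_genes == 0) {
    abort("need at least one planted module or noise gene")
  }
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1)")
  if (!is.null(modules) && nrow(modules) > 0 &&
      anyDuplicated(modules$module_id)) abort("module_ids must be unique")

  n <- nrow(design)
  with_seed(seed, {
    blocks <- list()
    latents <- NULL
    assignments <- tibble(gene_id = character(), module_id = integer(),
                          driver = character())
    if (!is.null(modules) && nrow(modules) > 0) {
      latents <- matrix(NA_real_, nrow = n, ncol = nrow(modules),
                        dimnames = list(design$sample_id, modules$module_id))
      for (k in seq_len(nrow(modules))) {
        spec <- modules[k, ]
        pat <- driver_pattern(spec$driver, design)
        raw <- spec$effect_size * pat + rnorm(n)
        latent <- as.numeric(scale(raw))
        latents[, k] <- latent
        a <- runif(spec$n_genes, 0.7, 1.0)
        if (isTRUE(spec$signed)) a <- a * sample(c(-1, 1), spec$n_genes, replace = TRUE)
        s <- abs(a) * sqrt((1 - spec$within_module_cor) / spec$within_module_cor)
        g_ids <- sprintf("M%02dG%03d", spec$module_id, seq_len(spec$n_genes))
        block <- baseline +
          outer(a, latent) +
          matrix(rnorm(spec$n_genes * n, sd = rep(s, n)), nrow = spec$n_genes)
        rownames(block) <- g_ids
        blocks[[length(blocks) + 1L]] <- block
        assignments <- dplyr::bind_rows(
          assignments,
          tibble(gene_id = g_ids, module_id = spec$module_id, driver = spec$driver)
        )
      }
    }
    if (n_noise_genes > 0) {
      noise <- matrix(rnorm(n_noise_genes * n, mean = baseline, sd = noise_sd),
                      nrow = n_noise_genes)
      rownames(noise) <- sprintf("NOISE%04d", seq_len(n_noise_genes))
      blocks[[length(blocks) + 1L]] <- noise
    }
    expr <- do.call(rbind, blocks)
    colnames(expr) <- design$sample_id
    if (missing_rate > 0) {
      drop <- runif(length(expr)) < missing_rate
      expr[drop] <- NA_real_
    }
    structure(
      list(expr = expr,
           truth = list(assignments = assignments, latents = latents,
                        modules = modules, baseline = baseline),
           design = design),
      class = "coex_sim"
    )
  })
}

#' Default trait-loading matrix
#'
#' Maps the five measured physiological traits (total chlorophyll,
#' chlorophyll a, chlorophyll b, Rubisco, PEPCase) onto planted modules.
#' Chlorophyll traits load on the first nitrogen-driven module, Rubisco on
#' the second nitrogen-driven module (or the first if only one exists), and
#' PEPCase on the first `trait_only` module, falling back to the last module
#' if none is declared. Loadings are 1 so that the default trait noise gives
#' a population trait-latent correlation of 0.9.
#'
#' @param truth The `truth` element of a [generate_expression()] result.
#' @return A 5 x n_modules numeric matrix (rows: traits, columns: module ids).
#' @export
default_trait_loadings <- function(truth) {
  mods <- truth$modules
  ids <- as.character(mods$module_id)
  L <- matrix(0, nrow = 5, ncol = length(ids),
              dimnames = list(c("total_chlorophyll", "chlorophyll_a",
                                "chlorophyll_b", "rubisco", "pepcase"), ids))
  nit <- ids[mods$driver == "nitrogen"]
  tro <- ids[mods$driver == "trait_only"]
  chl <- if (length(nit) >= 1) nit[1] else ids[1]
  rub <- if (length(nit) >= 2) nit[2] else chl
  pep <- if (length(tro) >= 1) tro[1] else ids[length(ids)]
  L["total_chlorophyll", chl] <- 1
  L["chlorophyll_a", chl] <- 1
  L["chlorophyll_b", chl] <- 1
  L["rubisco", rub] <- 1
  L["pepcase", pep] <- 1
  L
}

#' Generate a sample trait table
#'
#' Produces the seven screening variables used by the module-trait stage:
#' binary genotype (R = 1) and nitrogen (270 = 1) codes straight from the
#' design, and five numeric physiological traits generated as linear
#' combinations of planted latent profiles plus Gaussian noise:
#' \eqn{t = \sum_m \lambda_{tm} L_m + \eta}, \eqn{\eta \sim N(0, \sigma^2)}.
#' With a single unit loading, the population correlation between trait and
#' latent is \eqn{\lambda/\sqrt{\lambda^2 + \sigma^2}}; the default
#' `trait_noise_sd` 0.4843 yields 0.9.
#'
#' @param design Design tibble matching the simulated samples.
#' @param truth The `truth` element of a [generate_expression()] result.
#' @param loadings Traits x modules numeric matrix with module-id column
#'   names; default [default_trait_loadings()].
#' @param trait_noise_sd SD of the additive trait noise (>= 0).
#' @param seed Integer seed.
#' @return A tibble: `sample_id`, `genotype` (0/1), `nitrogen` (0/1) and one
#'   column per loading row.
#' @export
generate_traits <- function(design, truth, loadings = NULL,
                            trait_noise_sd = 0.4843, seed = NULL) {
  assert_design(design)
  if (is.null(loadings)) loadings <- default_trait_loadings(truth)
  if (is.null(colnames(loadings)) ||
      !all(colnames(loadings) %in% as.character(truth$modules$module_id))) {
    abort("`loadings` columns must name planted module ids")
  }
  lat <- truth$latents[design$sample_id, colnames(loadings), drop = FALSE]
  with_seed(seed, {
    vals <- lat %*% t(loadings) +
      matrix(rnorm(nrow(design) * nrow(loadings), sd = trait_noise_sd),
             nrow = nrow(design))
    out <- tibble(
      sample_id = design$sample_id,
      genotype = as.integer(design$genotype == "R"),
      nitrogen = as.integer(design$nitrogen == "270")
    )
    dplyr::bind_cols(out, as_tibble(vals))
  })
}

#' Generate a gene annotation table with planted enrichments
#'
#' Assigns terms (GO-style identifiers or TAP family labels) to genes. Every
#' gene receives each background term independently with probability
#' `background_rate`; each planted term additionally covers a fraction
#' `coverage` (default 0.9, always >= 0.8 by argument check) of its target
#' module's genes, so that a Fisher overrepresentation test has a known
#' positive.
#'
#' @param truth The `truth` element of a [generate_expression()] result (used
#'   for the gene universe and module membership).
#' @param universe Optional character vector of gene ids; default all genes in
#'   `truth$assignments` (planted genes).
#' @param n_terms Number of background terms.
#' @param planted Named list mapping module id (as character) to a term id.
#' @param background_rate Per-gene probability of carrying a background term,
#'   in (0, 1) (or 0 to disable background annotation of planted terms).
#' @param coverage Fraction of the target module covered by its planted term
#'   (in \[0.8, 1\]).
#' @param term_type `"GO"` or `"TAP"`.
#' @param seed Integer seed.
#' @return A tibble `gene_id`, `term_id`, `term_type` with unique pairs.
#' @export
generate_annotations <- function(truth, universe = NULL, n_terms = 30,
                                 planted = NULL, background_rate = 0.05,
                                 coverage = 0.9, term_type = c("GO", "TAP"),
                                 seed = NULL) {
  term_type <- match.arg(term_type)
  if (background_rate < 0 || background_rate >= 1) {
    abort("`background_rate` must be in [0, 1)")
  }
  if (coverage < 0.8 || coverage > 1) abort("`coverage` must be in [0.8, 1]")
  universe <- universe %||% truth$assignments$gene_id
  if (!is.null(planted) &&
      !all(names(planted) %in% as.character(truth$assignments$module_id))) {
    abort("planted term mapped to unknown module")
  }
  with_seed(seed, {
    terms <- sprintf("%s:%04d", if (term_type == "GO") "GO" else "TAP",
                     seq_len(n_terms))
    rows <- purrr::map(terms, function(tm) {
      hit <- universe[runif(length(universe)) < background_rate]
      if (length(hit) == 0) return(NULL)
      tibble(gene_id = hit, term_id = tm, term_type = term_type)
    })
    prows <- purrr::imap(planted %||% list(), function(tm, mod) {
      members <- truth$assignments$gene_id[
        truth$assignments$module_id == as.integer(mod)]
      k <- max(1L, ceiling(coverage * length(members)))
      covered <- sample(members, k)
      # background hits outside the module
      others <- setdiff(universe, members)
      bg <- others[runif(length(others)) < background_rate]
      tibble(gene_id = c(covered, bg), term_id = tm, term_type = term_type)
    })
    dplyr::bind_rows(c(rows, unname(prows))) |>
      dplyr::distinct(.data$gene_id, .data$term_id, .data$term_type) |>
      dplyr::arrange(.data$term_id, .data$gene_id)
  })
}

#' @export
print.coex_sim <- function(x, ...) {
  cat("<coex_sim> ", nrow(x$expr), " genes x ", ncol(x$expr), " samples; ",
      nrow(x$truth$modules %||% tibble()), " planted modules\n", sep = "")
  invisible(x)
}
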