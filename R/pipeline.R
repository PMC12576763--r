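#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis with the
#' defaults used for the nitrogen-response network: correlation threshold
#' 0.90, MCL inflation 1.8, Spearman cut 0.7, significance level 0.05 and
#' hub fraction 0.10. The configuration round-trips through YAML unchanged
#' ([write_config()] / [read_config()]).
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @param n_replicates Replicates per design cell (default 3 -> 48 samples).
#' @param modules Planted module specs ([default_module_specs()]).
#' @param n_noise_genes,noise_sd,missing_rate Background-gene settings for
#'   the simulation stage.
#' @param trait_noise_sd Trait noise SD (default 0.4843, population
#'   trait-latent correlation 0.9).
#' @param max_missing_fraction Gene filter missingness cut (default 0.5).
#' @param lfc_threshold,alpha DEG effect cut (default 1) and significance
#'   level (default 0.05).
#' @param threshold_r Absolute-correlation edge threshold (default 0.90).
#' @param inflation MCL inflation (default 1.8).
#' @param rho_cut Spearman screening threshold (default 0.7).
#' @param top_fraction Hub decile (default 0.10).
#' @param null_replicates Replicate graphs per null-model parameter value
#'   (default 10).
#' @param network_genes `"degs"` (network over DEG-union genes, the study
#'   design) or `"all"` (all filtered genes).
#' @param out_dir Output directory for [run_pipeline()] artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            n_replicates = 3,
                            modules = default_module_specs(),
                            n_noise_genes = 500,
                            noise_sd = 1,
                            missing_rate = 0,
                            trait_noise_sd = 0.4843,
                            max_missing_fraction = 0.5,
                            lfc_threshold = 1,
                            alpha = 0.05,
                            threshold_r = 0.90,
                            inflation = 1.8,
                            rho_cut = 0.7,
                            top_fraction = 0.10,
                            null_replicates = 10,
                            network_genes = c("degs", "all"),
                            out_dir = NULL) {
  network_genes <- match.arg(network_genes)
  cfg <- list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
              modules = as_tibble(modules),
              n_noise_genes = as.integer(n_noise_genes),
              noise_sd = noise_sd, missing_rate = missing_rate,
              trait_noise_sd = trait_noise_sd,
              max_missing_fraction = max_missing_fraction,
              lfc_threshold = lfc_threshold, alpha = alpha,
              threshold_r = threshold_r, inflation = inflation,
              rho_cut = rho_cut, top_fraction = top_fraction,
              null_replicates = as.integer(null_replicates),
              network_genes = network_genes, out_dir = out_dir)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_replicates >= 1, noise_sd > 0,
              missing_rate >= 0, missing_rate < 1,
              max_missing_fraction >= 0, max_missing_fraction <= 1,
              alpha > 0, alpha < 1,
              threshold_r >= 0, threshold_r < 1,
              inflation > 1,
              rho_cut > 0, rho_cut < 1,
              top_fraction > 0, top_fraction < 1,
              null_replicates >= 1)
  })
  invisible(cfg)
}

#' Write / read a pipeline configuration as YAML
#' @param cfg A `pipeline_config`.
#' @param path YAML file path.
#' @return `path` invisibly (writer); a `pipeline_config` (reader).
#' @export
write_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$modules <- purrr::transpose(as.list(as.data.frame(lst$modules)))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$modules <- dplyr::bind_rows(purrr::map(lst$modules, as_tibble))
  if (is.null(lst$out_dir)) lst["out_dir"] <- list(NULL)
  do.call(pipeline_config, lst)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage %s: %s", name, conditionMessage(e)))
  })
}

#' Run the full co-expression pipeline on synthetic data
#'
#' Executes every stage in order: simulate -> gene filter -> the eight
#' nitrogen contrasts -> exclusive DEG-set intersections -> Pearson
#' correlation -> hard thresholding -> MCL module detection -> module
#' eigengenes -> Spearman module-trait screening -> null-model KL fits ->
#' hub calling -> module GO enrichment. When `cfg$out_dir` is set, all
#' tables are written as TSV (the graph additionally as GraphML) and a JSON
#' manifest records parameters, seeds, per-stage row counts and output-file
#' checksums; reruns with the same configuration reproduce identical
#' artifacts and manifests.
#'
#' @param cfg A [pipeline_config()].
#' @return A list with elements `sim`, `expr`, `degs`, `intersections`,
#'   `graph`, `topology`, `partition`, `module_stats`, `eigengenes`,
#'   `screen`, `null_fits`, `hubs`, `enrichment`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  validate_config(cfg)
  design <- run_stage("design", generate_design(cfg$n_replicates))
  sim <- run_stage("simulate", generate_expression(
    design, cfg$modules, n_noise_genes = cfg$n_noise_genes,
    noise_sd = cfg$noise_sd, missing_rate = cfg$missing_rate,
    seed = derive_seed(cfg$seed, 1)))
  traits <- run_stage("traits", generate_traits(
    design, sim$truth, trait_noise_sd = cfg$trait_noise_sd,
    seed = derive_seed(cfg$seed, 2)))
  # plant one enriched term on each of the two largest nitrogen-responsive
  # modules (their genes are the ones that can reach the DEG-based network),
  # falling back to the largest modules overall
  nresp <- cfg$modules$driver %in% c("nitrogen", "interaction")
  ord <- order(!nresp, -cfg$modules$n_genes)
  ann_targets <- as.character(utils::head(cfg$modules$module_id[ord], 2))
  annotations <- run_stage("annotations", generate_annotations(
    sim$truth,
    planted = stats::setNames(
      as.list(sprintf("GO:9%03d", seq_along(ann_targets))), ann_targets),
    seed = derive_seed(cfg$seed, 3)))

  expr <- run_stage("filter", filter_genes(sim$expr, cfg$max_missing_fraction))
  degs <- run_stage("contrasts", select_degs_all(
    expr, design, lfc_threshold = cfg$lfc_threshold, alpha = cfg$alpha))
  deg_sets <- degs |>
    dplyr::filter(.data$deg) |>
    dplyr::mutate(set = paste0(.data$contrast_id, ":", .data$direction)) |>
    (\(d) split(d$gene_id, d$set))()
  inter <- run_stage("intersections", {
    if (length(deg_sets) == 0) NULL else intersect_sets(deg_sets)
  })

  net_genes <- if (cfg$network_genes == "degs") {
    unique(degs$gene_id[degs$deg])
  } else {
    rownames(expr)
  }
  if (length(net_genes) < 3) abort("stage network: fewer than 3 network genes")
  r <- run_stage("correlation", pearson_matrix(expr[net_genes, , drop = FALSE]))
  graph <- run_stage("threshold", threshold_graph(r, cfg$threshold_r))
  topo <- run_stage("topology", topology_summary(graph))
  partition <- run_stage("mcl", mcl_cluster(graph, inflation = cfg$inflation))
  mstats <- run_stage("module_stats",
                      module_size_stats(partition, igraph::vcount(graph)))
  eg <- run_stage("eigengenes", module_eigengenes(expr, partition))
  screen <- run_stage("screen", screen_modules(
    eg, traits, rho_cut = cfg$rho_cut, alpha = cfg$alpha))
  nulls <- run_stage("nullfit", fit_null_models(
    graph, replicates = cfg$null_replicates,
    seed = derive_seed(cfg$seed, 4)))
  hubs <- run_stage("hubs", call_hubs(graph, partition,
                                      top_fraction = cfg$top_fraction))
  enrichment <- run_stage("enrich", {
    mods <- names(eg)
    purrr::map(stats::setNames(mods, mods), function(m) {
      fisher_enrichment(partition$gene_id[partition$module == as.integer(m)],
                        annotations, universe = igraph::V(graph)$name,
                        alpha = cfg$alpha) |>
        dplyr::mutate(module = as.integer(m), .before = 1)
    }) |>
      dplyr::bind_rows()
  })

  res <- list(sim = sim, traits = traits, annotations = annotations,
              expr = expr, degs = degs, intersections = inter,
              graph = graph, topology = topo, partition = partition,
              module_stats = mstats, eigengenes = eg, screen = screen,
              null_fits = nulls, hubs = hubs, enrichment = enrichment)

  stage_rows <- list(
    design = nrow(design), genes_simulated = nrow(sim$expr),
    genes_filtered = nrow(expr), contrasts = length(unique(degs$contrast_id)),
    degs = length(unique(degs$gene_id[degs$deg])),
    intersection_classes = if (is.null(inter)) 0L else nrow(inter),
    network_nodes = igraph::vcount(graph),
    network_edges = igraph::ecount(graph),
    modules = mstats$n_modules, eigengenes = length(eg),
    screen_tests = nrow(screen), screen_selected = sum(screen$selected),
    null_models = nrow(nulls), hubs = sum(hubs$hub),
    enrichment_rows = nrow(enrichment)
  )
  manifest <- list(
    package = "canenet",
    version = as.character(utils::packageVersion("canenet")),
    seed = cfg$seed,
    parameters = unclass(cfg)[setdiff(names(cfg), c("modules", "out_dir"))],
    planted_modules = nrow(cfg$modules),
    stages = stage_rows
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(cfg$out_dir, f)
    write_expression_tsv(sim$expr, p("expression.tsv"))
    write_table_tsv(design, p("design.tsv"))
    write_table_tsv(traits, p("traits.tsv"))
    write_table_tsv(annotations, p("annotations.tsv"))
    write_table_tsv(degs, p("contrast_results.tsv"))
    if (!is.null(inter)) {
      write_table_tsv(dplyr::mutate(inter,
                                    genes = purrr::map_chr(.data$genes,
                                                           paste, collapse = ",")),
                      p("deg_intersections.tsv"))
    }
    write_edges_tsv(graph, p("edges.tsv"))
    write_graphml(graph, p("network.graphml"))
    write_table_tsv(partition, p("modules.tsv"))
    em <- eigengene_matrix(eg)
    write_table_tsv(dplyr::bind_cols(tibble(sample_id = rownames(em)),
                                     as_tibble(em)), p("eigengenes.tsv"))
    write_table_tsv(screen, p("module_trait_screen.tsv"))
    write_table_tsv(nulls, p("null_model_fits.tsv"))
    write_table_tsv(hubs, p("hubs.tsv"))
    write_table_tsv(enrichment, p("module_enrichment.tsv"))
    files <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
    manifest$files <- as.list(tools::md5sum(file.path(cfg$out_dir, files)))
    names(manifest$files) <- files
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  res$manifest <- manifest
  res
}
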