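#' Generate a random graph from a reference ensemble
#'
#' The three null ensembles used for topology comparison:
#' \describe{
#'   \item{erdos_renyi}{G(n, p): each pair independently with probability
#'     `p`.}
#'   \item{small_world}{Watts-Strogatz: ring lattice with `k` neighbours per
#'     node, each edge rewired with probability `beta`.}
#'   \item{scale_free}{Barabasi-Albert preferential attachment adding `m`
#'     edges per new node.}
#' }
#'
#' @param model One of `"erdos_renyi"`, `"small_world"`, `"scale_free"`.
#' @param n Number of nodes (>= 2).
#' @param params Named list: `p` for ER; `k` (even) and `beta` in \[0, 1\]
#'   for small-world; `m` (>= 1) for scale-free.
#' @param seed Integer seed.
#' @return An undirected simple igraph graph.
#' @export
generate_model_graph <- function(model = c("erdos_renyi", "small_world",
                                           "scale_free"),
                                 n, params = list(), seed = NULL) {
  model <- match.arg(model)
  if (n < 2) abort("`n` must be >= 2")
  with_seed(seed, {
    g <- switch(model,
      erdos_renyi = {
        p <- params$p %||% abort("ER needs params$p")
        if (p < 0 || p > 1) abort("ER p must be in [0, 1]")
        igraph::sample_gnp(n, p)
      },
      small_world = {
        k <- params$k %||% abort("small-world needs params$k")
        beta <- params$beta %||% abort("small-world needs params$beta")
        if (k < 2 || k %% 2 != 0) abort("small-world k must be even and >= 2")
        if (beta < 0 || beta > 1) abort("rewiring beta must be in [0, 1]")
        igraph::sample_smallworld(1, n, nei = k / 2, p = beta)
      },
      scale_free = {
        m <- params$m %||% abort("scale-free needs params$m")
        if (m < 1) abort("attachment m must be >= 1")
        igraph::sample_pa(n, m = m, directed = FALSE)
      }
    )
    igraph::simplify(g)
  })
}

# Adjacency eigenvalues scaled by 1/sqrt(n).
scaled_spectrum <- function(g) {
  n <- igraph::vcount(g)
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  eigen(a / sqrt(n), symmetric = TRUE, only.values = TRUE)$values
}

# Gaussian kernel density of values `ev` on `grid` with bandwidth `bw`,
# renormalized to integrate to 1 by the trapezoid rule.
kernel_density_on_grid <- function(ev, grid, bw) {
  d <- vapply(grid, function(x) mean(dnorm((x - ev) / bw)) / bw,
              numeric(1))
  z <- trapz_int(grid, d)
  if (z <= 0) abort("degenerate spectral density")
  d / z
}

#' Spectral density of a graph
#'
#' Eigenvalues of the adjacency matrix scaled by `1/sqrt(n)`, smoothed by a
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth, evaluated on a
#' regular grid covering the support (plus three bandwidths on either side)
#' and renormalized so the trapezoid integral is 1.
#'
#' @param g An igraph graph with >= 2 nodes.
#' @param grid Optional explicit grid; default built from the spectrum.
#' @param grid_size Number of grid points (default 512).
#' @return A tibble `x`, `density` with attributes `bw` and `eigenvalues`.
#' @export
spectral_density <- function(g, grid = NULL, grid_size = 512) {
  if (igraph::vcount(g) < 2) abort("need >= 2 nodes")
  ev <- scaled_spectrum(g)
  bw <- density_bandwidth(ev)
  if (is.null(grid)) {
    grid <- seq(min(ev) - 3 * bw, max(ev) + 3 * bw, length.out = grid_size)
  }
  d <- kernel_density_on_grid(ev, grid, bw)
  out <- tibble(x = grid, density = d)
  attr(out, "bw") <- bw
  attr(out, "eigenvalues") <- ev
  out
}

# Silverman bandwidth, floored at 1% of the spectral range (repeated
# eigenvalues of clique-like graphs can collapse the IQR-based rule to ~0)
# and at 1e-3 absolutely, so degenerate spectra still smooth.
density_bandwidth <- function(ev) {
  bw <- tryCatch(bw.nrd0(ev), error = function(e) 0)
  floor_bw <- max(1e-3, diff(range(ev)) / 100)
  if (!is.finite(bw)) bw <- 0
  max(bw, floor_bw)
}

#' Kullback-Leibler divergence between two densities on a shared grid
#'
#' `KL(p || q) = integral p log(p/q)` by the trapezoid rule; both densities
#' are renormalized on the grid and floored at `floor` before taking logs.
#'
#' @param p,q Density values on `x`.
#' @param x Ordered grid.
#' @param floor Density floor (default 1e-12).
#' @return Nonnegative scalar (0 for identical densities).
#' @export
kl_divergence <- function(p, q, x, floor = 1e-12) {
  p <- pmax(p, floor); q <- pmax(q, floor)
  p <- p / trapz_int(x, p); q <- q / trapz_int(x, q)
  max(0, trapz_int(x, p * log(p / q)))
}

# Default parameter grids matched to the observed graph's size and density.
default_param_grid <- function(g, model) {
  n <- igraph::vcount(g)
  dens <- igraph::edge_density(g)
  mean_deg <- mean(igraph::degree(g))
  switch(model,
    erdos_renyi = {
      p <- pmin(0.999, pmax(1e-4, dens * seq(0.5, 1.5, length.out = 5)))
      purrr::map(unique(p), \(v) list(p = v))
    },
    small_world = {
      k <- max(2, 2 * round(mean_deg / 2))
      # beta capped at 0.5: a fully rewired lattice (beta = 1) is spectrally
      # indistinguishable from ER, which would make selection ill-posed
      beta <- 10^seq(log10(0.01), log10(0.5), length.out = 5)
      purrr::map(beta, \(b) list(k = k, beta = b))
    },
    scale_free = purrr::map(1:6, \(m) list(m = m))
  )
}

#' Fit one random-graph model by spectral KL divergence
#'
#' For each candidate parameter set, draws `replicates` graphs from the
#' ensemble at the observed graph's node count, averages their spectral
#' densities on a common grid, and computes `KL(observed || model mean)`.
#' Returns the parameter minimizing the divergence.
#'
#' @param g_obs Observed igraph graph (>= 3 nodes).
#' @param model Model name (see [generate_model_graph()]).
#' @param param_grid List of parameter lists; default matched to the
#'   observed size/density ([default_param_grid]).
#' @param replicates Graphs drawn per parameter value (default 50).
#' @param grid_size Density grid size (default 512).
#' @param seed Integer seed.
#' @return A one-row tibble of class `graph_model_fit`: `model`,
#'   `param_name`, `best_param`, `kl`, `replicates`; attribute `grid_fits`
#'   (tibble of all parameter values and their KL).
#' @export
graph_kl <- function(g_obs, model, param_grid = NULL, replicates = 50,
                     grid_size = 512, seed = NULL) {
  if (igraph::vcount(g_obs) < 3) abort("observed graph is degenerate (< 3 nodes)")
  model <- match.arg(model, c("erdos_renyi", "small_world", "scale_free"))
  param_grid <- param_grid %||% default_param_grid(g_obs, model)
  if (length(param_grid) == 0) abort("empty parameter grid")
  n <- igraph::vcount(g_obs)
  obs_ev <- scaled_spectrum(g_obs)
  bw_obs <- density_bandwidth(obs_ev)

  fits <- purrr::imap(param_grid, function(params, i) {
    evs <- purrr::map(seq_len(replicates), function(r) {
      scaled_spectrum(generate_model_graph(
        model, n, params, seed = derive_seed(seed, 1000L * i + r)))
    })
    lo <- min(obs_ev, purrr::map_dbl(evs, min))
    hi <- max(obs_ev, purrr::map_dbl(evs, max))
    grid <- seq(lo - 3 * bw_obs, hi + 3 * bw_obs, length.out = grid_size)
    p_obs <- kernel_density_on_grid(obs_ev, grid, bw_obs)
    q <- purrr::map(evs, function(e) {
      kernel_density_on_grid(e, grid, density_bandwidth(e))
    })
    q_mean <- Reduce(`+`, q) / length(q)
    q_mean <- q_mean / trapz_int(grid, q_mean)
    tibble(
      param_name = names(params)[length(params)],
      param_value = params[[length(params)]],
      kl = kl_divergence(p_obs, q_mean, grid)
    )
  }) |>
    dplyr::bind_rows()
  best <- fits[which.min(fits$kl), ]
  out <- tibble(model = model, param_name = best$param_name,
                best_param = best$param_value, kl = best$kl,
                replicates = as.integer(replicates))
  attr(out, "grid_fits") <- fits
  class(out) <- c("graph_model_fit", class(out))
  out
}

#' Compare a graph against all three null ensembles
#'
#' Runs [graph_kl()] for Erdos-Renyi, small-world and scale-free ensembles
#' and flags the best-fitting (minimum-KL) model.
#'
#' @inheritParams graph_kl
#' @param models Models to fit (default all three).
#' @return A tibble of class `null_model_comparison` with one row per model
#'   and a logical `best` column; attribute `best_model`.
#' @export
fit_null_models <- function(g_obs, models = c("erdos_renyi", "small_world",
                                              "scale_free"),
                            replicates = 50, grid_size = 512, seed = NULL) {
  fits <- purrr::imap(stats::setNames(models, models), function(mod, nm) {
    graph_kl(g_obs, mod, replicates = replicates, grid_size = grid_size,
             seed = derive_seed(seed, match(mod, models)))
  }) |>
    dplyr::bind_rows()
  fits$best <- seq_len(nrow(fits)) == which.min(fits$kl)
  attr(fits, "best_model") <- fits$model[fits$best]
  class(fits) <- c("null_model_comparison", class(fits))
  fits
}
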