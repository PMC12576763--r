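test_that("model generators hit their closed-form edge structures", {
  er <- generate_model_graph("erdos_renyi", 100, list(p = 1), seed = 1)
  expect_equal(igraph::ecount(er), 4950)  # complete graph

  ws <- generate_model_graph("small_world", 20, list(k = 4, beta = 0),
                             seed = 2)
  expect_true(all(igraph::degree(ws) == 4))  # unrewired ring lattice

  ba <- generate_model_graph("scale_free", 500, list(m = 3), seed = 3)
  expect_equal(igraph::ecount(ba), 3 + 3 * 497)  # seed clique + m per node

  expect_error(generate_model_graph("erdos_renyi", 10, list(p = 2)), "p")
  expect_error(generate_model_graph("small_world", 10, list(k = 3, beta = 0)),
               "even")
  expect_error(generate_model_graph("scale_free", 10, list(m = 0)), "m")
})

test_that("preferential attachment is heavier-tailed than ER at equal density", {
  # tail mass beyond 3x the mean degree, averaged over seeds
  tails <- vapply(1:20, function(s) {
    ba <- generate_model_graph("scale_free", 500, list(m = 3), seed = s)
    p_match <- igraph::ecount(ba) / choose(500, 2)
    er <- generate_model_graph("erdos_renyi", 500, list(p = p_match),
                               seed = 1000 + s)
    c(ba = mean(igraph::degree(ba) > 3 * mean(igraph::degree(ba))),
      er = mean(igraph::degree(er) > 3 * mean(igraph::degree(er))))
  }, numeric(2))
  expect_gt(mean(tails["ba", ]), mean(tails["er", ]))
})

test_that("spectral density integrates to one and matches closed forms", {
  # edgeless graph: a single kernel bump at zero
  g0 <- igraph::make_empty_graph(10, directed = FALSE)
  d0 <- spectral_density(g0)
  expect_equal(pracma::trapz(d0$x, d0$density), 1, tolerance = 1e-6)
  # peak at zero up to one grid step
  expect_lt(abs(d0$x[which.max(d0$density)]), diff(d0$x[1:2]) + 1e-9)

  # complete graph K_n: eigenvalues (n-1)/sqrt(n) once, -1/sqrt(n) otherwise
  kn <- igraph::make_full_graph(12)
  ev <- sort(attr(spectral_density(kn), "eigenvalues"))
  expect_equal(ev[12], 11 / sqrt(12), tolerance = 1e-10)
  expect_equal(ev[1:11], rep(-1 / sqrt(12), 11), tolerance = 1e-10)

  # spectral moment identities: sum ev = 0, sum ev^2 = 2|E|/n
  er <- generate_model_graph("erdos_renyi", 60, list(p = 0.1), seed = 5)
  eve <- attr(spectral_density(er), "eigenvalues")
  expect_equal(sum(eve), 0, tolerance = 1e-9)
  expect_equal(sum(eve^2), 2 * igraph::ecount(er) / igraph::vcount(er),
               tolerance = 1e-9)

  # independent KDE oracle: stats::density at the same bandwidth
  sd_er <- spectral_density(er)
  bw <- attr(sd_er, "bw")
  ref <- stats::density(eve, bw = bw, from = min(sd_er$x), to = max(sd_er$x),
                        n = length(sd_er$x))
  # stats::density uses linear binning, so agreement is at kernel tolerance
  expect_lt(max(abs(sd_er$density - ref$y / pracma::trapz(ref$x, ref$y))),
            1e-3)

  # bipartite spectra are symmetric about zero
  ring <- igraph::make_ring(20)
  evr <- attr(spectral_density(ring), "eigenvalues")
  expect_equal(sort(evr), sort(-evr), tolerance = 1e-9)
})

test_that("KL divergence is a nonnegative, zero-on-self functional", {
  g <- generate_model_graph("erdos_renyi", 50, list(p = 0.2), seed = 6)
  d <- spectral_density(g)
  expect_equal(kl_divergence(d$density, d$density, d$x), 0, tolerance = 1e-12)
  g2 <- generate_model_graph("scale_free", 50, list(m = 2), seed = 7)
  d2 <- spectral_density(g2, grid = d$x)
  expect_gte(kl_divergence(d$density, d2$density, d$x), 0)
})

test_that("a graph drawn from an ensemble self-matches within that ensemble", {
  n <- 120; p <- 0.08
  obs <- generate_model_graph("erdos_renyi", n, list(p = p), seed = 8)
  fit <- graph_kl(obs, "erdos_renyi", param_grid = list(list(p = p)),
                  replicates = 15, seed = 9)
  expect_s3_class(fit, "graph_model_fit")
  # within-ensemble KL spread: each replicate against the ensemble mean
  within <- vapply(1:15, function(s) {
    gi <- generate_model_graph("erdos_renyi", n, list(p = p), seed = 300 + s)
    graph_kl(gi, "erdos_renyi", param_grid = list(list(p = p)),
             replicates = 15, seed = 9)$kl
  }, numeric(1))
  # self-match contract: the held-out draw sits inside the within-ensemble
  # KL range (20% slack on the max of 15 reference draws)
  expect_lte(fit$kl, max(within) * 1.2)
})

test_that("null-model comparison labels its minimum-KL fit", {
  obs <- generate_model_graph("scale_free", 150, list(m = 3), seed = 10)
  fits <- fit_null_models(obs, replicates = 5, seed = 11)
  expect_equal(nrow(fits), 3)
  expect_equal(sum(fits$best), 1)
  expect_equal(attr(fits, "best_model"), fits$model[which.min(fits$kl)])
  expect_true(all(fits$kl >= 0))
})
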