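test_that("Fisher enrichment reproduces extreme-table closed forms", {
  universe <- sprintf("g%03d", 1:100)
  gene_set <- universe[1:5]
  ann <- tibble::tibble(gene_id = universe[1:5], term_id = "T1",
                        term_type = "GO")
  res <- fisher_enrichment(gene_set, ann, universe)
  # term exactly equals the gene set: p = 1 / C(100, 5)
  expect_equal(res$p[res$term_id == "T1"], 1 / choose(100, 5),
               tolerance = 1e-12)
  expect_equal(res$a, 5); expect_equal(res$b, 0)
  expect_equal(res$c, 0); expect_equal(res$d, 95)
  expect_equal(res$a + res$b + res$c + res$d, 100)

  # a term covering the whole universe is never enriched: p = 1
  ann2 <- tibble::tibble(gene_id = universe, term_id = "ALL",
                         term_type = "GO")
  res2 <- fisher_enrichment(gene_set, ann2, universe)
  expect_equal(res2$p[res2$term_id == "ALL"], 1, tolerance = 1e-12)

  expect_error(fisher_enrichment(c("zz"), ann, universe), "within")
})

test_that("hypergeometric tails equal direct support summation", {
  set.seed(55)
  for (i in 1:60) {
    N <- sample(10:60, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    universe <- sprintf("u%03d", 1:N)
    term_genes <- sample(universe, K)
    gene_set <- sample(universe, n)
    ann <- tibble::tibble(gene_id = term_genes, term_id = "T",
                          term_type = "GO")
    res <- fisher_enrichment(gene_set, ann, universe)
    a <- sum(gene_set %in% term_genes)
    expect_equal(res$p[res$term_id == "T"], oracle_hyper_tail(a, K, N, n),
                 tolerance = 1e-12)
  }
})

test_that("the hypergeometric tail is monotone in the overlap", {
  N <- 60; K <- 20; n <- 15
  ps <- vapply(0:15, function(a) oracle_hyper_tail(a, K, N, n), numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
  # and the implementation agrees along the whole support
  imp <- phyper(0:15 - 1, K, N - K, n, lower.tail = FALSE)
  expect_equal(imp, ps, tolerance = 1e-12)
})

test_that("with no planted signal, enrichment false positives stay near alpha", {
  set.seed(99)
  d <- generate_design(3)
  sim <- generate_expression(d, default_module_specs(), n_noise_genes = 0,
                             seed = 61)
  fp <- 0; n_terms_total <- 0
  for (s in 1:10) {
    ann <- generate_annotations(sim$truth, n_terms = 20, planted = NULL,
                                background_rate = 0.2, seed = 600 + s)
    gene_set <- sample(sim$truth$assignments$gene_id, 40)
    res <- fisher_enrichment(gene_set, ann,
                             universe = sim$truth$assignments$gene_id)
    fp <- fp + sum(res$enriched)
    n_terms_total <- n_terms_total + nrow(res)
  }
  expect_lte(fp, 0.05 * n_terms_total)
})

test_that("TAP composition reports exact proportions and calibrated tests", {
  # 22 MYB-family members among 39 TAPs is 56.4 percent, not 57.4
  fams <- c(rep("MYB", 22), rep("bHLH", 8), rep("WRKY", 9))
  taps <- tibble::tibble(gene_id = sprintf("t%02d", 1:39), family = fams)
  bg <- c(MYB = 0.15, bHLH = 0.25, WRKY = 0.2, other = 0.4)
  res <- tap_composition_test(taps, bg)
  myb <- res[res$family == "MYB", ]
  expect_equal(myb$observed, 22)
  expect_equal(round(100 * myb$proportion, 1), 56.4)
  expect_lt(myb$p, 0.01)
  expect_true(myb$overrepresented)

  # observed proportion at the background frequency: p near 1/2
  big <- tibble::tibble(gene_id = sprintf("b%04d", 1:1000),
                        family = c(rep("MYB", 200), rep("other", 800)))
  res2 <- tap_composition_test(big, c(MYB = 0.2, other = 0.8))
  expect_lt(abs(res2$p[res2$family == "MYB"] - 0.5), 0.1)

  expect_error(tap_composition_test(taps, c(MYB = 0.5, bHLH = 0.5)),
               "missing from background")
  expect_error(tap_composition_test(taps, c(MYB = 0.3, bHLH = 0.3,
                                            WRKY = 0.3)), "sum to 1")

  # type-I calibration under draws from the background
  set.seed(123)
  flags <- 0; tests <- 0
  for (s in 1:200) {
    fam <- sample(names(bg), 40, replace = TRUE, prob = bg)
    sim_taps <- tibble::tibble(gene_id = sprintf("s%02d", 1:40), family = fam)
    res3 <- tap_composition_test(sim_taps, bg)
    flags <- flags + sum(res3$overrepresented)
    tests <- tests + nrow(res3)
  }
  expect_lte(flags / tests, 0.015)
})

test_that("BH inside enrichment equals its step-up definition", {
  set.seed(77)
  universe <- sprintf("g%03d", 1:80)
  ann <- tibble::tibble(
    gene_id = sample(universe, 300, replace = TRUE),
    term_id = sample(sprintf("T%02d", 1:15), 300, replace = TRUE),
    term_type = "GO"
  ) |> dplyr::distinct()
  res <- fisher_enrichment(sample(universe, 25), ann, universe)
  expect_equal(res$padj, oracle_bh(res$p), tolerance = 1e-12)
})
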