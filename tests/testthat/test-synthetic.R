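test_that("the factorial design has 16 cells times the replicate count", {
  expect_equal(nrow(generate_design(3)), 48)
  expect_equal(nrow(generate_design(1)), 16)
  expect_equal(nrow(generate_design(5)), 80)
  d <- generate_design(3)
  expect_false(anyDuplicated(d$sample_id) > 0)
  cells <- dplyr::count(d, genotype, nitrogen, segment)
  expect_equal(nrow(cells), 16)
  expect_true(all(cells$n == 3))
  expect_error(generate_design(0), "positive integer")
  expect_error(generate_design(1.5), "positive integer")
})

test_that("expression simulation is deterministic under a fixed seed", {
  d <- generate_design(2)
  s1 <- generate_expression(d, default_module_specs(), n_noise_genes = 20,
                            seed = 11)
  s2 <- generate_expression(d, default_module_specs(), n_noise_genes = 20,
                            seed = 11)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$truth$latents, s2$truth$latents)
  s3 <- generate_expression(d, default_module_specs(), n_noise_genes = 20,
                            seed = 12)
  expect_false(identical(s1$expr, s3$expr))
})

test_that("a perfectly tight module yields unit pairwise correlations", {
  d <- generate_design(3)
  spec <- module_spec(1, 10, "nitrogen", effect_size = 2,
                      within_module_cor = 1)
  sim <- generate_expression(d, spec, n_noise_genes = 0, seed = 3)
  r <- cor(t(sim$expr))
  expect_true(all(abs(r) > 1 - 1e-8))
})

test_that("a null module shows no nitrogen contrast on average", {
  d <- generate_design(3)
  diffs <- vapply(1:20, function(s) {
    sim <- generate_expression(d, module_spec(1, 10, "noise", effect_size = 0),
                               n_noise_genes = 0, seed = s)
    prof <- colMeans(sim$expr)
    mean(prof[d$nitrogen == "270"]) - mean(prof[d$nitrogen == "10"])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.2)
})

test_that("planted correlation structure is calibrated at n = 48", {
  d <- generate_design(3)
  specs <- dplyr::bind_rows(module_spec(1, 50, "genotype", 2, 0.95),
                            module_spec(2, 50, "nitrogen", 2, 0.95))
  within <- numeric(50); between <- numeric(50)
  for (s in 1:50) {
    sim <- generate_expression(d, specs, n_noise_genes = 0, seed = 100 + s)
    r <- cor(t(sim$expr))
    m1 <- grepl("^M01", rownames(r)); m2 <- !m1
    w1 <- r[m1, m1][upper.tri(r[m1, m1])]
    w2 <- r[m2, m2][upper.tri(r[m2, m2])]
    within[s] <- mean(abs(c(w1, w2)))
    between[s] <- mean(abs(r[m1, m2]))
  }
  # calibration: mean within-module |r| within +-0.05 of the 0.95 target
  expect_lt(abs(mean(within) - 0.95), 0.05)
  expect_true(all(within > 0.90 & within <= 1))
  expect_lt(mean(between), 0.5)
})

test_that("trait generation follows the closed-form attenuation", {
  d <- generate_design(3)
  spec <- module_spec(1, 5, "trait_only", effect_size = 0)
  sim <- generate_expression(d, spec, n_noise_genes = 0, seed = 5)
  L <- matrix(1, 1, 1, dimnames = list("marker", "1"))

  # noiseless coupling: trait is a monotone function of the latent
  tr0 <- generate_traits(d, sim$truth, loadings = L, trait_noise_sd = 1e-9,
                         seed = 6)
  expect_equal(cor(tr0$marker, sim$truth$latents[, "1"], method = "spearman"),
               1, tolerance = 1e-12)

  # population correlation 0.8 -> sigma = sqrt(1/0.64 - 1)
  sig <- sqrt(1 / 0.64 - 1)
  rhos <- vapply(1:50, function(s) {
    tr <- generate_traits(d, sim$truth, loadings = L, trait_noise_sd = sig,
                          seed = 200 + s)
    cor(tr$marker, sim$truth$latents[, "1"])
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.8), 0.05)
})

test_that("zero loadings leave traits decoupled from latent profiles", {
  d <- generate_design(3)
  sim <- generate_expression(d, module_spec(1, 5, "trait_only", 0),
                             n_noise_genes = 0, seed = 7)
  L <- matrix(0, 1, 1, dimnames = list("marker", "1"))
  tr <- generate_traits(d, sim$truth, loadings = L, trait_noise_sd = 1,
                        seed = 8)
  expect_lt(abs(cor(tr$marker, sim$truth$latents[, "1"],
                    method = "spearman")), 0.6)
})

test_that("planted annotations cover their module and little else", {
  d <- generate_design(3)
  sim <- generate_expression(d, default_module_specs(), n_noise_genes = 0,
                             seed = 9)
  ann <- generate_annotations(sim$truth, n_terms = 10,
                              planted = list("3" = "GO:PLANT"),
                              background_rate = 0.05, coverage = 0.9,
                              seed = 10)
  expect_false(anyDuplicated(ann[, c("gene_id", "term_id")]) > 0)
  m3 <- sim$truth$assignments$gene_id[sim$truth$assignments$module_id == 3]
  covered <- sum(ann$gene_id[ann$term_id == "GO:PLANT"] %in% m3)
  expect_gte(covered / length(m3), 0.8)
  outside <- ann$gene_id[ann$term_id == "GO:PLANT"]
  outside <- outside[!outside %in% m3]
  expect_lt(length(outside) / (nrow(sim$truth$assignments) - length(m3)), 0.15)
  expect_error(generate_annotations(sim$truth, planted = list("99" = "GO:X")),
               "unknown module")
})
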