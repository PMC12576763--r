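test_that("eigengene of identical profiles is that profile, fully explained", {
  prof <- rnorm(12)
  x <- rbind(a = prof, b = prof, c = prof)
  colnames(x) <- sprintf("s%02d", 1:12)
  e <- eigengene(x, c("a", "b", "c"))
  expect_equal(e$var_explained, 1, tolerance = 1e-12)
  expect_equal(cor(e$scores, prof), 1, tolerance = 1e-12)
  expect_equal(sum(e$scores^2), 1, tolerance = 1e-12)  # unit norm
})

test_that("two anti-correlated genes give a deterministic degenerate case", {
  prof <- rnorm(10)
  x <- rbind(up = prof, down = -prof)
  colnames(x) <- sprintf("s%02d", 1:10)
  e1 <- eigengene(x, c("up", "down"))
  e2 <- eigengene(x, c("up", "down"))
  expect_equal(e1$var_explained, 1, tolerance = 1e-12)
  expect_identical(e1$scores, e2$scores)
  expect_error(eigengene(x, c("up", "absent")), "absent")
  expect_error(eigengene(x, "up"), ">= 2")
})

test_that("eigengenes recover planted latent profiles", {
  d <- generate_design(3)
  spec <- module_spec(1, 30, "nitrogen", effect_size = 3,
                      within_module_cor = 0.95)
  for (s in 1:5) {
    sim <- generate_expression(d, spec, n_noise_genes = 0, seed = 40 + s)
    e <- eigengene(sim$expr, rownames(sim$expr))
    rho <- cor(e$scores, sim$truth$latents[, "1"], method = "spearman")
    expect_gt(abs(rho), 0.95)
  }
})

test_that("the first PC beats any single member gene (prcomp oracle)", {
  set.seed(13)
  for (rep in 1:5) {
    x <- matrix(rnorm(8 * 15), nrow = 8,
                dimnames = list(sprintf("g%d", 1:8), sprintf("s%02d", 1:15)))
    x[1:4, ] <- x[1:4, ] + rep(rnorm(15, sd = 2), each = 4)
    e <- eigengene(x, rownames(x))
    xs <- t(scale(t(x)))
    pc <- prcomp(t(xs), center = FALSE, scale. = FALSE)
    ve_oracle <- pc$sdev[1]^2 / sum(pc$sdev^2)
    expect_equal(e$var_explained, ve_oracle, tolerance = 1e-10)
    # optimality: variance captured by any single standardized gene profile
    total <- sum(xs^2)
    for (i in 1:8) {
      u <- xs[i, ] / sqrt(sum(xs[i, ]^2))
      expect_gte(e$var_explained + 1e-12, sum((xs %*% u)^2) / total)
    }
  }
})

test_that("Spearman machinery matches rank-Pearson and exact references", {
  set.seed(21)
  for (rep in 1:10) {
    a <- rnorm(30); b <- rnorm(30)
    sp <- canenet:::spearman_p(a, b)
    expect_equal(sp$rho, cor(rank(a), rank(b)), tolerance = 1e-12)
    expect_equal(sp$rho, cor(a, b, method = "spearman"), tolerance = 1e-12)
  }
  # exact permutation p equals cor.test's exact method on tie-free data
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    a <- rnorm(n); b <- rnorm(n)
    sp <- canenet:::spearman_p(a, b)
    ct <- cor.test(a, b, method = "spearman", exact = TRUE)
    expect_equal(sp$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("screening applies the conjunction rule with Bonferroni control", {
  d <- generate_design(3)
  specs <- dplyr::bind_rows(
    module_spec(1, 20, "trait_only", 0, 0.95),
    module_spec(2, 20, "noise", 0, 0.95)
  )
  sim <- generate_expression(d, specs, n_noise_genes = 0, seed = 31)
  part <- tibble::tibble(gene_id = sim$truth$assignments$gene_id,
                         module = sim$truth$assignments$module_id)
  eg <- module_eigengenes(sim$expr, part)
  L <- matrix(c(1, 0), 1, 2, dimnames = list("marker", c("1", "2")))
  tr <- generate_traits(d, sim$truth, loadings = L, trait_noise_sd = 1e-6,
                        seed = 32)
  sc <- screen_modules(eg, tr)
  expect_s3_class(sc, "coex_screen")
  expect_equal(attr(sc, "m"), 2 * 3)  # 2 modules x 3 variables
  expect_true(all(sc$p_bonf >= sc$p, na.rm = TRUE))  # Bonferroni monotone
  hit <- sc[sc$module == "1" & sc$variable == "marker", ]
  expect_true(hit$selected)
  expect_gt(abs(hit$rho), 0.99)
  miss <- sc[sc$module == "2" & sc$variable == "marker", ]
  expect_false(miss$selected)

  # a monotone transform of the eigengene itself correlates perfectly
  tr_mono <- tibble::tibble(sample_id = d$sample_id,
                            mono = exp(eg[["1"]]$scores[d$sample_id]))
  sc_mono <- screen_modules(eg["1"], tr_mono)
  expect_equal(sc_mono$rho, 1, tolerance = 1e-12)

  # constant variable: flagged, never selected
  tr$flat <- 1
  sc2 <- screen_modules(eg, tr)
  flat <- sc2[sc2$variable == "flat", ]
  expect_true(all(flat$flag == "constant"))
  expect_false(any(flat$selected))
})

test_that("the interaction code is centered, orthogonal, and screenable", {
  d <- generate_design(3)
  iv <- interaction_variable(d)
  expect_setequal(round(unique(iv$genotype_nitrogen), 10), c(0.25, -0.25))
  concordant <- d$sample_id[(d$genotype == "R" & d$nitrogen == "270") |
                              (d$genotype == "NR" & d$nitrogen == "10")]
  expect_true(all(iv$genotype_nitrogen[iv$sample_id %in% concordant] == 0.25))
  g <- as.integer(d$genotype == "R"); n <- as.integer(d$nitrogen == "270")
  expect_equal(cor(iv$genotype_nitrogen, g), 0, tolerance = 1e-12)
  expect_equal(cor(iv$genotype_nitrogen, n), 0, tolerance = 1e-12)

  # an interaction-driven module is selected for the interaction variable
  # but for neither main effect
  sim <- generate_expression(d, module_spec(1, 25, "interaction", 6, 0.95),
                             n_noise_genes = 0, seed = 33)
  eg <- module_eigengenes(
    sim$expr, tibble::tibble(gene_id = rownames(sim$expr), module = 1L))
  tr <- tibble::tibble(sample_id = d$sample_id, genotype = g, nitrogen = n,
                       interaction = iv$genotype_nitrogen)
  sc <- screen_modules(eg, tr)
  expect_true(sc$selected[sc$variable == "interaction"])
  expect_false(sc$selected[sc$variable == "genotype"])
  expect_false(sc$selected[sc$variable == "nitrogen"])
})
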