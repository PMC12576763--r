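---
title: "Methods: co-expression network analysis of nitrogen response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression network analysis of nitrogen response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

canenet implements a gene co-expression network pipeline for factorial
nitrogen-response transcriptome experiments: two sugarcane genotypes with
contrasting nitrogen use efficiency (R = responsive, NR = non-responsive),
two ammonium-nitrate levels (10 and 270 mg N per kg of sand), four leaf
developmental segments (B0, B, M, P) and three biological replicates — 48
samples. This vignette documents the models, the parameters that matter,
the numerical choices, and what the synthetic-data generator does and does
not establish.

## Pipeline model

The pipeline consumes a variance-stabilized expression matrix (genes x
samples) and runs, in order:

1. **Gene filter.** Genes with more than half missing entries or zero
   variance are removed (`filter_genes()`), the standard pre-filter before
   correlation estimation.
2. **Nitrogen contrasts.** Eight contrasts, one per genotype x segment
   cell, each varying only the nitrogen level. `select_degs()` is a
   deliberate surrogate for a count-model test: a per-gene Welch t-test on
   the transformed values, Benjamini-Hochberg adjustment across genes, and
   the conjunction rule *differential iff* \(p_{adj} < 0.05\) **and**
   \(|\Delta| > 1\) (strict) with \(\Delta\) the mean difference (270 minus
   10) on the transformed scale. "Up" means higher at 270. Because the
   surrogate operates on the same matrix the network uses, its gene sets
   are internally consistent with all downstream stages; its counts are not
   comparable to a negative-binomial analysis and are not treated as such
   anywhere in the package.
3. **Set intersections.** `intersect_sets()` computes exclusive
   (UpSet-style) intersection classes over the DEG sets; class sizes always
   sum to the union size, and the core (genes in every set) is recorded.
4. **Network.** Pearson correlation over all DEG-union genes
   (`pearson_matrix()`, pairwise-complete when values are missing,
   optionally in row blocks with block-size-independent results), then a
   hard threshold: an edge iff \(|r| > 0.90\), strictly
   (`threshold_graph()`). Isolated genes are dropped, so the reported node
   count means connected genes.
5. **Modules.** A from-scratch Markov Cluster Algorithm
   (`mcl_cluster()`), inflation 1.8. Edge weights entering MCL are
   \(|r|\): the network keeps edges by absolute correlation and MCL
   requires nonnegative input, so anti-correlated partners are clustered
   together rather than discarded — a documented choice, since the
   upstream thresholding is sign-blind.
6. **Eigengenes and screening.** The eigengene of a module is the first
   principal component of its gene-standardized expression submatrix
   (`eigengene()`), oriented to correlate nonnegatively with the module
   mean profile. `screen_modules()` computes Spearman correlations between
   eigengenes and sample variables (binary genotype and nitrogen codes plus
   numeric traits: total chlorophyll, chlorophyll a and b, Rubisco,
   PEPCase), Bonferroni-corrected over the full family m = modules x
   variables; a pair is selected iff \(|\rho| > 0.7\) and
   \(p_{Bonf} < 0.05\).
7. **Null models.** `fit_null_models()` compares the observed graph
   against Erdős–Rényi, Watts–Strogatz and Barabási–Albert ensembles by
   Kullback–Leibler divergence between adjacency spectral densities,
   \(KL(\text{observed} \,\|\, \text{model mean})\); the minimum-KL model
   is reported.
8. **Hubs.** `call_hubs()` flags nodes in the top decile of both degree
   and unweighted-shortest-path betweenness.
9. **Enrichment.** One-sided hypergeometric (Fisher exact)
   overrepresentation per annotation term with BH control
   (`fisher_enrichment()`), and an exact-binomial family composition test
   for transcription-associated proteins (`tap_composition_test()`).

## Key parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `threshold_r` | 0.90 | absolute Pearson r | edge retention (strict >) |
| `inflation` | 1.8 | MCL entrywise power | module granularity (larger = finer) |
| `rho_cut` | 0.7 | absolute Spearman rho | module-trait selection |
| `alpha` | 0.05 | probability | BH / Bonferroni significance level |
| `top_fraction` | 0.10 | fraction | hub decile for degree and betweenness |
| `lfc_threshold` | 1 | transformed-scale difference | DEG effect cut (strict >) |
| `max_missing_fraction` | 0.5 | fraction | gene filter |

## The synthetic-data generator

The generator plants known structure so every stage can be verified without
raw sequencing data. Latent module profiles are
\(L_m = \mathrm{std}(\delta_m c_m + \varepsilon)\): a centered factor
pattern \(c_m\) of the module's driver (genotype, nitrogen, a leaf-gradient
score, a genotype-by-nitrogen product, or nothing), an effect size
\(\delta_m\) in SD units, unit Gaussian sample noise, standardized per
module so that effect sizes and correlations are interpretable in SD units.
Member genes are \(x_g = \mu + a_g L_m + e_g\) with loadings
\(a_g \sim U(0.7, 1)\) (all-positive unless a module is declared signed)
and residual SD \(s_g = a_g\sqrt{(1-c)/c}\), which makes the population
correlation between any two members exactly the target \(c\) — the
calibration is closed-form, not fitted. Traits are linear in the latents
plus Gaussian noise; with a unit loading the population trait-latent
correlation is \(\lambda/\sqrt{\lambda^2 + \sigma^2}\), and the default
\(\sigma = 0.4843\) gives 0.9. Annotation terms hit background genes at a
fixed rate and cover at least 80% (default 90%) of a designated module.

Default study conditions: 48 samples (3 replicates), eight planted modules
(two genotype-driven, two nitrogen-driven, one segment gradient, one
interaction, one trait-only, one null) of 20–60 genes over 500 unstructured
background genes. Planted effect sizes (4–6 latent-SD units for driven
modules) were set from an a-priori power analysis of the Welch/BH surrogate
at n = 3 per side, so that the planted responders are the strong,
detectable two-fold-scale changers that the DEG definition targets; weaker
effects are essentially undetectable at three replicates under BH across
hundreds of genes, which is a property of the design, not of the
implementation.

What the generator does **not** emulate: count noise (it draws Gaussian
values directly on the transformed scale — the noise model of real
variance-stabilized data is unknown and this assumption is recorded here),
mean-variance trends, correlated backgrounds, batch structure, or partially
overlapping modules. Planted modules are near-cliques at the default
within-module correlation 0.95; consequently module subgraphs are nearly
regular, and per-module hub calling often keeps every member (all nodes tie
at the cutoff). Passing tests therefore demonstrate algorithmic
correctness and recovery under clean modular structure, not performance on
real tangled transcriptomes.

## Numerical choices

- **MCL.** Column-stochastic flow matrix with unit self-loops (standard
  regularization ensuring aperiodicity); expansion 2; entries below 1e-5
  pruned after each inflation with column renormalization; convergence when
  the maximum entrywise change falls below 1e-6 (non-convergence at 200
  iterations is an error, not a silent stop). Clusters are read from
  attractor rows of the limit matrix; a node claimed by several attractor
  systems goes to the one holding most of its limiting mass, ties broken
  toward the system containing the lexicographically smallest gene id.
  Module labels are assigned by decreasing size, ties by smallest member
  id, so numbering is reproducible (module numbers carry no meaning beyond
  size rank).
- **Spearman p-values.** Exact permutation (all n! rank permutations,
  valid under ties via average ranks) for n ≤ 9; the usual t approximation
  otherwise. Binary factors enter as 0/1 codes (rank-based point-biserial).
  The genotype-by-nitrogen interaction screen (`interaction_variable()`,
  product of centered binary codes) is separate and not counted in the
  default Bonferroni family of m = modules x 7.
- **Spectral densities.** Adjacency eigenvalues scaled by
  \(1/\sqrt{n}\); Gaussian kernel with Silverman bandwidth, floored at 1%
  of the spectral range (clique-heavy graphs repeat eigenvalues and can
  collapse the IQR-based rule to zero) and at 1e-3 absolutely; trapezoid
  normalization to unit mass; densities floored at 1e-12 before logs in the
  KL integral. The divergence direction is observed-versus-model.
- **Null-model grids.** ER probability: five points at 0.5–1.5 times the
  observed density. Watts–Strogatz: ring degree fixed at the nearest even
  mean degree, rewiring β on a five-point log grid from 0.01 to 0.5 — the
  grid is deliberately capped below full rewiring because a β = 1 lattice
  is spectrally indistinguishable from ER, which would make model selection
  ill-posed. Barabási–Albert: m in 1..6. Fits average the spectral density
  over seeded replicate draws per grid value.
- **Hub cutoff.** The ⌊f·n⌋-th largest score (at least the maximum) with
  ≥ and all boundary ties kept: on tie-free scores exactly the top decile
  qualifies; on degenerate graphs (regular rings, cliques) the hub set can
  legitimately exceed 10%.
- **Eigengene sign.** PC signs are arbitrary; orientation against the
  module mean profile (falling back to the first member, then the first
  nonzero score, for exactly balanced anti-correlated cases) makes screens
  reproducible.
- **Degenerate inputs.** Zero-variance genes are an error naming the gene
  in `pearson_matrix()` (they must be filtered); constant screening
  variables are reported with a flag and never selected; an empty graph
  summarizes to zeros; an all-removed filter result is an explicit error.

## Problem sizes in the test suite

The suite verifies MCL on 200 random graphs of up to 60 nodes and a
two-K5 barbell; betweenness against a brute-force path-enumeration oracle
on 50 random 30-node graphs; hypergeometric tails against direct support
summation on 500 random tables (≤ 60 genes); planted-trait recovery over
100 simulated 48-sample datasets at Bonferroni m = 1393; and null-model
self-consistency on 300-node instances with 20 trials per generating
ensemble (8 replicate draws per grid value). These sizes were chosen as the
smallest at which each property is sharply testable.

## Known limitations

- The DEG stage is a surrogate; absolute DEG counts are not comparable to
  count-model analyses.
- Genotype-only modules never enter a DEG-derived network (genotype is
  constant within every contrast), mirroring the fact that a
  nitrogen-contrast design only recruits nitrogen-responsive genes; the
  `network_genes = "all"` configuration bypasses this.
- Near-clique planted modules make per-module centrality nearly uniform;
  hub calling is better exercised on the global scope or on real data.
- Exact Spearman permutation is limited to n ≤ 9 (362,880 permutations);
  beyond that the t approximation is used.
- GO terms are treated as flat labels: no ontology-graph propagation or
  elim-style decorrelation.
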