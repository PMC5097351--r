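# Generators: determinism, planted structure, distributional contracts.

test_that("atlas spec validation names the offending field", {
  expect_error(atlas_spec(n_genes = 0), "n_genes")
  expect_error(atlas_spec(10, replicates_per_tissue = 4),
               "replicates_per_tissue")
  expect_error(atlas_spec(10, n_modules = 2, module_sizes = c(8, 8)),
               "module_sizes")
  expect_error(atlas_spec(10, noise_sd = -1), "noise_sd")
  expect_error(atlas_spec(10, within_module_corr = 1.2),
               "within_module_corr")
})

test_that("same spec and seed give byte-identical atlases", {
  a1 <- generate_expression_atlas(atlas_spec(30, n_tissues = 8,
                                             n_modules = 2, seed = 5))
  a2 <- generate_expression_atlas(atlas_spec(30, n_tissues = 8,
                                             n_modules = 2, seed = 5))
  expect_identical(a1$atlas$tpm, a2$atlas$tpm)
  expect_identical(a1$module_labels, a2$module_labels)
  a3 <- generate_expression_atlas(atlas_spec(30, n_tissues = 8,
                                             n_modules = 2, seed = 6))
  expect_false(identical(a1$atlas$tpm, a3$atlas$tpm))
})

test_that("zero noise forces within-module correlation 1 after transform", {
  sim <- make_small_atlas(n_modules = 2, module_size = 5, n_tissues = 8)
  x <- preprocess_atlas(sim$atlas)$matrix
  for (m in 1:2) {
    rows <- names(sim$module_labels)[which(sim$module_labels == m)]
    cc <- stats::cor(t(x[rows, ]))
    expect_true(all(abs(cc - 1) < 1e-12))
  }
})

test_that("pure-noise genes have near-zero between-module correlation", {
  # Monte-Carlo oracle: mean cross-module correlation over replicate
  # datasets should sit within 3 standard errors of 0
  vals <- sapply(1:100, function(i) {
    sim <- make_small_atlas(n_modules = 2, module_size = 5, n_tissues = 8,
                            w = 0.01, noise_sd = 0, seed = 1000 + i)
    x <- preprocess_atlas(sim$atlas)$matrix
    g1 <- names(sim$module_labels)[sim$module_labels == 1][1:3]
    g2 <- names(sim$module_labels)[sim$module_labels == 2][1:3]
    mean(stats::cor(t(x[g1, ]), t(x[g2, ])))
  })
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 1e-12)
})

test_that("planted type-I pairs share a module, IV span two, V/VI singletons", {
  sim <- make_small_atlas(n_modules = 4, module_size = 15, n_tissues = 8,
                          extra_singletons = 30)
  sp <- pair_spec(10, divergence_mix = c(I = 1), seed = 2)
  p1 <- generate_duplicate_pairs(sp, sim$module_labels)
  lab <- sim$module_labels
  expect_true(all(lab[p1$gene1] == lab[p1$gene2]))
  sp <- pair_spec(12, divergence_mix = c(I = 0.25, IV = 0.25, V = 0.25,
                                         VI = 0.25), seed = 2)
  pp <- generate_duplicate_pairs(sp, sim$module_labels)
  p4 <- pp[pp$planted_divergence == "IV"]
  expect_true(all(lab[p4$gene1] != lab[p4$gene2]))
  p6 <- pp[pp$planted_divergence == "VI"]
  expect_true(all(is.na(lab[p6$gene1])) && all(is.na(lab[p6$gene2])))
  expect_error(generate_duplicate_pairs(
    pair_spec(10, divergence_mix = c(II = 1)), sim$module_labels),
    "divergence_benchmark")
  expect_error(generate_duplicate_pairs(
    pair_spec(500, divergence_mix = c(VI = 1)), sim$module_labels),
    "exceed")
})

test_that("duplication types follow the multinomial and dS its moments", {
  sim <- make_small_atlas(n_modules = 1, module_size = 2, n_tissues = 8,
                          extra_singletons = 4200)
  props <- c(WGD = 0.3, tandem = 0.2, inserted = 0.5)
  sp <- pair_spec(2000, type_proportions = props,
                  divergence_mix = c(VI = 1), seed = 3)
  pp <- generate_duplicate_pairs(sp, sim$module_labels)
  for (ty in names(props)) {
    n_obs <- sum(pp$dup_type == ty)
    se <- sqrt(2000 * props[ty] * (1 - props[ty]))
    expect_lt(abs(n_obs - 2000 * props[ty]), 3 * se)
  }
  wgd_ds <- pp$dS[pp$dup_type == "WGD"]
  # WGD dS ~ N(0.15, 0.05) truncated at 0: truncation mass is ~0.13%
  expect_lt(abs(mean(wgd_ds) - 0.15), 3 * 0.05 / sqrt(length(wgd_ds)) + 0.002)
  expect_lt(abs(stats::sd(wgd_ds) - 0.05),
            3 * 0.05 / sqrt(2 * length(wgd_ds)) + 0.002)
  expect_true(all(pp$dS >= 0))
})

test_that("subgenome structure honors exact counts and emits valid pathways", {
  sg0 <- generate_subgenome_structure(
    subgenome_spec(n_maize1 = 150, n_maize2 = 95, n_pathways = 0, seed = 4))
  expect_equal(sum(sg0$map$subgenome == "maize1"), 150)
  expect_equal(sum(sg0$map$subgenome == "maize2"), 95)
  sg <- generate_subgenome_structure(
    subgenome_spec(n_maize1 = 150, n_maize2 = 95, n_pathways = 5,
                   n_tandem = 4, n_inserted = 4, seed = 4))
  expect_equal(length(sg$lost_genes), 150 - 95)
  expect_equal(nrow(sg$retained_pairs), 95)
  expect_false(anyDuplicated(sg$map$gene_id) > 0)
  wgd <- sg$pairs[sg$pairs$dup_type == "WGD"]
  for (pw in sg$pathways) {
    expect_true(all(pw %in% sg$map$gene_id))
    n_in <- sum(wgd$gene1 %in% pw & wgd$gene2 %in% pw)
    expect_gte(n_in, 2)
  }
})

test_that("fractionation is binomial when the maize2 count is free", {
  losses <- sapply(1:40, function(i) {
    sg <- generate_subgenome_structure(
      subgenome_spec(n_maize1 = 200, n_maize2 = NULL,
                     fractionation_rate = 0.2, n_pathways = 0, seed = i))
    length(sg$lost_genes)
  })
  se <- sqrt(200 * 0.2 * 0.8)
  expect_lt(abs(mean(losses) - 40), 3 * se / sqrt(length(losses)))
  expect_gt(stats::sd(losses), 0)   # genuinely random, not clamped
})

test_that("benchmark generator is deterministic and matches its mix", {
  b1 <- generate_divergence_benchmark(n_pairs = 40, seed = 9)
  b2 <- generate_divergence_benchmark(n_pairs = 40, seed = 9)
  expect_identical(b1$atlas$tpm, b2$atlas$tpm)
  expect_identical(b1$pairs, b2$pairs)
  mix <- c(I = 0.12, II = 0.18, III = 0.03, IV = 0.50, V = 0.06,
           VI = 0.05, unclassified = 0.06)
  cnt <- table(b1$pairs$planted_divergence)
  expect_equal(sum(cnt), 40)
  expect_true(all(abs(cnt[names(mix)] - 40 * mix) <= 1))
})
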