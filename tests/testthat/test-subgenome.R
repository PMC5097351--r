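# Edge fractionation, pathway tests, permutation nulls, module
# enrichment, hub detection.

k4_map <- data.table::data.table(
  gene_id = c("a1", "a2", "b1", "b2", "amb"),
  subgenome = c("maize1", "maize1", "maize2", "maize2", "ambiguous"),
  block_id = "B1", chrom = "chr1", start = 1:5, end = 2:6)

test_that("complete graph on 2+2 labeled genes counts (1, 1, 4)", {
  genes <- c("a1", "a2", "b1", "b2")
  e <- t(utils::combn(genes, 2))
  edges <- data.table::data.table(gene1 = e[, 1], gene2 = e[, 2], z = 3)
  fr <- count_subgenome_edges(make_network(edges), k4_map)
  expect_equal(c(fr$m1_intra, fr$m2_intra, fr$inter), c(1, 1, 4))
  expect_equal(unname(fr$densities), c(1, 1, 1))
})

test_that("ambiguous genes are dropped before counting", {
  edges <- data.table::data.table(gene1 = c("a1", "amb"),
                                  gene2 = c("amb", "b1"), z = 3)
  fr <- count_subgenome_edges(make_network(edges,
                                           gene_ids = k4_map$gene_id),
                              k4_map)
  expect_equal(fr$m1_intra + fr$m2_intra + fr$inter, 0)
  expect_error(count_subgenome_edges(make_network(edges, "amb"),
                                     k4_map[5]), "labeled")
})

test_that("edge partition conserves the labeled-subset edge total", {
  set.seed(3)
  genes <- k4_map$gene_id
  e <- t(utils::combn(genes, 2))
  keep <- sample(c(TRUE, FALSE), nrow(e), replace = TRUE)
  edges <- data.table::data.table(gene1 = e[keep, 1], gene2 = e[keep, 2],
                                  z = 3)
  fr <- count_subgenome_edges(make_network(edges, gene_ids = genes), k4_map)
  labeled <- genes[1:4]
  n_lab <- sum(edges$gene1 %in% labeled & edges$gene2 %in% labeled)
  expect_equal(fr$m1_intra + fr$m2_intra + fr$inter, n_lab)
})

test_that("pathway filters drop low-edge and low-WGD pathways", {
  sg <- generate_subgenome_structure(
    subgenome_spec(n_maize1 = 200, n_maize2 = 150, n_pathways = 12,
                   pathway_size_range = c(14L, 20L), seed = 8))
  edges <- simulate_subgenome_edges(sg$map, sg$pathways, 0.3, 0.3, 0.3,
                                    seed = 2)
  net <- make_network(edges, gene_ids = sg$map$gene_id)
  pf <- pathway_fractionation(net, sg$map, sg$pathways, sg$pairs,
                              min_edges = 7, min_wgd_pairs = 2)
  pp <- pf$per_pathway
  expect_true(all(pp$total_edges[pp$retained] >= 7))
  expect_true(all(pp$n_wgd_pairs[pp$retained] >= 2))
  expect_true(all(!pp$retained[pp$total_edges < 7]))
  # a pathway with one WGD pair must not be retained
  pw1 <- list(one_pair = c(sg$retained_pairs$gene1[1],
                           sg$retained_pairs$gene2[1],
                           sg$map$gene_id[300:310]))
  expect_error(pathway_fractionation(net, sg$map, pw1, sg$pairs),
               "fewer than 2 pathways")
})

test_that("degenerate paired differences give statistic 0 and p 1", {
  out <- coexdiv:::.paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 1)
})

test_that("permutation null matches the combinatorial inter fraction", {
  pn <- permute_edge_null(10, 10, 30, observed_inter = 16, n_perm = 500,
                          seed = 4)
  # expected inter fraction = 100/190
  expect_lt(abs(mean(pn$null) / 30 - 100 / 190), 0.02)
  # observation at the null mean is not significant
  pn2 <- permute_edge_null(10, 10, 30, round(30 * 100 / 190),
                           n_perm = 500, seed = 4)
  expect_gt(pn2$p.value, 0.5)
  # determinism
  pn3 <- permute_edge_null(10, 10, 30, 16, n_perm = 500, seed = 4)
  expect_identical(pn$null, pn3$null)
  expect_error(permute_edge_null(3, 3, 100, 1), "possible")
})

test_that("pair-index decoding enumerates each unordered pair once", {
  n <- 9
  ij <- coexdiv:::.decode_pair(seq_len(choose(n, 2)), n)
  expect_true(all(ij[, 1] < ij[, 2]))
  expect_equal(anyDuplicated(paste(ij[, 1], ij[, 2])), 0L)
})

test_that("contingency test matches the textbook chi-square formula", {
  # identical realization rates -> statistic 0, p 1
  fr <- structure(list(m1_intra = 5, m2_intra = 5, inter = 20,
                       possible_m1 = 50, possible_m2 = 50,
                       possible_inter = 200),
                  class = "edge_fractionation")
  out <- contingency_edge_test(fr)
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 1)
  # (10, 90 | 20, 180): equal proportions -> 0
  fr2 <- structure(list(m1_intra = 10, m2_intra = 0, inter = 20,
                        possible_m1 = 100, possible_m2 = 0,
                        possible_inter = 200),
                   class = "edge_fractionation")
  expect_equal(contingency_edge_test(fr2)$statistic, 0)
  # random tables: Pearson X2 = sum (O-E)^2 / E
  set.seed(5)
  for (i in 1:10) {
    o <- matrix(sample(5:60, 4), 2)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    x2 <- sum((o - e)^2 / e)
    fr3 <- structure(list(m1_intra = o[1, 1], m2_intra = 0, inter = o[2, 1],
                          possible_m1 = o[1, 1] + o[1, 2], possible_m2 = 0,
                          possible_inter = o[2, 1] + o[2, 2]),
                     class = "edge_fractionation")
    expect_equal(contingency_edge_test(fr3)$statistic, x2,
                 tolerance = 1e-12)
  }
})

test_that("module enrichment skips small modules and Bonferroni-adjusts", {
  map <- data.table::data.table(
    gene_id = sprintf("g%03d", 1:200),
    subgenome = rep(c("maize1", "maize2"), c(120, 80)),
    block_id = "B1", chrom = "chr1", start = 1:200, end = 2:201)
  # module 1: 30 genes at background proportions; module 2: 19 labeled
  mod <- data.table::data.table(
    gene_id = c(sprintf("g%03d", 1:18), sprintf("g%03d", 121:132),
                sprintf("g%03d", 19:30), sprintf("g%03d", 133:139)),
    module_id = rep(c(1L, 2L), c(30, 19)))
  res <- module_subgenome_enrichment(mod, map, min_labeled = 20)
  expect_equal(nrow(res), 1L)
  expect_equal(res$module_id, 1L)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_adjusted, 1)
  # Bonferroni multiplies by the number of tested modules
  mod5 <- data.table::rbindlist(lapply(1:5, function(k)
    data.table::data.table(
      gene_id = sprintf("g%03d", ((k - 1) * 24 + 1):((k - 1) * 24 + 24)),
      module_id = k)))
  res5 <- module_subgenome_enrichment(mod5, map, min_labeled = 10)
  expect_equal(res5$p_adjusted, pmin(1, res5$p_value * nrow(res5)))
  expect_warning(module_subgenome_enrichment(mod[31:49], map,
                                             min_labeled = 50), "no module")
})

test_that("a planted star center is detected as a hub", {
  set.seed(6)
  n_bg <- 500; m_bg <- 600
  g <- igraph::sample_gnm(n_bg, m_bg)
  el <- igraph::as_edgelist(g)
  ids <- sprintf("n%03d", seq_len(n_bg))
  star <- data.table::data.table(gene1 = "hub", gene2 = ids[1:50])
  edges <- rbind(data.table::data.table(gene1 = ids[el[, 1]],
                                        gene2 = ids[el[, 2]]), star)
  net <- make_network(edges, gene_ids = c(ids, "hub"))
  hr <- detect_hub_genes(net, n_perm = 100, seed = 9)
  expect_true("hub" %in% hr$hub_genes)
  hr2 <- detect_hub_genes(net, n_perm = 100, seed = 9)
  expect_identical(hr$cutoff, hr2$cutoff)
  expect_identical(hr$hub_genes, hr2$hub_genes)
  hr3 <- detect_hub_genes(net, n_perm = 100, seed = 10, null_stat = "max")
  expect_true(hr3$cutoff >= hr$cutoff)
})

test_that("hub subgenome bias reproduces the direct chi-square", {
  map <- data.table::data.table(
    gene_id = sprintf("h%02d", 1:40),
    subgenome = rep(c("maize1", "maize2"), each = 20),
    block_id = "B1", chrom = "chr1", start = 1:40, end = 2:41)
  # all 20 hubs maize1 against a 50/50 background: X2 = 10 + 10 = 20
  out <- hub_subgenome_bias(sprintf("h%02d", 1:20), map,
                            background = c(50, 50))
  expect_equal(out$statistic, 20, tolerance = 1e-12)
  # hubs at background proportions: statistic 0
  out0 <- hub_subgenome_bias(sprintf("h%02d", c(1:10, 21:30)), map,
                             background = c(50, 50))
  expect_equal(out0$statistic, 0, tolerance = 1e-12)
  expect_error(hub_subgenome_bias("nope", map), "label")
})

test_that("dominant subgenome densities are detected by the paired test", {
  sg <- generate_subgenome_structure(
    subgenome_spec(n_maize1 = 300, n_maize2 = 240, n_pathways = 30,
                   pathway_size_range = c(16L, 24L), seed = 12))
  edges <- simulate_subgenome_edges(sg$map, sg$pathways,
                                    density_m1 = 0.4, density_m2 = 0.2,
                                    density_inter = 0.25, seed = 13)
  net <- make_network(edges, gene_ids = sg$map$gene_id)
  pf <- pathway_fractionation(net, sg$map, sg$pathways, sg$pairs)
  expect_lt(pf$tests$m1_vs_m2_density$p.value, 0.05)
  expect_gt(pf$tests$m1_vs_m2_density$statistic, 0)
})
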