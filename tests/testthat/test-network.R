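# Correlation, Fisher standardization, thresholding, MCL, graph metrics.

test_that("correlation matrix: self 1, anticorrelation -1, constants flagged", {
  x <- rbind(a = c(1, 2, 3, 5), b = -c(1, 2, 3, 5), flat = c(2, 2, 2, 2))
  r <- correlation_matrix(x)
  expect_equal(r["a", "a"], 1)
  expect_equal(r["a", "b"], -1)
  expect_identical(attr(r, "undefined"), "flat")
  expect_true(all(is.na(r["flat", c("a", "b")])))
  expect_error(correlation_matrix(x[, 1:2]), "3 tissue")
})

test_that("Fisher transform hits closed forms and standardizes to N(0,1)", {
  expect_equal(coexdiv:::.fisher_z(0), 0)
  expect_equal(coexdiv:::.fisher_z(0.9), 0.5 * log(19), tolerance = 1e-12)
  sim <- make_small_atlas(n_modules = 5, module_size = 6, n_tissues = 12,
                          extra_singletons = 40, w = 0.9, seed = 3)
  r <- correlation_matrix(preprocess_atlas(sim$atlas)$matrix)
  fs <- fisher_standardize(r)
  up <- upper.tri(fs$z)
  expect_lt(abs(mean(fs$z[up])), 1e-9)
  expect_lt(abs(stats::sd(fs$z[up]) - 1), 1e-9)
  # strictly monotone in R: order by correlation equals order by z
  i <- which(up, arr.ind = TRUE)
  expect_identical(order(r[up]), order(fs$z[up]))
})

test_that("edge threshold is strict and monotone in the cutoff", {
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  z["a", "b"] <- z["b", "a"] <- 2.5          # exactly at the cutoff
  z["a", "c"] <- z["c", "a"] <- 2.6
  diag(z) <- NA
  net <- threshold_network(z, cutoff = 2.5)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$gene2, "c")
  sim <- make_small_atlas(n_modules = 3, module_size = 5, n_tissues = 10,
                          extra_singletons = 20, w = 0.8, seed = 8)
  fs <- fisher_standardize(correlation_matrix(
    preprocess_atlas(sim$atlas)$matrix))
  e25 <- threshold_network(fs, 2.5)$edges
  e30 <- threshold_network(fs, 3.0)$edges
  key <- function(e) paste(e$gene1, e$gene2)
  expect_true(all(key(e30) %in% key(e25)))
})

test_that("blocked network construction is independent of block size", {
  sim <- make_small_atlas(n_modules = 4, module_size = 8, n_tissues = 16,
                          extra_singletons = 30, w = 0.9, seed = 12)
  x <- preprocess_atlas(sim$atlas)$matrix
  n1 <- build_network(x, block_size = 7)
  n2 <- build_network(x, block_size = 1000)
  expect_equal(n1$edges, n2$edges, tolerance = 1e-10)
  expect_equal(n1$f_mean, n2$f_mean, tolerance = 1e-12)
  # and agrees with the dense path
  fs <- fisher_standardize(correlation_matrix(x))
  dense <- threshold_network(fs, 2.5)$edges
  expect_equal(n1$edges$gene1, dense$gene1)
  expect_equal(n1$edges$gene2, dense$gene2)
})

test_that("restricted pass returns all edges incident to chosen genes", {
  sim <- make_small_atlas(n_modules = 3, module_size = 6, n_tissues = 12,
                          extra_singletons = 10, w = 1, seed = 5)
  x <- preprocess_atlas(sim$atlas)$matrix
  full <- build_network(x)
  g <- rownames(x)[1]
  part <- build_network(x, restrict_to = g)
  want <- full$edges[full$edges$gene1 == g | full$edges$gene2 == g]
  expect_setequal(paste(part$edges$gene1, part$edges$gene2),
                  paste(want$gene1, want$gene2))
})

test_that("MCL recovers cliques as modules and yields a partition", {
  cl <- function(genes) t(utils::combn(genes, 2))
  e <- rbind(cl(paste0("a", 1:5)), cl(paste0("b", 1:5)))
  edges <- data.table::data.table(gene1 = e[, 1], gene2 = e[, 2], z = 3)
  res <- detect_modules_mcl(make_network(edges))
  expect_equal(res$n_modules, 2L)
  ass <- res$assignment
  expect_equal(anyDuplicated(ass$gene_id), 0L)
  byg <- split(ass$gene_id, ass$module_id)
  expect_setequal(vapply(byg, function(v) paste(sort(substr(v, 1, 1)),
                                                collapse = ""),
                         character(1)),
                  c("aaaaa", "bbbbb"))
  one <- detect_modules_mcl(make_network(
    data.table::data.table(gene1 = e[1:10, 1], gene2 = e[1:10, 2], z = 3)))
  expect_equal(one$n_modules, 1L)
})

test_that("MCL agrees with connected components on random clique unions", {
  set.seed(77)
  for (rep in 1:5) {
    sizes <- sample(3:8, sample(2:5, 1), replace = TRUE)
    genes <- character(0); edges <- NULL
    for (k in seq_along(sizes)) {
      gs <- sprintf("c%d_%02d", k, seq_len(sizes[k]))
      genes <- c(genes, gs)
      e <- t(utils::combn(gs, 2))
      edges <- rbind(edges, e)
    }
    res <- detect_modules_mcl(make_network(
      data.table::data.table(gene1 = edges[, 1], gene2 = edges[, 2])))
    expect_equal(res$n_modules, length(sizes))
    comp <- sub("_.*", "", res$assignment$gene_id)
    expect_equal(length(unique(paste(comp,
                                     res$assignment$module_id))),
                 length(sizes))
  }
})

test_that("pair graph metrics match definitions and a brute-force cut", {
  edges <- data.table::data.table(
    gene1 = c("a", "a", "b", "c", "d"),
    gene2 = c("b", "c", "c", "d", "e"))
  net <- make_network(edges, gene_ids = c("a", "b", "c", "d", "e", "f"))
  m <- pair_graph_metrics(net, "a", "b")
  expect_equal(m$shortest_path_len, 1)
  expect_equal(m$clustering_coeff_1, 1)  # a's neighbors b,c are linked
  m2 <- pair_graph_metrics(net, "a", "f")
  expect_true(is.infinite(m2$shortest_path_len))
  expect_equal(m2$edge_connectivity, 0L)
  # two triangles joined by one bridge: connectivity 1 across the bridge
  bridge <- data.table::data.table(
    gene1 = c("p", "p", "q", "x", "x", "y", "q"),
    gene2 = c("q", "r", "r", "y", "z", "z", "x"))
  nb <- make_network(bridge)
  expect_equal(pair_graph_metrics(nb, "p", "z")$edge_connectivity, 1L)
  expect_error(pair_graph_metrics(net, "a", "nope"), "absent")
})

test_that("edge connectivity equals exhaustive edge-subset removal", {
  set.seed(99)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    vs <- paste0("v", seq_len(n))
    all_pairs <- t(utils::combn(vs, 2))
    m <- sample(3:min(12, nrow(all_pairs)), 1)
    pick <- all_pairs[sample(nrow(all_pairs), m), , drop = FALSE]
    edges <- data.table::data.table(gene1 = pick[, 1], gene2 = pick[, 2])
    st <- sample(vs, 2)
    got <- pair_graph_metrics(make_network(edges, gene_ids = vs),
                              st[1], st[2])$edge_connectivity
    want <- oracle_edge_connectivity(
      data.frame(from = pick[, 1], to = pick[, 2]), st[1], st[2])
    expect_equal(got, want)
  }
})

test_that("relabeling genes permutes but preserves the degree multiset", {
  sim <- make_small_atlas(n_modules = 3, module_size = 6, n_tissues = 10,
                          w = 0.95, seed = 21, extra_singletons = 10)
  x <- preprocess_atlas(sim$atlas)$matrix
  net1 <- build_network(x)
  x2 <- x
  rownames(x2) <- rev(rownames(x))
  net2 <- build_network(x2[order(rownames(x2)), ])
  deg <- function(net) sort(table(c(net$edges$gene1, net$edges$gene2)))
  expect_equal(as.integer(deg(net1)), as.integer(deg(net2)))
})
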