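# Shared-neighbor proportions, the six-type classifier, enrichment and
# age summaries.

test_that("shared-neighbor proportions follow the set definitions", {
  # N1 = {a,b,c,d}, N2 = {c,d,e}: overlap 2 -> (0.5, 2/3)
  edges <- data.table::data.table(
    gene1 = c("g1", "g1", "g1", "g1", "g2", "g2", "g2"),
    gene2 = c("a", "b", "c", "d", "c", "d", "e"))
  net <- make_network(edges)
  pr <- shared_neighbor_proportions(net, "g1", "g2")
  expect_equal(pr$gene1common, 0.5)
  expect_equal(pr$gene2common, 2 / 3, tolerance = 1e-12)
  expect_equal(c(pr$n1, pr$n2), c(4L, 3L))
  # identical neighbor sets -> (1, 1); disjoint -> (0, 0)
  e2 <- data.table::data.table(gene1 = c("u", "u", "v", "v"),
                               gene2 = c("a", "b", "a", "b"))
  pr2 <- shared_neighbor_proportions(make_network(e2), "u", "v")
  expect_equal(c(pr2$gene1common, pr2$gene2common), c(1, 1))
  e3 <- data.table::data.table(gene1 = c("u", "v"), gene2 = c("a", "b"))
  pr3 <- shared_neighbor_proportions(make_network(e3), "u", "v")
  expect_equal(c(pr3$gene1common, pr3$gene2common), c(0, 0))
  # the partner itself is excluded from both neighbor sets
  e4 <- data.table::data.table(gene1 = c("u", "u", "v"),
                               gene2 = c("v", "a", "a"))
  pr4 <- shared_neighbor_proportions(make_network(e4), "u", "v")
  expect_equal(c(pr4$n1, pr4$n2), c(1L, 1L))
  expect_equal(c(pr4$gene1common, pr4$gene2common), c(1, 1))
  expect_error(shared_neighbor_proportions(net, "g1", "zz"), "absent")
})

test_that("the geometric classifier reproduces every rule", {
  cl <- function(g1c, g2c, n1 = 20, n2 = 20)
    classify_pair_type(g1c, g2c, n1, n2)
  expect_equal(cl(1.0, 1.0), "I")
  expect_equal(cl(0.55, 0.48), "II")     # dist to (.5,.5) ~ 0.054
  expect_equal(cl(0.95, 0.02), "III")    # dist to (1,0) ~ 0.054
  expect_equal(cl(0.02, 0.95), "III")    # swap-invariant center
  expect_equal(cl(0.05, 0.08), "IV")     # dist to (0,0) ~ 0.094
  expect_equal(cl(0.3, 0.4), "unclassified")
  expect_equal(classify_pair_type(0, 0, 12, 0), "V")
  expect_equal(classify_pair_type(0, 0, 0, 12), "V")
  expect_equal(classify_pair_type(0, 0, 0, 0), "VI")
  expect_equal(classify_pair_type(0, 0, 5, 50), "excluded")
  expect_equal(classify_pair_type(0, 0, 0, 5), "excluded")
  expect_error(classify_pair_type(0, 0, -1, 5), "negative")
  expect_error(classify_pair_type(1.4, 0, 20, 20), "0, 1")
})

test_that("classifier discs are pairwise disjoint on a 0.01 grid", {
  g <- seq(0, 1, by = 0.01)
  pts <- expand.grid(x = g, y = g)
  centers <- rbind(c(1, 1), c(0.5, 0.5), c(1, 0), c(0, 1), c(0, 0))
  d <- sapply(seq_len(nrow(centers)), function(k)
    sqrt((pts$x - centers[k, 1])^2 + (pts$y - centers[k, 2])^2) <= 0.1)
  # type III has two centers forming one class
  hits <- cbind(d[, 1], d[, 2], d[, 3] | d[, 4], d[, 5])
  expect_equal(max(rowSums(hits)), 1L)
})

test_that("classification is symmetric under swapping pair members", {
  set.seed(13)
  swap_map <- c(I = "I", II = "II", III = "III", IV = "IV", V = "V",
                VI = "VI", unclassified = "unclassified",
                excluded = "excluded")
  for (i in 1:50) {
    g1c <- stats::runif(1); g2c <- stats::runif(1)
    n1 <- sample(0:40, 1); n2 <- sample(0:40, 1)
    a <- classify_pair_type(g1c, g2c, n1, n2)
    b <- classify_pair_type(g2c, g1c, n2, n1)
    expect_identical(swap_map[[a]], b)
  }
})

test_that("batch classification matches the per-pair path", {
  b <- generate_divergence_benchmark(n_pairs = 30, seed = 3)
  ev <- evaluate_divergence_recovery(b)
  expect_equal(ev$accuracy, 1)
})

test_that("enrichment log2 ratios and binomial p-values are exact", {
  rec <- data.table::data.table(
    dup_type = c(rep("WGD", 10), rep("tandem", 30)),
    type_label = c(rep("I", 5), rep("IV", 5), rep("I", 5), rep("IV", 25)))
  enr <- type_by_duptype_enrichment(rec)
  # marginal WGD proportion 0.25; class I has 5/10 WGD -> log2(2) = 1
  row <- enr[enr$type_label == "I" & enr$dup_type == "WGD"]
  expect_equal(row$log2_ratio, 1)
  expect_equal(row$p_value, oracle_binom_p(5, 10, 0.25), tolerance = 1e-12)
  # observed equal to expected -> ratio 0
  rec2 <- data.table::data.table(
    dup_type = rep(c("WGD", "tandem"), 20),
    type_label = rep(c("I", "IV"), each = 20))
  enr2 <- type_by_duptype_enrichment(rec2)
  expect_true(all(abs(enr2$log2_ratio) < 1e-12))
  # empty cell reports -Inf with a valid binomial p
  rec3 <- data.table::data.table(
    dup_type = c(rep("WGD", 5), rep("tandem", 15)),
    type_label = c(rep("I", 5), rep("IV", 15)))
  enr3 <- type_by_duptype_enrichment(rec3)
  r0 <- enr3[enr3$type_label == "I" & enr3$dup_type == "tandem"]
  expect_identical(r0$log2_ratio, -Inf)
  expect_equal(r0$p_value, oracle_binom_p(0, 5, 0.75), tolerance = 1e-12)
})

test_that("binomial cell p-values match enumeration for many cells", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(1:20, 1); x <- sample(0:n, 1); p <- stats::runif(1, 0.05, 0.95)
    expect_equal(stats::binom.test(x, n, p)$p.value, oracle_binom_p(x, n, p),
                 tolerance = 1e-9)
  }
})

test_that("dS normalization and the rank-sum comparison behave", {
  rec <- data.table::data.table(
    dup_type = c(rep("WGD", 6), rep("inserted", 6)),
    dS = c(0.1, 0.12, 0.2, 0.15, 0.11, 0.19,
           0.5, 0.6, 0.45, 0.66, 0.52, 0.58),
    type_label = rep(c("I", "IV"), each = 6))
  out <- ds_by_type_summary(rec)
  wgd_norm <- rec$dS[rec$dup_type == "WGD"] / out$sd_wgd
  expect_equal(stats::sd(wgd_norm), 1, tolerance = 1e-12)
  expect_equal(out$test$p.value,
               oracle_ranksum_p(rec$dS[rec$type_label %in% c("I")],
                                rec$dS[rec$type_label %in% c("IV")]),
               tolerance = 1e-9)
  rec_flat <- data.table::copy(rec)
  rec_flat$dS[rec_flat$dup_type == "WGD"] <- 0.2
  expect_error(ds_by_type_summary(rec_flat), "sd")
})

test_that("rank-sum p equals exhaustive label permutation for small n", {
  set.seed(17)
  for (i in 1:6) {
    x <- stats::runif(sample(3:5, 1)); y <- stats::runif(sample(3:5, 1))
    got <- stats::wilcox.test(x, y, alternative = "two.sided")$p.value
    expect_equal(got, oracle_ranksum_p(x, y), tolerance = 1e-9)
  }
})
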