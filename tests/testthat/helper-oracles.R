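# Independent brute-force oracles used across the suite.  Each one is a
# direct, unoptimized statement of the quantity's definition, kept free
# of the package's implementation path.

# Exhaustive global-alignment score: enumerate every alignment (monotone
# column path) of two short peptides and score it with BLOSUM62-with-X
# and affine gaps (gap of length L costs open + L * extend).
oracle_nw_score <- function(s1, s2, gap_open = 11, gap_extend = 1) {
  mat <- coexdiv:::.blosum62x()
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    # state: 0 = last column was a match, 1 = gap in seq2, 2 = gap in seq1
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      rec(i + 1, j + 1, score + mat[a[i], b[j]], 0)
    if (i <= length(a))
      rec(i + 1, j, score - (if (state == 1) gap_extend else
        gap_open + gap_extend), 1)
    if (j <= length(b))
      rec(i, j + 1, score - (if (state == 2) gap_extend else
        gap_open + gap_extend), 2)
  }
  rec(1, 1, 0, -1)
  best
}

# Minimum number of edges to remove to disconnect s from t, by trying
# all edge subsets in increasing size.
oracle_edge_connectivity <- function(edges, s, t) {
  verts <- unique(c(edges$from, edges$to, s, t))
  m <- nrow(edges)
  for (k in 0:m) {
    for (drop in if (k == 0) list(integer(0)) else
         asplit(utils::combn(m, k), 2)) {
      g <- igraph::graph_from_data_frame(edges[setdiff(seq_len(m), drop), ,
                                               drop = FALSE],
                                         directed = FALSE, vertices = verts)
      if (!is.finite(igraph::distances(g, s, t)[1, 1])) return(k)
    }
  }
  m
}

# Two-sided exact binomial p-value by direct enumeration of outcomes
# whose likelihood does not exceed that of the observation.
oracle_binom_p <- function(x, n, p) {
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# Two-sided rank-sum p-value by exhaustive permutation of group labels.
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# tiny deterministic atlas: k modules of given size + singletons
make_small_atlas <- function(n_modules = 2, module_size = 5, n_tissues = 8,
                             extra_singletons = 0, w = 1, noise_sd = 0,
                             seed = 42) {
  spec <- atlas_spec(n_genes = n_modules * module_size + extra_singletons,
                     n_tissues = n_tissues, n_modules = n_modules,
                     module_sizes = rep(module_size, n_modules),
                     within_module_corr = w, noise_sd = noise_sd,
                     replicates_per_tissue = 2, seed = seed)
  generate_expression_atlas(spec)
}

# network object from a bare edge list (helper for divergence tests)
make_network <- function(edges, gene_ids = NULL) {
  ed <- data.table::as.data.table(edges)
  if (!"z" %in% names(ed)) ed[, z := 3]
  if (is.null(gene_ids)) gene_ids <- sort(unique(c(ed$gene1, ed$gene2)))
  structure(list(gene_ids = gene_ids, edges = ed, cutoff = 2.5),
            class = "coexpression_network")
}
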