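# Subgenome-level analyses of the co-expression network: edge
# fractionation (intra vs inter subgenome), pathway-level paired tests,
# permutation nulls, module enrichment and hub-gene bias.

# subgenome lookup restricted to distinctly anchored genes
.distinct_labels <- function(map) {
  map <- data.table::as.data.table(map)
  map[subgenome %in% c("maize1", "maize2"),
      c("gene_id", "subgenome"), with = FALSE]
}

#' Count intra- and inter-subgenome co-expression edges
#'
#' Partitions the edges among a gene subset by the subgenome labels of
#' their endpoints.  Only genes anchored distinctly to maize1 or maize2
#' contribute; genes labeled ambiguous (or absent from the map) are
#' dropped before counting.  Densities divide observed edge counts by the
#' number of possible pairs of each kind within the subset.
#'
#' @param network a `coexpression_network` (or an edge data.table).
#' @param map subgenome map (`gene_id`, `subgenome`, ...).
#' @param gene_subset optional character vector restricting the analysis
#'   (e.g. one pathway); default: all network genes.
#' @return list of class `edge_fractionation` with counts `m1_intra`,
#'   `m2_intra`, `inter`, possible-pair counts, `densities`, and the
#'   numbers of maize1/maize2 genes used.
#' @export
count_subgenome_edges <- function(network, map, gene_subset = NULL) {
  edges <- if (inherits(network, "coexpression_network"))
    network$edges else data.table::as.data.table(network)
  all_genes <- if (inherits(network, "coexpression_network"))
    network$gene_ids else unique(c(edges$gene1, edges$gene2))
  if (is.null(gene_subset)) gene_subset <- all_genes
  lab <- .distinct_labels(map)
  sg <- stats::setNames(lab$subgenome, lab$gene_id)
  sub <- intersect(gene_subset, names(sg))
  n1 <- sum(sg[sub] == "maize1"); n2 <- sum(sg[sub] == "maize2")
  if (n1 + n2 == 0) stop("no distinctly labeled genes in subset")
  ed <- edges[gene1 %in% sub & gene2 %in% sub]
  s1 <- sg[ed$gene1]; s2 <- sg[ed$gene2]
  m1_intra <- sum(s1 == "maize1" & s2 == "maize1")
  m2_intra <- sum(s1 == "maize2" & s2 == "maize2")
  inter <- sum(s1 != s2)
  possible <- c(m1 = n1 * (n1 - 1) / 2, m2 = n2 * (n2 - 1) / 2,
                inter = as.numeric(n1) * n2)
  dens <- c(m1 = if (possible[["m1"]] > 0) m1_intra / possible[["m1"]] else NA_real_,
            m2 = if (possible[["m2"]] > 0) m2_intra / possible[["m2"]] else NA_real_,
            inter = if (possible[["inter"]] > 0) inter / possible[["inter"]] else NA_real_)
  structure(list(m1_intra = m1_intra, m2_intra = m2_intra, inter = inter,
                 possible_m1 = possible[["m1"]],
                 possible_m2 = possible[["m2"]],
                 possible_inter = possible[["inter"]],
                 densities = dens, n_maize1 = n1, n_maize2 = n2),
            class = "edge_fractionation")
}

# paired two-sample t-test that tolerates the all-differences-zero case
.paired_t <- function(x, y) {
  d <- x - y
  if (all(is.na(d))) return(list(statistic = NA_real_, p.value = NA_real_))
  d <- d[!is.na(d)]
  if (length(d) < 2 || stats::sd(d) == 0) {
    # degenerate variance: no evidence of a difference
    return(list(statistic = 0, p.value = if (all(d == 0)) 1 else NA_real_))
  }
  tt <- stats::t.test(d)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Pathway-level co-expression edge fractionation
#'
#' Computes [count_subgenome_edges()] for every pathway, keeps pathways
#' with at least `min_edges` subgenome-labeled edges and at least
#' `min_wgd_pairs` retained WGD duplicate pairs, and runs paired
#' two-sample t-tests across the retained pathways: maize1 vs maize2
#' intra densities, total intra vs inter density, and the same two
#' comparisons on absolute edge counts.
#'
#' @inheritParams count_subgenome_edges
#' @param pathways named list of gene sets (see [read_gmt()]).
#' @param pairs duplicate-pair table with `gene1`, `gene2`, `dup_type`
#'   used for the WGD-pair filter.
#' @param min_edges minimum labeled edges per pathway (default 7).
#' @param min_wgd_pairs minimum retained WGD pairs whose both members are
#'   in the pathway (default 2).
#' @return list with `per_pathway` (data.table of counts and densities),
#'   `tests` (list of paired t-test results), and `n_retained`.
#' @export
pathway_fractionation <- function(network, map, pathways, pairs,
                                  min_edges = 7L, min_wgd_pairs = 2L) {
  pairs <- data.table::as.data.table(pairs)
  wgd <- pairs[dup_type == "WGD"]
  rows <- list()
  for (pw in names(pathways)) {
    genes <- pathways[[pw]]
    n_wgd <- sum(wgd$gene1 %in% genes & wgd$gene2 %in% genes)
    fr <- tryCatch(count_subgenome_edges(network, map, genes),
                   error = function(e) NULL)
    if (is.null(fr)) next
    total_edges <- fr$m1_intra + fr$m2_intra + fr$inter
    rows[[pw]] <- data.table::data.table(
      pathway = pw, n_genes = length(genes), n_wgd_pairs = n_wgd,
      m1_intra = fr$m1_intra, m2_intra = fr$m2_intra, inter = fr$inter,
      total_edges = total_edges,
      d_m1 = fr$densities[["m1"]], d_m2 = fr$densities[["m2"]],
      d_inter = fr$densities[["inter"]],
      d_intra = (fr$m1_intra + fr$m2_intra) /
        max(fr$possible_m1 + fr$possible_m2, 1),
      retained = total_edges >= min_edges & n_wgd >= min_wgd_pairs)
  }
  per_pathway <- data.table::rbindlist(rows)
  kept <- per_pathway[retained == TRUE]
  if (nrow(kept) < 2)
    stop("fewer than 2 pathways pass the edge/WGD-pair filters")
  tests <- list(
    m1_vs_m2_density = .paired_t(kept$d_m1, kept$d_m2),
    intra_vs_inter_density = .paired_t(kept$d_intra, kept$d_inter),
    m1_vs_m2_count = .paired_t(kept$m1_intra, kept$m2_intra),
    intra_vs_inter_count = .paired_t(kept$m1_intra + kept$m2_intra,
                                     kept$inter))
  list(per_pathway = per_pathway, tests = tests, n_retained = nrow(kept))
}

# decode 1-based index of an unordered pair (i < j) among n items
.decode_pair <- function(idx, n) {
  # idx in 1..choose(n,2); row-major over i: pairs (i, i+1..n)
  i <- n - 1 - floor(sqrt(2 * (choose(n, 2) - idx) + 0.25) - 0.5)
  base <- (i - 1) * n - i * (i - 1) / 2
  j <- idx - base + i
  cbind(as.integer(i), as.integer(j))
}

#' Permutation null for the inter-subgenome edge count
#'
#' Each permutation draws the same number of distinct unordered edges
#' uniformly among `n1 + n2` labeled nodes and counts how many connect
#' the two subgenomes.  The two-sided p-value compares the observed
#' inter-edge count to the null by mean-centered absolute deviation with
#' add-one smoothing.
#'
#' @param n1,n2 numbers of maize1 and maize2 genes.
#' @param n_edges number of edges to draw per permutation.
#' @param observed_inter observed inter-subgenome edge count.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list with `null` (integer vector of inter counts), `p.value`,
#'   `observed`, `null_mean`.
#' @export
permute_edge_null <- function(n1, n2, n_edges, observed_inter,
                              n_perm = 1000L, seed = 1L) {
  n <- n1 + n2
  n_pairs <- choose(n, 2)
  if (n_edges > n_pairs) stop("more edges than possible pairs")
  if (n_edges < 1) stop("need at least one edge")
  set.seed(seed)
  null <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n_pairs, n_edges)
    ij <- .decode_pair(idx, n)
    # nodes 1..n1 are maize1, the rest maize2
    null[b] <- sum((ij[, 1] <= n1) != (ij[, 2] <= n1))
  }
  mu <- mean(null)
  p <- (1 + sum(abs(null - mu) >= abs(observed_inter - mu))) / (1 + n_perm)
  list(null = null, p.value = p, observed = observed_inter, null_mean = mu)
}

#' Contingency test of intra vs inter subgenome edge realization
#'
#' Builds the 2x2 table of (realized edges, unrealized possible pairs)
#' for pooled intra-subgenome pairs versus inter-subgenome pairs and
#' applies a 1-df Pearson chi-square test (no continuity correction):
#' are inter-subgenome pairs co-expressed at a different rate than
#' intra-subgenome pairs?
#'
#' @param fractionation an `edge_fractionation` from
#'   [count_subgenome_edges()].
#' @return list with `statistic`, `p.value`, `table`.
#' @export
contingency_edge_test <- function(fractionation) {
  fr <- fractionation
  intra_obs <- fr$m1_intra + fr$m2_intra
  intra_pos <- fr$possible_m1 + fr$possible_m2
  tab <- rbind(intra = c(edges = intra_obs, non_edges = intra_pos - intra_obs),
               inter = c(edges = fr$inter,
                         non_edges = fr$possible_inter - fr$inter))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has an empty row or column")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p.value = ct$p.value, table = tab)
}

#' Subgenome enrichment of co-expression modules
#'
#' For every module with at least `min_labeled` maize1+maize2 genes,
#' tests whether its subgenome composition departs from the genome-wide
#' background proportions with a 1-df chi-square goodness-of-fit test;
#' p-values are Bonferroni-adjusted by the number of tested modules.
#'
#' @param modules module assignment (data.table `gene_id`, `module_id`,
#'   or the list returned by [detect_modules_mcl()]).
#' @param map subgenome map.
#' @param min_labeled minimum labeled genes per tested module (default 20).
#' @param background optional numeric `c(n_maize1, n_maize2)` background
#'   totals; defaults to the counts in `map`.
#' @return data.table with per-module counts, `statistic`, `p_value`,
#'   `p_adjusted`, `enriched_subgenome` (empty with a warning when no
#'   module qualifies).
#' @export
module_subgenome_enrichment <- function(modules, map, min_labeled = 20L,
                                        background = NULL) {
  if (is.list(modules) && !is.data.frame(modules))
    modules <- modules$assignment
  modules <- data.table::as.data.table(modules)
  lab <- .distinct_labels(map)
  if (is.null(background))
    background <- c(sum(lab$subgenome == "maize1"),
                    sum(lab$subgenome == "maize2"))
  if (any(background <= 0)) stop("background counts must be positive")
  p_bg <- background / sum(background)
  dt <- merge(modules, lab, by = "gene_id")
  counts <- dt[, .(n1 = sum(subgenome == "maize1"),
                   n2 = sum(subgenome == "maize2")), by = module_id]
  counts <- counts[n1 + n2 >= min_labeled]
  if (nrow(counts) == 0L) {
    warning("no module with >= ", min_labeled, " labeled genes")
    return(data.table::data.table(module_id = integer(0), n1 = integer(0),
                                  n2 = integer(0), statistic = numeric(0),
                                  p_value = numeric(0),
                                  p_adjusted = numeric(0),
                                  enriched_subgenome = character(0)))
  }
  res <- counts[, {
    ct <- suppressWarnings(stats::chisq.test(c(n1, n2), p = p_bg))
    .(statistic = unname(ct$statistic), p_value = ct$p.value,
      enriched_subgenome = if (n1 / (n1 + n2) > p_bg[1]) "maize1" else "maize2")
  }, by = .(module_id, n1, n2)]
  res[, p_adjusted := pmin(1, p_value * nrow(res))]
  data.table::setorder(res, p_adjusted)
  res[]
}

#' Detect hub genes against a degree-permutation null
#'
#' Draws `n_perm` uniform random graphs with the observed numbers of
#' nodes and edges, pools their degree distributions, and sets the hub
#' cutoff at the `(1 - alpha)` nearest-rank quantile of the pooled null
#' degrees.  Hubs are genes whose observed degree exceeds the cutoff
#' (strict).  `null_stat = "max"` instead uses the `(1 - alpha)` quantile
#' of the per-permutation maximum degree.
#'
#' @param network a `coexpression_network`.
#' @param n_perm number of permutation graphs (default 1000).
#' @param alpha tail probability for the cutoff (default 0.05).
#' @param null_stat `"pooled"` (default) or `"max"`.
#' @param seed integer seed.
#' @return list of class `hub_result` with `degrees` (named), `cutoff`,
#'   `hub_genes`, `n_permutations`, `alpha`.
#' @export
detect_hub_genes <- function(network, n_perm = 1000L, alpha = 0.05,
                             null_stat = c("pooled", "max"), seed = 1L) {
  null_stat <- match.arg(null_stat)
  stopifnot(inherits(network, "coexpression_network"))
  ed <- network$edges
  if (nrow(ed) == 0L) stop("network has no edges")
  n <- length(network$gene_ids)
  m <- nrow(ed)
  deg_tab <- table(factor(c(ed$gene1, ed$gene2), levels = network$gene_ids))
  degrees <- stats::setNames(as.integer(deg_tab), network$gene_ids)
  set.seed(seed)
  if (null_stat == "pooled") {
    pooled <- integer(n_perm * n)
    for (b in seq_len(n_perm)) {
      g <- igraph::sample_gnm(n, m)
      pooled[(b - 1L) * n + seq_len(n)] <- igraph::degree(g)
    }
    srt <- sort(pooled)
    cutoff <- srt[ceiling((1 - alpha) * length(srt))]
  } else {
    mx <- integer(n_perm)
    for (b in seq_len(n_perm)) {
      g <- igraph::sample_gnm(n, m)
      mx[b] <- max(igraph::degree(g))
    }
    srt <- sort(mx)
    cutoff <- srt[ceiling((1 - alpha) * length(srt))]
  }
  structure(list(degrees = degrees, cutoff = as.integer(cutoff),
                 hub_genes = names(degrees)[degrees > cutoff],
                 n_permutations = n_perm, alpha = alpha,
                 null_stat = null_stat),
            class = "hub_result")
}

#' Subgenome bias of hub genes
#'
#' 1-df chi-square goodness-of-fit of the hub genes' subgenome labels
#' against the background maize1/maize2 proportions (accounting for the
#' different gene numbers of the two subgenomes).
#'
#' @param hubs a `hub_result` from [detect_hub_genes()] (or a character
#'   vector of hub gene IDs).
#' @param map subgenome map.
#' @param background optional `c(n_maize1, n_maize2)`; defaults to the
#'   counts in `map`.
#' @return list with `statistic`, `p.value`, `n_hub_maize1`,
#'   `n_hub_maize2`.
#' @export
hub_subgenome_bias <- function(hubs, map, background = NULL) {
  hub_genes <- if (inherits(hubs, "hub_result")) hubs$hub_genes else hubs
  lab <- .distinct_labels(map)
  if (is.null(background))
    background <- c(sum(lab$subgenome == "maize1"),
                    sum(lab$subgenome == "maize2"))
  sg <- stats::setNames(lab$subgenome, lab$gene_id)
  hl <- sg[intersect(hub_genes, names(sg))]
  if (!length(hl)) stop("no hub gene with a distinct subgenome label")
  n1 <- sum(hl == "maize1"); n2 <- sum(hl == "maize2")
  ct <- suppressWarnings(
    stats::chisq.test(c(n1, n2), p = background / sum(background)))
  list(statistic = unname(ct$statistic), p.value = ct$p.value,
       n_hub_maize1 = n1, n_hub_maize2 = n2)
}

utils::globalVariables(c("subgenome", "gene1", "gene2", "retained",
                         "p_value", "p_adjusted"))
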