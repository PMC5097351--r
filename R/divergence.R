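# Co-expression divergence classification of duplicate pairs.
#
# Each pair is characterized by two shared-neighbor proportions:
# gene1common = |N1 & N2| / |N1| and gene2common = |N1 & N2| / |N2|,
# where Nk is gene k's neighbor set with the duplicate partner excluded.
# The (gene1common, gene2common) point is then matched against five discs
# of radius 0.1 centered at (1,1) [type I, complete sharing], (0.5,0.5)
# [II, partial], (1,0)/(0,1) [III, one-sided], and (0,0) [IV, none];
# pairs with a gene lacking neighbors fall into types V/VI, and pairs
# with fewer than ten neighbors on either side are excluded.

.DIVERGENCE_CENTERS <- list(I = rbind(c(1, 1)),
                            II = rbind(c(0.5, 0.5)),
                            III = rbind(c(1, 0), c(0, 1)),
                            IV = rbind(c(0, 0)))

#' Shared-neighbor proportions of a duplicate pair
#'
#' Computes each member's proportion of co-expression neighbors shared
#' with its duplicate.  The partner gene itself is excluded from both
#' neighbor sets before intersecting, so a direct duplicate-duplicate
#' edge does not inflate the overlap.  A gene with no neighbors gets
#' proportion 0.
#'
#' @param network a `coexpression_network`.
#' @param gene1,gene2 gene IDs present in the network.
#' @return list with `gene1common`, `gene2common`, `n1`, `n2`.
#' @export
shared_neighbor_proportions <- function(network, gene1, gene2) {
  nb <- neighbor_sets(network, c(gene1, gene2))
  .shared_props(nb[[1]], nb[[2]], gene1, gene2,
                all_genes = network$gene_ids)
}

.shared_props <- function(nb1, nb2, gene1, gene2, all_genes = NULL) {
  if (!is.null(all_genes)) {
    miss <- setdiff(c(gene1, gene2), all_genes)
    if (length(miss))
      stop("gene(s) absent from network: ", paste(miss, collapse = ", "))
  }
  n1set <- setdiff(nb1, gene2)
  n2set <- setdiff(nb2, gene1)
  common <- length(intersect(n1set, n2set))
  n1 <- length(n1set); n2 <- length(n2set)
  list(gene1common = if (n1 == 0) 0 else common / n1,
       gene2common = if (n2 == 0) 0 else common / n2,
       n1 = n1, n2 = n2)
}

#' Classify one pair's divergence type from its overlap geometry
#'
#' Applies the six-type rule set: type VI when neither gene has
#' neighbors; type V when exactly one gene has none and the other has at
#' least `min_neighbors`; pairs where either gene has between 1 and
#' `min_neighbors - 1` neighbors (or one has 0 and the other too few) are
#' `excluded`; otherwise the Euclidean distance of
#' `(gene1common, gene2common)` to the four center geometries decides
#' types I--IV, and points outside every disc are `unclassified`.
#'
#' @param gene1common,gene2common shared-neighbor proportions in `[0,1]`.
#' @param n1,n2 neighbor counts (partner excluded).
#' @param radius disc radius of the geometric classifier (default 0.1).
#' @param min_neighbors minimum neighbors per gene for the geometric
#'   classes (default 10).
#' @return one of `"I"..."VI"`, `"unclassified"`, `"excluded"`.
#' @export
classify_pair_type <- function(gene1common, gene2common, n1, n2,
                               radius = 0.1, min_neighbors = 10L) {
  if (n1 < 0 || n2 < 0) stop("negative neighbor counts")
  if (any(c(gene1common, gene2common) < 0) ||
      any(c(gene1common, gene2common) > 1))
    stop("proportions must lie in [0, 1]")
  if (n1 == 0 && n2 == 0) return("VI")
  if (xor(n1 == 0, n2 == 0)) {
    return(if (max(n1, n2) >= min_neighbors) "V" else "excluded")
  }
  if (n1 < min_neighbors || n2 < min_neighbors) return("excluded")
  p <- c(gene1common, gene2common)
  for (ty in names(.DIVERGENCE_CENTERS)) {
    d <- apply(.DIVERGENCE_CENTERS[[ty]], 1,
               function(ct) sqrt(sum((ct - p)^2)))
    if (any(d <= radius)) return(ty)
  }
  "unclassified"
}

#' Classify the divergence of a table of duplicate pairs
#'
#' Batch version of [shared_neighbor_proportions()] +
#' [classify_pair_type()].  Pairs with a member absent from the network
#' node set are treated as having no neighbors for that member (genes
#' filtered out of the atlas or with undefined profiles cannot have
#' edges).
#'
#' @param network a `coexpression_network`.
#' @param pairs data.table with `gene1`, `gene2` (other columns carried
#'   through).
#' @inheritParams classify_pair_type
#' @return data.table with the pair columns plus `n1`, `n2`,
#'   `gene1common`, `gene2common`, `type_label`.
#' @export
classify_divergence <- function(network, pairs, radius = 0.1,
                                min_neighbors = 10L) {
  pairs <- data.table::as.data.table(pairs)
  genes <- unique(c(pairs$gene1, pairs$gene2))
  nb <- neighbor_sets(network, intersect(genes, network$gene_ids))
  get_nb <- function(g) {
    v <- nb[[g]]
    if (is.null(v)) character(0) else v
  }
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    g1 <- pairs$gene1[k]; g2 <- pairs$gene2[k]
    pr <- .shared_props(get_nb(g1), get_nb(g2), g1, g2)
    c(pr, list(type_label = classify_pair_type(
      pr$gene1common, pr$gene2common, pr$n1, pr$n2,
      radius = radius, min_neighbors = min_neighbors)))
  })
  out <- data.table::copy(pairs)
  out[, n1 := vapply(res, `[[`, integer(1), "n1")]
  out[, n2 := vapply(res, `[[`, integer(1), "n2")]
  out[, gene1common := vapply(res, `[[`, numeric(1), "gene1common")]
  out[, gene2common := vapply(res, `[[`, numeric(1), "gene2common")]
  out[, type_label := vapply(res, `[[`, character(1), "type_label")]
  out
}

#' Duplication-type enrichment across divergence classes
#'
#' For every divergence class, compares the observed proportion of each
#' duplication type against its marginal proportion among all
#' non-excluded pairs (the expectation).  Reports the log2 ratio of
#' observed to expected proportion (`-Inf` for empty cells) and a
#' two-sided exact binomial p-value per cell.
#'
#' @param records classified pair table from [classify_divergence()]
#'   (needs `dup_type` and `type_label`).
#' @return data.table with `type_label`, `dup_type`, `observed`,
#'   `n_class`, `expected_prop`, `log2_ratio`, `p_value`.
#' @export
type_by_duptype_enrichment <- function(records) {
  rec <- data.table::as.data.table(records)
  if (!all(c("dup_type", "type_label") %in% names(rec)))
    stop("records need dup_type and type_label columns")
  rec <- rec[type_label != "excluded"]
  if (nrow(rec) == 0L) stop("no classified pairs")
  marg <- prop.table(table(rec$dup_type))
  classes <- sort(unique(rec$type_label))
  out <- list()
  for (tl in classes) {
    sub <- rec[type_label == tl]
    n_class <- nrow(sub)
    for (d in names(marg)) {
      obs <- sum(sub$dup_type == d)
      p_exp <- as.numeric(marg[[d]])
      out[[length(out) + 1L]] <- data.table::data.table(
        type_label = tl, dup_type = d, observed = obs, n_class = n_class,
        expected_prop = p_exp,
        log2_ratio = if (obs == 0) -Inf else
          log2((obs / n_class) / p_exp),
        p_value = stats::binom.test(obs, n_class, p_exp)$p.value)
    }
  }
  data.table::rbindlist(out)
}

#' Duplication-age (dS) distributions across divergence classes
#'
#' Normalizes every pair's dS by the standard deviation of dS among WGD
#' pairs (so WGD ages have unit spread) and summarizes the normalized
#' distribution per divergence class; a two-sided Wilcoxon rank-sum test
#' compares two requested groups of classes (by default the
#' neighbor-sharing classes I--III against the divergent classes IV--V).
#'
#' @param records classified pair table with `dup_type`, `dS`,
#'   `type_label`.
#' @param group1,group2 character vectors of class labels to compare.
#' @return list with `summary` (per-class n, median and quartiles of
#'   normalized dS), `sd_wgd`, and `test` (p.value, statistic, groups).
#' @export
ds_by_type_summary <- function(records, group1 = c("I", "II", "III"),
                               group2 = c("IV", "V")) {
  rec <- data.table::as.data.table(records)
  wgd_ds <- rec$dS[rec$dup_type == "WGD"]
  if (length(wgd_ds) < 2) stop("need at least 2 WGD pairs to normalize dS")
  sd_wgd <- stats::sd(wgd_ds)
  if (sd_wgd == 0) stop("sd of WGD dS is 0; cannot normalize")
  rec <- rec[type_label != "excluded"]
  rec[, norm_ds := dS / sd_wgd]
  summ <- rec[, .(n = .N,
                  q1 = stats::quantile(norm_ds, 0.25),
                  median = stats::median(norm_ds),
                  q3 = stats::quantile(norm_ds, 0.75)),
              by = type_label][order(type_label)]
  x <- rec[type_label %in% group1, norm_ds]
  y <- rec[type_label %in% group2, norm_ds]
  test <- if (length(x) && length(y)) {
    wt <- stats::wilcox.test(x, y, alternative = "two.sided")
    list(p.value = wt$p.value, statistic = unname(wt$statistic),
         groups = list(group1 = group1, group2 = group2))
  } else NULL
  list(summary = summ, sd_wgd = sd_wgd, test = test)
}

utils::globalVariables(c("type_label", "n1", "n2", "gene1common",
                         "gene2common", "norm_ds", "dS", ".N", "."))
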