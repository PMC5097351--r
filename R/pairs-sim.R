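# Planted duplicate pairs over an existing module structure.

# truncated-at-zero normal by resampling
.rtruncnorm0 <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

# draw duplication types and dS values for a set of pairs
.draw_dup_types <- function(n, type_proportions, ds_params) {
  types <- sample(names(type_proportions), n, replace = TRUE,
                  prob = type_proportions)
  ds <- numeric(n)
  for (ty in unique(types)) {
    sel <- which(types == ty)
    p <- ds_params[[ty]]
    ds[sel] <- .rtruncnorm0(length(sel), p[["mean"]], p[["sd"]])
  }
  list(dup_type = types, dS = ds)
}

# split n into integer counts proportional to mix (largest remainder)
.apportion <- function(n, mix) {
  raw <- n * mix / sum(mix)
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    up <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[up] <- cnt[up] + 1L
  }
  stats::setNames(as.integer(cnt), names(mix))
}

#' Plant duplicate pairs with known divergence labels on module structure
#'
#' Realizes planted co-expression divergence through module co-membership:
#' type I pairs are two genes of the same planted module, type IV pairs
#' span two different modules, type V pairs one module gene and one
#' unassigned singleton, type VI two singletons.  Each pair also carries a
#' duplication type drawn from `type_proportions` and a dS value from its
#' type's truncated normal distribution.  Divergence types that require
#' partial neighbor overlap (II, III, unclassified) cannot be realized on
#' a plain module partition; use [generate_divergence_benchmark()] for
#' those.
#'
#' @param spec a [pair_spec()].
#' @param module_labels named integer vector of module labels (`NA` =
#'   unassigned), as returned by [generate_expression_atlas()].
#' @param min_module_size modules smaller than this are not used to host
#'   planted pairs (default 12, so that both members keep at least ten
#'   neighbors after excluding each other).
#' @return data.table with columns `gene1`, `gene2`, `dup_type`, `dS`,
#'   `planted_divergence`.
#' @export
generate_duplicate_pairs <- function(spec, module_labels,
                                     min_module_size = 12L) {
  stopifnot(inherits(spec, "pair_spec"))
  set.seed(spec$seed)
  mix <- spec$divergence_mix
  bad <- setdiff(names(mix)[mix > 0], c("I", "IV", "V", "VI"))
  if (length(bad))
    stop("divergence types ", paste(bad, collapse = ", "),
         " need mixed-profile structure; use generate_divergence_benchmark()")
  counts <- stats::setNames(rep(0L, 4L), c("I", "IV", "V", "VI"))
  ap <- .apportion(spec$n_pairs, mix)
  counts[names(ap)] <- ap
  genes <- names(module_labels)
  sizes <- table(module_labels)
  big_mods <- as.integer(names(sizes)[sizes >= min_module_size])
  if (any(counts[c("I", "IV", "V")] > 0) && length(big_mods) == 0L)
    stop("no module of size >= ", min_module_size, " to host planted pairs")
  if (counts[["IV"]] > 0 && length(big_mods) < 2L)
    stop("type IV pairs require at least two modules")
  pool_mod <- lapply(big_mods, function(m) genes[which(module_labels == m)])
  names(pool_mod) <- as.character(big_mods)
  pool_single <- genes[is.na(module_labels)]

  take_mod <- function(m, k) {
    avail <- pool_mod[[as.character(m)]]
    if (length(avail) < k) stop("requested pairs exceed available genes")
    picked <- avail[seq_len(k)]
    pool_mod[[as.character(m)]] <<- avail[-seq_len(k)]
    picked
  }
  take_single <- function(k) {
    if (length(pool_single) < k) stop("requested pairs exceed available genes")
    picked <- pool_single[seq_len(k)]
    pool_single <<- pool_single[-seq_len(k)]
    picked
  }

  g1 <- character(0); g2 <- character(0); lab <- character(0)
  # type I: both members in the same module, round-robin over modules
  if (counts[["I"]] > 0) {
    ms <- rep(big_mods, length.out = counts[["I"]])
    for (m in ms) {
      p <- take_mod(m, 2L)
      g1 <- c(g1, p[1]); g2 <- c(g2, p[2]); lab <- c(lab, "I")
    }
  }
  # type IV: members in two different modules
  if (counts[["IV"]] > 0) {
    ma <- rep(big_mods, length.out = counts[["IV"]])
    mb <- rep(c(big_mods[-1], big_mods[1]), length.out = counts[["IV"]])
    for (i in seq_len(counts[["IV"]])) {
      g1 <- c(g1, take_mod(ma[i], 1L)); g2 <- c(g2, take_mod(mb[i], 1L))
      lab <- c(lab, "IV")
    }
  }
  # type V: one module gene, one singleton
  if (counts[["V"]] > 0) {
    ms <- rep(big_mods, length.out = counts[["V"]])
    for (m in ms) {
      g1 <- c(g1, take_mod(m, 1L)); g2 <- c(g2, take_single(1L))
      lab <- c(lab, "V")
    }
  }
  # type VI: two singletons
  if (counts[["VI"]] > 0) {
    for (i in seq_len(counts[["VI"]])) {
      s <- take_single(2L)
      g1 <- c(g1, s[1]); g2 <- c(g2, s[2]); lab <- c(lab, "VI")
    }
  }
  dup <- .draw_dup_types(length(g1), spec$type_proportions, spec$ds_params)
  cp <- .canonical_pairs(g1, g2)
  data.table::data.table(gene1 = cp$gene1, gene2 = cp$gene2,
                         dup_type = dup$dup_type, dS = dup$dS,
                         planted_divergence = lab)
}
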