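# Synthetic post-WGD genome: two subgenomes in paired homeologous blocks,
# fractionation (lost maize2 homeologs), tandem arrays, non-syntenic
# insertions, and pathway gene sets anchored on retained WGD pairs.

#' Generate a synthetic subgenome/synteny structure
#'
#' Lays out maize1 genes in homeologous blocks with maize2 copies on a
#' second chromosome set.  Each maize1 gene is an ancestral homeolog
#' slot; its maize2 partner is lost with probability `fractionation_rate`
#' (when `n_maize2` is supplied it fixes the retained count exactly and
#' overrides the rate).  Optional tandem copies sit adjacent to host
#' genes inside a block; inserted genes are placed at non-syntenic
#' positions and labeled ambiguous.  Pathway gene sets are emitted so
#' that each contains at least two retained WGD pairs.
#'
#' @param spec a [subgenome_spec()].
#' @param gene_ids optional character vector of gene IDs to draw names
#'   from (e.g. atlas genes); by default IDs are invented.
#' @return list with `map` (subgenome map data.table), `pairs` (planted
#'   duplicate pairs with `dup_type`), `retained_pairs`, `lost_genes`
#'   (maize1 genes whose homeolog was fractionated), `pathways` (named
#'   list), and `spec`.
#' @export
generate_subgenome_structure <- function(spec, gene_ids = NULL) {
  stopifnot(inherits(spec, "subgenome_spec"))
  set.seed(spec$seed)
  n1 <- spec$n_maize1
  # fractionation: which ancestral slots lost their maize2 copy
  if (is.null(spec$n_maize2)) {
    lost <- which(stats::rbinom(n1, 1L, spec$fractionation_rate) == 1L)
  } else {
    n_lost <- n1 - spec$n_maize2
    lost <- if (n_lost > 0) sort(sample.int(n1, n_lost)) else integer(0)
  }
  n2 <- n1 - length(lost)
  n_total <- n1 + n2 + spec$n_tandem + spec$n_inserted
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("zm%05d", seq_len(n_total))
  } else {
    if (length(gene_ids) < n_total)
      stop("need at least ", n_total, " gene IDs")
    gene_ids <- sample(gene_ids, n_total)
  }
  nxt <- 0L
  take_ids <- function(k) { out <- gene_ids[nxt + seq_len(k)]; nxt <<- nxt + k; out }

  block_size <- 40L
  n_blocks <- ceiling(n1 / block_size)
  slot_block <- rep(seq_len(n_blocks), each = block_size)[seq_len(n1)]
  slot_rank <- unlist(lapply(table(slot_block), seq_len), use.names = FALSE)
  gap <- 10000L
  m1_ids <- take_ids(n1)
  m1 <- data.table::data.table(
    gene_id = m1_ids, subgenome = "maize1",
    block_id = sprintf("B%03d", slot_block),
    chrom = sprintf("chr%d", (slot_block - 1L) %% 5L + 1L),
    start = slot_rank * gap, end = slot_rank * gap + 3000L)
  retained <- setdiff(seq_len(n1), lost)
  m2_ids <- take_ids(n2)
  m2 <- data.table::data.table(
    gene_id = m2_ids, subgenome = "maize2",
    block_id = sprintf("B%03d", slot_block[retained]),
    chrom = sprintf("chr%d", (slot_block[retained] - 1L) %% 5L + 6L),
    start = slot_rank[retained] * gap,
    end = slot_rank[retained] * gap + 3000L)
  retained_pairs <- data.table::data.table(gene1 = m1_ids[retained],
                                           gene2 = m2_ids)
  lost_genes <- m1_ids[lost]

  # tandem copies adjacent to random syntenic hosts (0 intervening genes)
  tandem_pairs <- NULL; tnd <- NULL
  if (spec$n_tandem > 0) {
    all_syn <- rbind(m1, m2)
    hosts <- all_syn[sample(nrow(all_syn), spec$n_tandem)]
    t_ids <- take_ids(spec$n_tandem)
    tnd <- data.table::data.table(
      gene_id = t_ids, subgenome = hosts$subgenome,
      block_id = hosts$block_id, chrom = hosts$chrom,
      start = hosts$start + 4000L, end = hosts$start + 7000L)
    tandem_pairs <- data.table::data.table(gene1 = hosts$gene_id,
                                           gene2 = t_ids)
  }
  # inserted duplicates at non-syntenic positions
  inserted_pairs <- NULL; ins <- NULL
  if (spec$n_inserted > 0) {
    i_ids <- take_ids(spec$n_inserted)
    partners <- sample(c(m1$gene_id, m2$gene_id), spec$n_inserted)
    ins <- data.table::data.table(
      gene_id = i_ids, subgenome = "ambiguous", block_id = NA_character_,
      chrom = sprintf("chr%d", sample.int(10L, spec$n_inserted,
                                          replace = TRUE)),
      start = sample.int(10000000L, spec$n_inserted),
      end = 0L)
    ins[, end := start + 3000L]
    inserted_pairs <- data.table::data.table(gene1 = partners, gene2 = i_ids)
  }
  map <- data.table::rbindlist(list(m1, m2, tnd, ins))

  mk <- function(p, ty) if (is.null(p)) NULL else {
    cp <- .canonical_pairs(p$gene1, p$gene2)
    data.table::data.table(gene1 = cp$gene1, gene2 = cp$gene2, dup_type = ty)
  }
  pairs <- data.table::rbindlist(list(mk(retained_pairs, "WGD"),
                                      mk(tandem_pairs, "tandem"),
                                      mk(inserted_pairs, "inserted")))

  # pathways: each gets >= 2 retained WGD pairs plus random labeled genes
  if (spec$n_pathways > 0 && nrow(retained_pairs) < 2)
    stop("cannot emit pathways: fewer than 2 retained WGD pairs")
  pathways <- list()
  labeled <- c(m1$gene_id, m2$gene_id)
  for (k in seq_len(spec$n_pathways)) {
    size <- sample(seq(spec$pathway_size_range[1],
                       spec$pathway_size_range[2]), 1L)
    n_seed_pairs <- min(max(2L, size %/% 6L), nrow(retained_pairs))
    sel <- sample.int(nrow(retained_pairs), n_seed_pairs)
    core <- c(retained_pairs$gene1[sel], retained_pairs$gene2[sel])
    extra <- sample(setdiff(labeled, core),
                    max(0L, size - length(core)))
    pathways[[sprintf("PWY%04d", k)]] <- c(core, extra)
  }
  list(map = map, pairs = pairs, retained_pairs = retained_pairs,
       lost_genes = lost_genes, pathways = pathways, spec = spec)
}

#' Simulate pathway co-expression edges with controlled subgenome densities
#'
#' For every pathway, each possible gene pair becomes an edge
#' independently with a probability set by the pair's subgenome classes:
#' `density_m1` for maize1 intra pairs, `density_m2` for maize2 intra
#' pairs, `density_inter` for inter-subgenome pairs.  Neutral networks
#' use equal densities; subgenome-dominant networks raise `density_m1`.
#'
#' @param map subgenome map.
#' @param pathways named list of gene sets.
#' @param density_m1,density_m2,density_inter edge probabilities.
#' @param seed integer seed.
#' @return edge data.table (`gene1`, `gene2`, `z`).
#' @export
simulate_subgenome_edges <- function(map, pathways, density_m1 = 0.15,
                                     density_m2 = 0.15,
                                     density_inter = 0.15, seed = 1L) {
  set.seed(seed)
  lab <- .distinct_labels(map)
  sg <- stats::setNames(lab$subgenome, lab$gene_id)
  out <- list()
  for (pw in names(pathways)) {
    genes <- intersect(pathways[[pw]], names(sg))
    if (length(genes) < 2) next
    cmb <- utils::combn(sort(genes), 2L)
    s1 <- sg[cmb[1, ]]; s2 <- sg[cmb[2, ]]
    p <- ifelse(s1 != s2, density_inter,
                ifelse(s1 == "maize1", density_m1, density_m2))
    hit <- stats::runif(length(p)) < p
    if (any(hit))
      out[[pw]] <- data.table::data.table(gene1 = cmb[1, hit],
                                          gene2 = cmb[2, hit])
  }
  edges <- unique(data.table::rbindlist(out))
  if (nrow(edges) == 0L)
    return(data.table::data.table(gene1 = character(0),
                                  gene2 = character(0), z = numeric(0)))
  edges[, z := 3]
  data.table::setorder(edges, gene1, gene2)
  edges[]
}

utils::globalVariables(c("z", "end"))
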