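# Markov clustering (MCL) of the thresholded co-expression graph.
#
# Canonical algorithm with default parameters: add self-loops, column-
# normalize the (binary) adjacency into a stochastic flow matrix, then
# alternate expansion (matrix power 2) and inflation (elementwise power,
# column renormalization), pruning tiny entries, until the flow stops
# changing.  Clusters are read off the attractors (nodes with positive
# return flow); attractor rows that share nodes are merged, and a node
# joins the cluster of its lowest-indexed attractor.

.col_normalize <- function(m) {
  cs <- Matrix::colSums(m)
  cs[cs == 0] <- 1
  m %*% Matrix::Diagonal(x = 1 / cs)
}

#' Detect co-expression modules with Markov clustering
#'
#' Runs MCL on the thresholded network treated as a binary undirected
#' graph (isolated genes are left unassigned).  Defaults follow the
#' canonical algorithm: inflation 2, expansion 2, self-loop weight 1,
#' prune threshold 1e-5, convergence when the largest entry change drops
#' below 1e-6, at most 200 iterations.
#'
#' @param network a `coexpression_network` (or an edge data.table with
#'   columns `gene1`, `gene2`).
#' @param inflation elementwise inflation exponent (default 2).
#' @param self_loop_weight self-loop weight added to every node.
#' @param prune entries below this are dropped after each inflation.
#' @param tol convergence tolerance on the max entry change.
#' @param max_iter iteration cap; non-convergence is an error.
#' @param min_module_size modules of at least this many genes are counted
#'   as reported modules (default 10).
#' @return list with `assignment` (data.table `gene_id`, `module_id`),
#'   `sizes` (named integer vector by module), `n_modules`,
#'   `n_modules_large`, and `iterations`.
#' @export
detect_modules_mcl <- function(network, inflation = 2,
                               self_loop_weight = 1, prune = 1e-5,
                               tol = 1e-6, max_iter = 200L,
                               min_module_size = 10L) {
  edges <- if (inherits(network, "coexpression_network"))
    network$edges else data.table::as.data.table(network)
  if (nrow(edges) == 0L) stop("empty network: no edges to cluster")
  nodes <- sort(unique(c(edges$gene1, edges$gene2)))
  n <- length(nodes)
  i <- match(edges$gene1, nodes); j <- match(edges$gene2, nodes)
  a <- Matrix::sparseMatrix(i = c(i, j, seq_len(n)),
                            j = c(j, i, seq_len(n)),
                            x = c(rep(1, 2 * length(i)),
                                  rep(self_loop_weight, n)),
                            dims = c(n, n))
  m <- .col_normalize(a)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter)
      stop(sprintf("MCL did not converge after %d iterations", max_iter))
    m2 <- m %*% m                                   # expansion (power 2)
    m2 <- as(m2, "CsparseMatrix")
    m2@x <- m2@x^inflation                          # inflation
    m2 <- Matrix::drop0(m2 * (m2 > prune))          # prune
    m2 <- .col_normalize(m2)
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < tol) break
  }
  # attractors have positive return flow; their rows list cluster members
  attractors <- which(Matrix::diag(m) > prune)
  if (!length(attractors)) stop("MCL produced no attractors")
  member_of <- rep(NA_integer_, n)                  # lowest-indexed attractor
  owner <- rep(NA_integer_, n)
  for (a_i in rev(attractors)) {
    mem <- which(m[a_i, ] > prune)
    owner[mem] <- a_i
  }
  # merge attractors that claim overlapping members (shared nodes)
  cluster_of_attractor <- stats::setNames(seq_along(attractors), attractors)
  for (a_i in attractors) {
    mem <- which(m[a_i, ] > prune)
    other <- unique(owner[mem])
    other <- other[!is.na(other) & other != a_i]
    for (o in other) {
      ca <- cluster_of_attractor[[as.character(a_i)]]
      co <- cluster_of_attractor[[as.character(o)]]
      if (ca != co)
        cluster_of_attractor[cluster_of_attractor == max(ca, co)] <-
          min(ca, co)
    }
  }
  member_of <- cluster_of_attractor[as.character(owner)]
  # any node missed by every attractor row follows its strongest column flow
  orphan <- which(is.na(member_of))
  for (o in orphan) {
    col <- m[, o]
    best <- attractors[which.max(col[attractors])]
    member_of[o] <- cluster_of_attractor[[as.character(best)]]
  }
  module_id <- as.integer(factor(rank(member_of, ties.method = "min")))
  assignment <- data.table::data.table(gene_id = nodes, module_id = module_id)
  sizes <- table(assignment$module_id)
  # renumber by decreasing size for stable reporting
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  assignment[, module_id := relabel[as.character(module_id)]]
  sizes <- sort(table(assignment$module_id), decreasing = TRUE)
  sizes <- stats::setNames(as.integer(sizes), names(sizes))
  list(assignment = assignment[order(gene_id)],
       sizes = sizes,
       n_modules = length(sizes),
       n_modules_large = sum(sizes >= min_module_size),
       iterations = it)
}

utils::globalVariables(c("module_id", "gene_id"))
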