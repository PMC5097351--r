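#' Graph-theoretic divergence metrics for a duplicate pair
#'
#' Measures how far apart two duplicates sit in the co-expression graph:
#' the number of edges on the shortest path between them (`Inf` when they
#' lie in different components), each gene's local clustering coefficient
#' (how close its neighborhood is to a clique; 0 for degree < 2), and the
#' pair's edge connectivity -- the minimum number of edges whose removal
#' disconnects the two genes.
#'
#' @param network a `coexpression_network`.
#' @param gene1,gene2 gene IDs, both present in the network node set.
#' @return list with `shortest_path_len`, `clustering_coeff_1`,
#'   `clustering_coeff_2`, `edge_connectivity`.
#' @export
pair_graph_metrics <- function(network, gene1, gene2) {
  stopifnot(inherits(network, "coexpression_network"))
  miss <- setdiff(c(gene1, gene2), network$gene_ids)
  if (length(miss))
    stop("gene(s) absent from network: ", paste(miss, collapse = ", "))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("gene1", "gene2")], directed = FALSE,
    vertices = data.frame(name = network$gene_ids))
  sp <- igraph::distances(g, v = gene1, to = gene2)[1, 1]
  cc <- unname(igraph::transitivity(g, type = "localundirected",
                                    vids = c(gene1, gene2)))
  cc[is.nan(cc)] <- 0
  ec <- if (is.infinite(sp)) 0L else
    igraph::edge_connectivity(g, source = gene1, target = gene2)
  list(shortest_path_len = sp,
       clustering_coeff_1 = cc[1], clustering_coeff_2 = cc[2],
       edge_connectivity = as.integer(ec))
}
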