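#' Pearson correlation matrix of gene expression profiles
#'
#' Correlates every pair of genes across tissue columns.  Genes with zero
#' variance (constant profiles) have no defined correlation; they are
#' flagged and their rows/columns set to `NA`.
#'
#' @param x numeric genes x tissues matrix (row names = gene IDs),
#'   typically the asinh-transformed, filtered atlas.
#' @return correlation matrix with attribute `undefined` (character vector
#'   of zero-variance gene IDs).
#' @export
correlation_matrix <- function(x) {
  if (ncol(x) < 3) stop("need at least 3 tissue columns for correlation")
  sds <- apply(x, 1, stats::sd)
  undef <- rownames(x)[sds == 0]
  r <- suppressWarnings(stats::cor(t(x)))
  if (length(undef)) {
    r[undef, ] <- NA_real_
    r[, undef] <- NA_real_
  }
  diag(r) <- 1
  attr(r, "undefined") <- undef
  r
}

#' Fisher-transform and standardize a correlation matrix
#'
#' Applies `f = atanh(R)` to every off-diagonal pair (correlations of
#' magnitude 1 are clamped to `1 - 1e-12` so duplicated profiles keep a
#' large finite score) and standardizes so the pooled edge-score
#' distribution has mean 0 and standard deviation 1.  The standardization
#' population is the upper triangle of all defined pairs, each unordered
#' pair counted once.
#'
#' @param r correlation matrix from [correlation_matrix()].
#' @return list with `z` (standardized score matrix, `NA` diagonal),
#'   `f_mean`, `f_sd`, `n_pairs` and `undefined`.
#' @export
fisher_standardize <- function(r) {
  undef <- attr(r, "undefined")
  if (is.null(undef)) undef <- character(0)
  f <- .fisher_z(r)
  diag(f) <- NA_real_
  up <- upper.tri(f) & !is.na(f)
  if (!any(up)) stop("no defined gene pairs to standardize")
  mu <- mean(f[up])
  sdv <- stats::sd(f[up])
  if (sdv == 0) stop("degenerate edge-score distribution (sd = 0)")
  z <- (f - mu) / sdv
  list(z = z, f_mean = mu, f_sd = sdv, n_pairs = sum(up),
       undefined = undef)
}

#' Threshold a standardized score matrix into an edge list
#'
#' An undirected edge joins every gene pair with `z > cutoff` (strict);
#' self-pairs and undefined pairs are never edges.
#'
#' @param z standardized score matrix, or the list from
#'   [fisher_standardize()].
#' @param cutoff edge threshold on the standardized scale (default 2.5).
#' @return a `coexpression_network`: list with `gene_ids`, `edges`
#'   (data.table `gene1`, `gene2`, `z`), and `cutoff`.
#' @export
threshold_network <- function(z, cutoff = 2.5) {
  if (is.list(z)) z <- z$z
  ids <- rownames(z)
  hit <- which(upper.tri(z) & !is.na(z) & z > cutoff, arr.ind = TRUE)
  edges <- data.table::data.table(gene1 = ids[hit[, 1]],
                                  gene2 = ids[hit[, 2]],
                                  z = z[hit])
  data.table::setorder(edges, gene1, gene2)
  structure(list(gene_ids = ids, edges = edges, cutoff = cutoff),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %d genes, %d edges (z > %g)\n",
              length(x$gene_ids), nrow(x$edges), x$cutoff))
  invisible(x)
}

#' Build a co-expression network from an expression matrix, in blocks
#'
#' Memory-bounded equivalent of [correlation_matrix()] +
#' [fisher_standardize()] + [threshold_network()]: the all-pairs score
#' matrix is streamed in row blocks, one pass to accumulate the pooled
#' Fisher-score mean and standard deviation and a second pass to emit
#' edges.  Results are independent of `block_size` (up to floating-point
#' roundoff in the pooled moments).  With `restrict_to`, the second pass
#' only visits the given genes and returns the edges incident to them --
#' the standardization is still computed over all pairs.
#'
#' @param x numeric genes x tissues matrix (asinh scale), or an
#'   [expression_atlas()] which is then preprocessed with
#'   [preprocess_atlas()].
#' @param cutoff standardized edge threshold (default 2.5).
#' @param block_size rows per block (default 1024).
#' @param restrict_to optional character vector of gene IDs.
#' @return a `coexpression_network` (see [threshold_network()]) with
#'   additional fields `f_mean`, `f_sd`, `n_pairs`, `undefined`, and
#'   `restricted`.
#' @export
build_network <- function(x, cutoff = 2.5, block_size = 1024L,
                          restrict_to = NULL) {
  if (inherits(x, "expression_atlas")) x <- preprocess_atlas(x)$matrix
  if (ncol(x) < 3) stop("need at least 3 tissue columns")
  n_t <- ncol(x)
  ctr <- x - rowMeans(x)
  ss <- sqrt(rowSums(ctr^2))
  undef <- rownames(x)[ss == 0]
  keep <- ss > 0
  xs <- ctr[keep, , drop = FALSE] / ss[keep]
  ids <- rownames(xs)
  n <- nrow(xs)
  if (n < 2) stop("fewer than two genes with defined profiles")

  blocks <- split(seq_len(n), ceiling(seq_len(n) / block_size))
  # pass 1: pooled moments of the Fisher scores over the upper triangle
  s1 <- 0; s2 <- 0; cnt <- 0
  for (bl in blocks) {
    f <- .fisher_z(tcrossprod(xs[bl, , drop = FALSE], xs))
    for (k in seq_along(bl)) {
      gi <- bl[k]
      if (gi < n) {
        v <- f[k, (gi + 1L):n]
        s1 <- s1 + sum(v); s2 <- s2 + sum(v * v); cnt <- cnt + length(v)
      }
    }
  }
  if (cnt == 0) stop("no defined gene pairs to standardize")
  mu <- s1 / cnt
  sdv <- sqrt(max(s2 / cnt - mu^2, 0) * cnt / (cnt - 1))
  if (sdv == 0) stop("degenerate edge-score distribution (sd = 0)")
  f_cut <- mu + cutoff * sdv

  # pass 2: emit edges above the threshold
  if (is.null(restrict_to)) {
    rows <- seq_len(n)
  } else {
    rows <- which(ids %in% restrict_to)
    if (!length(rows)) stop("restrict_to matches no defined gene")
  }
  rblocks <- split(rows, ceiling(seq_along(rows) / block_size))
  e1 <- list(); e2 <- list(); ez <- list(); nb <- 0L
  for (bl in rblocks) {
    f <- .fisher_z(tcrossprod(xs[bl, , drop = FALSE], xs))
    for (k in seq_along(bl)) {
      gi <- bl[k]
      js <- if (is.null(restrict_to)) {
        if (gi < n) gi + which(f[k, (gi + 1L):n] > f_cut) else integer(0)
      } else {
        setdiff(which(f[k, ] > f_cut), gi)
      }
      if (length(js)) {
        nb <- nb + 1L
        e1[[nb]] <- rep(gi, length(js)); e2[[nb]] <- js
        ez[[nb]] <- (f[k, js] - mu) / sdv
      }
    }
  }
  if (nb) {
    i <- unlist(e1); j <- unlist(e2)
    edges <- data.table::data.table(
      gene1 = ids[pmin(i, j)], gene2 = ids[pmax(i, j)], z = unlist(ez))
    edges <- unique(edges, by = c("gene1", "gene2"))
    data.table::setorder(edges, gene1, gene2)
  } else {
    edges <- data.table::data.table(gene1 = character(0),
                                    gene2 = character(0), z = numeric(0))
  }
  structure(list(gene_ids = ids, edges = edges, cutoff = cutoff,
                 f_mean = mu, f_sd = sdv, n_pairs = cnt,
                 undefined = undef, restricted = restrict_to),
            class = "coexpression_network")
}

#' Neighbor sets of selected genes in a network
#'
#' @param network a `coexpression_network`.
#' @param genes character vector of gene IDs (default: all network genes).
#' @return named list mapping each gene to the character vector of its
#'   co-expression neighbors.
#' @export
neighbor_sets <- function(network, genes = network$gene_ids) {
  stopifnot(inherits(network, "coexpression_network"))
  ed <- network$edges
  adj <- split(c(ed$gene2, ed$gene1), c(ed$gene1, ed$gene2))
  out <- lapply(genes, function(g) {
    v <- adj[[g]]
    if (is.null(v)) character(0) else unique(v)
  })
  names(out) <- genes
  out
}
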