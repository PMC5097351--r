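#' Expression atlas container
#'
#' A thin container for a gene x tissue-replicate TPM matrix plus the map
#' from matrix columns to tissues.  TPM values must be non-negative and
#' complete (no NA); gene IDs must be unique; every column must be mapped
#' to exactly one tissue.
#'
#' @param tpm numeric matrix, genes in rows (row names = gene IDs),
#'   tissue-replicate libraries in columns.
#' @param replicate_map data.table with columns `column`, `tissue` covering
#'   every matrix column, or `NULL` when columns are already per-tissue
#'   (each column is then its own tissue).
#' @return an object of class `expression_atlas`.
#' @export
expression_atlas <- function(tpm, replicate_map = NULL) {
  if (!is.matrix(tpm) || !is.numeric(tpm)) stop("tpm must be a numeric matrix")
  if (is.null(rownames(tpm))) stop("tpm must have gene IDs as row names")
  if (anyDuplicated(rownames(tpm))) stop("duplicate gene IDs")
  if (anyNA(tpm)) stop("TPM matrix contains NA; missing values are not permitted")
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  if (is.null(colnames(tpm))) stop("tpm must have column names")
  if (is.null(replicate_map)) {
    replicate_map <- data.table::data.table(column = colnames(tpm),
                                            tissue = colnames(tpm))
  }
  replicate_map <- data.table::as.data.table(replicate_map)
  missing_cols <- setdiff(colnames(tpm), replicate_map$column)
  if (length(missing_cols))
    stop("columns missing from replicate map: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(replicate_map$column))
    stop("replicate map assigns a column to more than one tissue")
  structure(list(tpm = tpm,
                 replicate_map = replicate_map[column %in% colnames(tpm)]),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat(sprintf("<expression_atlas> %d genes x %d columns (%d tissues)\n",
              nrow(x$tpm), ncol(x$tpm),
              length(unique(x$replicate_map$tissue))))
  invisible(x)
}

#' @export
dim.expression_atlas <- function(x) dim(x$tpm)

#' Average biological replicates into one column per tissue
#'
#' Each tissue column of the result is the arithmetic mean of its replicate
#' libraries; gene order is preserved and tissues keep their first-appearance
#' order in the replicate map.
#'
#' @param atlas an [expression_atlas()].
#' @return an `expression_atlas` with one column per tissue.
#' @export
average_replicates <- function(atlas) {
  stopifnot(inherits(atlas, "expression_atlas"))
  map <- atlas$replicate_map
  tissues <- unique(map$tissue)
  out <- matrix(0, nrow(atlas$tpm), length(tissues),
                dimnames = list(rownames(atlas$tpm), tissues))
  for (t in tissues) {
    cols <- map$column[map$tissue == t]
    if (!length(cols)) stop("tissue with zero replicate columns: ", t)
    sub <- atlas$tpm[, cols, drop = FALSE]
    out[, t] <- rowMeans(sub)
  }
  expression_atlas(out)
}

#' Filter to expressed genes
#'
#' A gene is kept when it has TPM > 0 in at least three tissues, or
#' TPM > 5 in at least one tissue (both comparisons strict).  The filter
#' operates on replicate-averaged per-tissue values.
#'
#' @param atlas a replicate-averaged [expression_atlas()].
#' @param min_positive_tissues number of tissues with TPM > 0 required by
#'   the first clause (default 3).
#' @param high_tpm TPM threshold for the single-tissue clause (default 5).
#' @return list with elements `atlas` (the expressed subset) and
#'   `removed` (character vector of dropped gene IDs).
#' @export
filter_expressed <- function(atlas, min_positive_tissues = 3, high_tpm = 5) {
  stopifnot(inherits(atlas, "expression_atlas"))
  m <- atlas$tpm
  keep <- rowSums(m > 0) >= min_positive_tissues |
    apply(m, 1, max) > high_tpm
  list(atlas = expression_atlas(m[keep, , drop = FALSE],
                                atlas$replicate_map),
       removed = rownames(m)[!keep])
}

#' Inverse hyperbolic sine transform
#'
#' Elementwise `x -> log(x + sqrt(x^2 + 1))`, which compresses large TPM
#' values while preserving the relative magnitude of small ones.  Input
#' must be non-negative.
#'
#' @param atlas an [expression_atlas()] (or a bare numeric matrix/vector).
#' @return an object of the same type, transformed.
#' @export
asinh_transform <- function(atlas) {
  if (inherits(atlas, "expression_atlas")) {
    out <- atlas
    out$tpm <- asinh_transform(atlas$tpm)
    return(out)
  }
  if (any(atlas < 0)) stop("asinh_transform: negative expression values")
  asinh(atlas)
}

#' Load, average, filter and transform an atlas in one step
#'
#' Convenience wrapper running [average_replicates()], [filter_expressed()]
#' and [asinh_transform()] in order, returning the transformed per-tissue
#' matrix ready for correlation.
#'
#' @param atlas an [expression_atlas()] with replicate columns.
#' @inheritParams filter_expressed
#' @return list with `matrix` (genes x tissues, asinh scale) and `removed`.
#' @export
preprocess_atlas <- function(atlas, min_positive_tissues = 3, high_tpm = 5) {
  avg <- average_replicates(atlas)
  flt <- filter_expressed(avg, min_positive_tissues, high_tpm)
  list(matrix = asinh_transform(flt$atlas$tpm), removed = flt$removed)
}

# quiet R CMD check notes for data.table non-standard evaluation
utils::globalVariables(c("column", "tissue"))
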