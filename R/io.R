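#' Read and write the tab-separated formats used across the pipeline
#'
#' All stages exchange plain TSV: an expression matrix with a `gene_id`
#' column and one column per tissue-replicate, a two-column replicate map,
#' a duplicate-pair table, a subgenome/synteny map, thresholded edge lists,
#' module assignments, and pathway gene sets in GMT.
#'
#' @param path file path.
#' @return `read_expression_tsv` returns a numeric matrix with gene IDs as
#'   row names; the other readers return `data.table`s (or a named list of
#'   character vectors for GMT).
#' @name coexdiv-io
NULL

#' @rdname coexdiv-io
#' @export
read_expression_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (names(dt)[1] != "gene_id")
    stop("expression TSV must have 'gene_id' as its first column")
  ids <- dt[[1]]
  m <- as.matrix(dt[, -1, with = FALSE])
  if (anyNA(m)) stop("expression matrix contains missing values; NA cells are not permitted")
  if (anyDuplicated(ids)) stop("duplicate gene IDs in expression matrix")
  rownames(m) <- ids
  m
}

#' @rdname coexdiv-io
#' @param m numeric gene x column matrix with row names.
#' @export
write_expression_tsv <- function(m, path) {
  dt <- data.table::data.table(gene_id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname coexdiv-io
#' @export
read_replicate_map <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1:2))
  if (!all(c("column", "tissue") %in% names(dt)))
    stop("replicate map must have columns 'column' and 'tissue'")
  dt[, c("column", "tissue"), with = FALSE]
}

#' @rdname coexdiv-io
#' @param map data.table with columns `column`, `tissue`.
#' @export
write_replicate_map <- function(map, path) {
  data.table::fwrite(map, path, sep = "\t")
  invisible(path)
}

#' @rdname coexdiv-io
#' @export
read_pair_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("gene1", "gene2", "dup_type", "dS")
  if (!all(need %in% names(dt)))
    stop("pair table must have columns gene1, gene2, dup_type, dS")
  dt
}

#' @rdname coexdiv-io
#' @param pairs duplicate-pair data.table.
#' @export
write_pair_table <- function(pairs, path) {
  data.table::fwrite(pairs, path, sep = "\t")
  invisible(path)
}

#' @rdname coexdiv-io
#' @export
read_subgenome_map <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  need <- c("gene_id", "subgenome", "block_id", "chrom", "start", "end")
  if (!all(need %in% names(dt)))
    stop("subgenome map must have columns gene_id, subgenome, block_id, chrom, start, end")
  if (anyDuplicated(dt$gene_id)) stop("subgenome map has duplicated gene IDs")
  if (any(!is.na(dt$start) & !is.na(dt$end) & dt$start > dt$end))
    stop("subgenome map has start > end")
  dt
}

#' @rdname coexdiv-io
#' @param smap subgenome map data.table.
#' @export
write_subgenome_map <- function(smap, path) {
  data.table::fwrite(smap, path, sep = "\t")
  invisible(path)
}

#' @rdname coexdiv-io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("GMT line with fewer than 3 fields")
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' @rdname coexdiv-io
#' @param sets named list of character vectors (gene sets).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "coexdiv", sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname coexdiv-io
#' @export
read_edge_list <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(c("gene1", "gene2", "z") %in% names(dt)))
    stop("edge list must have columns gene1, gene2, z")
  dt
}

#' @rdname coexdiv-io
#' @param edges edge data.table with `gene1`, `gene2`, `z`.
#' @export
write_edge_list <- function(edges, path) {
  data.table::fwrite(edges, path, sep = "\t")
  invisible(path)
}

#' @rdname coexdiv-io
#' @export
read_module_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(c("gene_id", "module_id") %in% names(dt)))
    stop("module table must have columns gene_id, module_id")
  dt
}

#' @rdname coexdiv-io
#' @param modules module data.table with `gene_id`, `module_id`.
#' @export
write_module_table <- function(modules, path) {
  data.table::fwrite(modules, path, sep = "\t")
  invisible(path)
}

#' @rdname coexdiv-io
#' @export
read_protein_fasta <- function(path) {
  Biostrings::readAAStringSet(path)
}

#' @rdname coexdiv-io
#' @param seqs AAStringSet.
#' @export
write_protein_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
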