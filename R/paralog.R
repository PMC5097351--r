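# Paralog detection from protein sequences and duplication-type
# assignment from synteny.

.AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                  "F","P","S","T","W","Y","V","X")

# BLOSUM62 with the ambiguity code X scored 0 against everything
.blosum62x <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[.AA_ALPHABET, .AA_ALPHABET]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  m
}

.check_protein <- function(s, what) {
  if (!nzchar(s)) stop(what, ": empty sequence")
  bad <- setdiff(strsplit(s, "")[[1]], .AA_ALPHABET)
  if (length(bad))
    stop(what, ": illegal residue(s) ", paste(unique(bad), collapse = ""))
  s
}

#' Global protein alignment with BLOSUM62 and affine gaps
#'
#' Needleman-Wunsch global alignment under BLOSUM62 (X scored 0 against
#' everything) with affine gap penalties: a gap of length L costs
#' `gap_open + L * gap_extend`.  Coverage counts residue-residue aligned
#' columns only (columns with a gap are excluded from the numerator);
#' denominators are the full protein lengths.
#'
#' @param seq1,seq2 protein sequences (character or `AAString`) over the
#'   20 amino acids plus X.
#' @param gap_open,gap_extend affine gap penalties (defaults 11 and 1,
#'   the standard BLOSUM62 pairing).
#' @return list with `score`, `coverage` (length-2 numeric), and the two
#'   `aligned` strings.
#' @export
global_align <- function(seq1, seq2, gap_open = 11, gap_extend = 1) {
  s1 <- .check_protein(as.character(seq1), "seq1")
  s2 <- .check_protein(as.character(seq2), "seq2")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s1), Biostrings::AAString(s2),
    substitutionMatrix = .blosum62x(),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  cp <- strsplit(ap, "")[[1]]; cs <- strsplit(as_, "")[[1]]
  both <- sum(cp != "-" & cs != "-")
  list(score = Biostrings::score(pa),
       coverage = c(both / nchar(s1), both / nchar(s2)),
       aligned = c(ap, as_))
}

#' Detect paralogous duplicate pairs in a proteome
#'
#' All-against-all global alignment; a pair is retained as a paralogous
#' duplicate when the aligned fraction exceeds `min_coverage` for *both*
#' proteins (strict) and the alignment score reaches `min_score`.  Output
#' contains each unordered pair once and no self-pairs.
#'
#' @param proteome named character vector or `AAStringSet` of protein
#'   sequences (names = gene IDs); at least 2 sequences.
#' @param min_coverage aligned-length fraction both members must exceed
#'   (default 0.4).
#' @param min_score minimum alignment score (default 50).
#' @inheritParams global_align
#' @return data.table with `gene1`, `gene2`, `score`, `coverage1`,
#'   `coverage2`.
#' @export
detect_paralog_pairs <- function(proteome, min_coverage = 0.4,
                                 min_score = 50, gap_open = 11,
                                 gap_extend = 1) {
  seqs <- as.character(proteome)
  if (is.null(names(seqs))) names(seqs) <- names(proteome)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("proteome sequences must have unique names")
  if (length(seqs) < 2) stop("need at least 2 sequences")
  for (k in seq_along(seqs)) .check_protein(seqs[k], names(seqs)[k])
  mat <- .blosum62x()
  ids <- names(seqs)
  n <- length(seqs)
  lens <- nchar(seqs)
  out <- vector("list", n - 1L)
  aa <- Biostrings::AAStringSet(seqs)
  gaps <- function(s) nchar(gsub("[^-]", "", s))
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    # cheap score-only pass; full alignments (for the coverage rule) are
    # computed only for pairs that reach the score threshold
    sc <- Biostrings::pairwiseAlignment(
      aa[js], aa[[i]], substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend, type = "global",
      scoreOnly = TRUE)
    cand <- which(sc >= min_score)
    if (!length(cand)) next
    pa <- Biostrings::pairwiseAlignment(
      aa[js[cand]], aa[[i]], substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend, type = "global")
    ap <- as.character(Biostrings::alignedPattern(pa))
    as_ <- as.character(Biostrings::alignedSubject(pa))
    # residue-residue columns = alignment length minus gaps in either row
    both <- nchar(ap) - gaps(ap) - gaps(as_)
    covj <- both / lens[js[cand]]
    covi <- both / lens[i]
    keep <- covi > min_coverage & covj > min_coverage
    if (any(keep)) {
      cp <- .canonical_pairs(rep(ids[i], sum(keep)), ids[js[cand]][keep])
      out[[i]] <- data.table::data.table(
        gene1 = cp$gene1, gene2 = cp$gene2, score = sc[cand][keep],
        coverage1 = ifelse(cp$gene1 == ids[i], covi, covj[keep]),
        coverage2 = ifelse(cp$gene1 == ids[i], covj[keep], covi))
    }
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L)
    return(data.table::data.table(gene1 = character(0), gene2 = character(0),
                                  score = numeric(0), coverage1 = numeric(0),
                                  coverage2 = numeric(0)))
  data.table::setorder(res, gene1, gene2)
  res
}

#' Assign duplication types from a subgenome/synteny map
#'
#' Classifies each duplicate pair as `WGD` (the two members occupy the
#' maize1 and maize2 copies of the same homeologous block), `tandem`
#' (same block and subgenome, separated by at most `tandem_window`
#' intervening genes), or `inserted` (at least one member outside any
#' syntenic block, or the members not in a conserved syntenic
#' relationship).  Pairs with a member missing from the map are labeled
#' `inserted` and flagged `unplaced`.
#'
#' @param pairs data.table with `gene1`, `gene2` (other columns carried
#'   through).
#' @param map subgenome map data.table (`gene_id`, `subgenome`,
#'   `block_id`, `chrom`, `start`, `end`).
#' @param tandem_window maximum intervening genes for a tandem call
#'   (default 5).
#' @return the pair table with `dup_type` and `unplaced` columns.
#' @export
classify_duplication_type <- function(pairs, map, tandem_window = 5L) {
  pairs <- data.table::as.data.table(pairs)
  map <- data.table::as.data.table(map)
  # rank of each gene inside its (block, subgenome) run, by position
  map2 <- data.table::copy(map)
  placed <- !is.na(map2$block_id) & map2$subgenome %in% c("maize1", "maize2")
  map2[, pos_rank := NA_integer_]
  map2[placed, pos_rank := as.integer(rank(start, ties.method = "first")),
       by = c("block_id", "subgenome")]
  look <- function(g, col) map2[[col]][match(g, map2$gene_id)]
  g1 <- pairs$gene1; g2 <- pairs$gene2
  in_map <- g1 %in% map2$gene_id & g2 %in% map2$gene_id
  sg1 <- look(g1, "subgenome"); sg2 <- look(g2, "subgenome")
  bl1 <- look(g1, "block_id"); bl2 <- look(g2, "block_id")
  rk1 <- look(g1, "pos_rank"); rk2 <- look(g2, "pos_rank")
  ch1 <- look(g1, "chrom"); ch2 <- look(g2, "chrom")
  placed1 <- in_map & !is.na(bl1) & sg1 %in% c("maize1", "maize2")
  placed2 <- in_map & !is.na(bl2) & sg2 %in% c("maize1", "maize2")
  both_placed <- placed1 & placed2
  wgd <- both_placed & bl1 == bl2 & sg1 != sg2
  tandem <- both_placed & !wgd & bl1 == bl2 & sg1 == sg2 & ch1 == ch2 &
    abs(rk1 - rk2) - 1L <= tandem_window
  dup_type <- ifelse(wgd, "WGD", ifelse(tandem, "tandem", "inserted"))
  dup_type[is.na(dup_type)] <- "inserted"
  unplaced <- !(g1 %in% map2$gene_id) | !(g2 %in% map2$gene_id)
  if (any(unplaced))
    warning(sum(unplaced), " pair(s) with unplaced gene(s) labeled inserted")
  out <- data.table::copy(pairs)
  out[, dup_type := dup_type]
  out[, unplaced := unplaced]
  out
}

utils::globalVariables(c("pos_rank", "start", "dup_type", "unplaced", "BLOSUM62"))
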