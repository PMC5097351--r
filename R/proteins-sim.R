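# Synthetic proteome: families of similar protein sequences whose
# members should be recovered as paralogous duplicates, plus unrelated
# singletons that should not.

#' Generate synthetic protein families
#'
#' Each family is a random amino-acid sequence plus a copy carrying point
#' substitutions at rate `sub_rate`; singleton sequences are unrelated
#' random proteins.  Family pairs are the ground truth for paralog
#' detection.
#'
#' @param n_families number of two-member families.
#' @param n_singletons number of unrelated singleton proteins.
#' @param len_range integer range of sequence lengths.
#' @param sub_rate per-residue substitution probability within a family.
#' @param seed integer seed.
#' @return list with `proteome` (named character vector) and
#'   `true_pairs` (data.table `gene1`, `gene2`).
#' @export
generate_protein_families <- function(n_families = 20L, n_singletons = 10L,
                                      len_range = c(80L, 200L),
                                      sub_rate = 0.05, seed = 1L) {
  set.seed(seed)
  aa20 <- setdiff(.AA_ALPHABET, "X")
  rand_seq <- function(len) paste(sample(aa20, len, replace = TRUE),
                                  collapse = "")
  seqs <- character(0)
  g1 <- character(0); g2 <- character(0)
  for (f in seq_len(n_families)) {
    len <- sample(seq(len_range[1], len_range[2]), 1L)
    s <- rand_seq(len)
    v <- strsplit(s, "")[[1]]
    nmut <- stats::rbinom(1L, len, sub_rate)
    if (nmut > 0) {
      pos <- sample.int(len, nmut)
      for (p in pos) v[p] <- sample(setdiff(aa20, v[p]), 1L)
    }
    ida <- sprintf("fam%03da", f); idb <- sprintf("fam%03db", f)
    seqs[ida] <- s
    seqs[idb] <- paste(v, collapse = "")
    g1 <- c(g1, ida); g2 <- c(g2, idb)
  }
  for (k in seq_len(n_singletons)) {
    len <- sample(seq(len_range[1], len_range[2]), 1L)
    seqs[sprintf("sng%03d", k)] <- rand_seq(len)
  }
  list(proteome = seqs,
       true_pairs = data.table::data.table(gene1 = g1, gene2 = g2))
}
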