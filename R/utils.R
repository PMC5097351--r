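#' Derive a stage-specific random seed from a base seed
#'
#' Each pipeline stage draws from its own substream so that changing the
#' inputs of one stage never perturbs the random numbers of another.  The
#' substream seed is a deterministic hash of the base seed and the stage
#' name, kept inside the 32-bit integer range.
#'
#' @param seed integer base seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1000003
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483587)
}

# stop() with the offending field named, for spec validators
.fail_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

.check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    .fail_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

.check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    .fail_field(field, "must be a probability in [0, 1]")
  as.numeric(x)
}

# canonical unordered pair representation: gene1 < gene2 lexicographically
.canonical_pairs <- function(g1, g2) {
  swap <- g1 > g2
  tmp <- g1[swap]; g1[swap] <- g2[swap]; g2[swap] <- tmp
  list(gene1 = g1, gene2 = g2)
}

# Fisher z-transform with the |R| = 1 clamp used throughout the package.
# Perfectly correlated (often duplicated) profiles are kept at a large
# finite score instead of being discarded.
.fisher_z <- function(r, clamp = 1 - 1e-12) {
  r <- pmin(pmax(r, -clamp), clamp)
  atanh(r)
}
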