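# Synthetic expression atlas with planted co-expression modules.
#
# Latent-profile model: every module owns one latent tissue profile (a
# centered unit vector over tissues).  A member gene's biological profile
# is sqrt(w) * latent + sqrt(1-w) * own noise, where w is the target
# within-module correlation; at w = 1 all members realize the module
# program exactly.  Profiles are mapped to non-negative TPM by a
# per-profile positive affine map, replicates add optional measurement
# noise on the TPM scale.

# draw a centered, unit-norm random direction over n_tissues
.random_profile <- function(n_tissues) {
  v <- stats::rnorm(n_tissues)
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

# orthonormalize centered rows of a matrix (Gram-Schmidt); rows stay
# centered because centered vectors are closed under linear combination
.orthonormalize_rows <- function(m) {
  for (i in seq_len(nrow(m))) {
    v <- m[i, ] - mean(m[i, ])
    if (i > 1) for (j in seq_len(i - 1)) v <- v - sum(v * m[j, ]) * m[j, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) stop("degenerate profile during orthonormalization")
    m[i, ] <- v / nv
  }
  m
}

# Assemble an expression_atlas from a profile plan.
# profiles: n_profiles x n_tissues matrix of centered unit directions.
# gene_profile: per-gene index into profiles.
# Assumes the caller has seeded the RNG.
.build_atlas_from_plan <- function(profiles, gene_profile, gene_ids,
                                   within_module_corr, noise_sd,
                                   n_tissues, replicates_per_tissue,
                                   exact_genes = NULL) {
  n <- length(gene_profile)
  w <- within_module_corr
  base <- profiles[gene_profile, , drop = FALSE]
  if (w < 1) {
    eps <- matrix(stats::rnorm(n * n_tissues), n, n_tissues)
    eps <- eps - rowMeans(eps)
    eps <- eps / sqrt(rowSums(eps^2))
    mixed <- sqrt(w) * base + sqrt(1 - w) * eps
    if (length(exact_genes)) mixed[exact_genes, ] <- base[exact_genes, ]
    base <- mixed
  }
  # per-profile positive affine map to TPM; amplitudes are kept compact so
  # the downstream asinh transform is close to affine over the dynamic
  # range and planted correlations carry through it faithfully
  n_prof <- nrow(profiles)
  a <- stats::runif(n_prof, 0.8, 2)
  cbase <- stats::runif(n_prof, 0.05, 0.3)
  rmin <- base[, 1]
  for (j in 2:ncol(base)) rmin <- pmin(rmin, base[, j])
  tpm <- a[gene_profile] * (base - rmin) + cbase[gene_profile]
  # replicate columns with optional measurement noise
  reps <- replicates_per_tissue
  tissues <- sprintf("T%02d", seq_len(n_tissues))
  out <- matrix(0, n, n_tissues * reps)
  colnames(out) <- as.vector(vapply(tissues, function(t)
    paste0(t, ":r", seq_len(reps)), character(reps)))
  for (t in seq_len(n_tissues)) for (r in seq_len(reps)) {
    col <- tpm[, t]
    if (noise_sd > 0) col <- pmax(0, col + stats::rnorm(n, 0, noise_sd))
    out[, (t - 1L) * reps + r] <- col
  }
  rownames(out) <- gene_ids
  rep_map <- data.table::data.table(
    column = colnames(out),
    tissue = rep(tissues, each = reps))
  expression_atlas(out, rep_map)
}

#' Generate a synthetic expression atlas with planted modules
#'
#' Genes are assigned to `n_modules` planted co-expression modules (sizes
#' from `module_sizes`); remaining genes are unassigned singletons with
#' independent profiles.  Same-module genes share one latent tissue
#' profile with target correlation `within_module_corr`; at
#' `within_module_corr = 1` and `noise_sd = 0` module members are exact
#' copies of the module program, so their pairwise Pearson correlation is
#' 1 even after the asinh transform.  Output is deterministic given the
#' spec seed.
#'
#' @param spec an [atlas_spec()].
#' @return list with `atlas` (an [expression_atlas()]), `module_labels`
#'   (named integer vector, `NA` for unassigned genes) and `spec`.
#' @export
generate_expression_atlas <- function(spec) {
  stopifnot(inherits(spec, "atlas_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))
  labels <- rep(NA_integer_, n)
  idx <- 1L
  for (m in seq_len(spec$n_modules)) {
    sz <- spec$module_sizes[m]
    labels[idx:(idx + sz - 1L)] <- m
    idx <- idx + sz
  }
  n_singletons <- n - idx + 1L
  n_prof <- spec$n_modules + n_singletons
  profiles <- matrix(0, n_prof, spec$n_tissues)
  for (p in seq_len(n_prof)) profiles[p, ] <- .random_profile(spec$n_tissues)
  gene_profile <- ifelse(is.na(labels),
                         spec$n_modules + cumsum(is.na(labels))[seq_len(n)],
                         labels)
  atlas <- .build_atlas_from_plan(profiles, gene_profile, gene_ids,
                                  spec$within_module_corr, spec$noise_sd,
                                  spec$n_tissues, spec$replicates_per_tissue)
  names(labels) <- gene_ids
  list(atlas = atlas, module_labels = labels, spec = spec)
}
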