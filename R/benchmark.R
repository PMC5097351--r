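# Planted-divergence benchmark: a synthetic atlas whose duplicate pairs
# realize all six divergence types (plus "unclassified") with known labels.
#
# Partial neighbor sharing cannot be realized by a plain module partition:
# at high within-module correlation, "is co-expressed with" is nearly
# transitive, so neighbor sets of two module genes are either identical or
# disjoint.  Types II, III and unclassified are therefore planted through
# mixed-profile "tester" genes: a gene whose (exact) profile is the equal
# mix of two latent directions, orthonormalized within the cluster,
# correlates with both groups at sqrt(w)/sqrt(2) while the groups stay
# mutually uncorrelated.  The shared/private group sizes then set the
# realized overlap proportions.
#
# Because the edge threshold is a quantile of the standardized Fisher-z
# distribution (mean + cutoff * sd over all gene pairs), whether a designed
# correlation becomes an edge depends on the global composition of the
# atlas.  The generator therefore calibrates itself: it computes the
# predicted mean and sd of the pooled z distribution from its design counts
# and solves for the number of background genes -- either extra unassigned
# singleton genes (which dilute the same-profile spike and lower the
# threshold) or one large background module (which widens the distribution
# and raises it) -- so that the threshold lands at a fixed fraction
# (t_frac) of the weakest designed edge score.  This is closed-form
# arithmetic on the design, done before any data are drawn.

.bench_sizes <- list(bg_module = 40L,
                     ii_group = 60L, ii_pairs_per_cluster = 10L,
                     iii_shared = 11L, iii_private = 95L,
                     uc_shared = 21L, uc_private = 49L,
                     uc_pairs_per_cluster = 10L)

.choose2 <- function(k) k * (k - 1) / 2

# Solve for booster-module size and filler count so the predicted
# standardized threshold sits at `target`.  `cnts`/`fs` give the designed
# pair classes (counts and Fisher scores); `f_group` is the score of
# same-latent pairs, which the booster module also contributes.
.calibrate_background <- function(cnts, fs, f_group, n0, n_tissues,
                                  z_cutoff, target, F_min) {
  s0 <- 1 / sqrt(n_tissues - 3)
  predict_fstar <- function(s, F) {
    n <- n0 + s + F
    N <- .choose2(n)
    cn <- c(cnts, .choose2(s))
    fv <- c(fs, f_group)
    mu <- sum(cn * fv) / N
    m2 <- (sum(cn * fv^2) + (N - sum(cn)) * s0^2) / N
    mu + z_cutoff * sqrt(max(m2 - mu^2, 0))
  }
  if (predict_fstar(0L, F_min) >= target) {
    lo <- F_min; hi <- 500000L           # more fillers lower the threshold
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (predict_fstar(0L, mid) >= target) lo <- mid else hi <- mid
    }
    res <- list(s_boost = 0L, n_filler = hi)
  } else {
    lo <- 0L; hi <- 20000L               # a bigger booster raises it
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (predict_fstar(mid, F_min) <= target) lo <- mid else hi <- mid
    }
    res <- list(s_boost = hi, n_filler = F_min)
  }
  res$f_star_pred <- predict_fstar(res$s_boost, res$n_filler)
  res$target <- target
  res
}

# P(X > a, Y > a) for standard bivariate normal with correlation rho:
# probability that a shared-group gene survives thinning in both
# neighbor sets, whose two edge noises share the common component.
.orthant_both <- function(a, rho = 0.5) {
  if (!is.finite(a)) return(if (a > 0) 0 else 1)
  f <- function(x) stats::dnorm(x) *
    stats::pnorm((rho * x - a) / sqrt(1 - rho^2))
  stats::integrate(f, a, Inf, rel.tol = 1e-8)$value
}

#' Generate a benchmark atlas with planted divergence types
#'
#' Builds a synthetic tissue atlas (default 64 tissues, 2 replicates)
#' together with `n_pairs` duplicate pairs whose co-expression divergence
#' labels are known by construction: type I pairs share a module, type IV
#' pairs span two modules, type V pairs one module gene plus a singleton,
#' type VI two singletons, and types II, III and `unclassified` are
#' realized through mixed-profile genes attached to shared and private
#' gene groups whose sizes set the planted neighbor-overlap proportions
#' (0.5/0.5, 1/0.095 and 0.3/0.3 respectively).  The background gene
#' content is calibrated so that the standardized Z threshold separates
#' designed co-expression from noise (see the package vignette).
#'
#' @param n_pairs number of duplicate pairs to plant (default 500).
#' @param divergence_mix named proportions over planted labels
#'   `I, II, III, IV, V, VI, unclassified`.
#' @param within_module_corr,noise_sd,n_tissues,replicates_per_tissue
#'   atlas noise model, as in [atlas_spec()].
#' @param type_proportions,ds_params duplication-type model, as in
#'   [pair_spec()].
#' @param z_cutoff standardized edge threshold the benchmark is calibrated
#'   for (default 2.5).
#' @param t_frac calibration target: the predicted threshold is placed at
#'   this fraction of the weakest designed edge score (default 0.85).
#' @param seed integer seed; all outputs are deterministic given it.
#' @return list with `atlas`, `pairs` (data.table with planted labels),
#'   `module_labels`, and `calibration` diagnostics.
#' @export
generate_divergence_benchmark <- function(n_pairs = 500L,
    divergence_mix = c(I = 0.12, II = 0.18, III = 0.03, IV = 0.50,
                       V = 0.06, VI = 0.05, unclassified = 0.06),
    within_module_corr = 1, noise_sd = 0,
    n_tissues = 64L, replicates_per_tissue = 2L,
    type_proportions = c(WGD = 0.15, tandem = 0.10, inserted = 0.75),
    ds_params = list(WGD = c(mean = 0.15, sd = 0.05),
                     tandem = c(mean = 0.30, sd = 0.25),
                     inserted = c(mean = 0.45, sd = 0.15)),
    z_cutoff = 2.5, t_frac = 0.85, seed = 1L) {
  stopifnot(abs(sum(divergence_mix) - 1) < 1e-8, within_module_corr > 0,
            within_module_corr <= 1)
  sz <- .bench_sizes
  cnt <- .apportion(n_pairs, divergence_mix[c("I", "II", "III", "IV", "V",
                                              "VI", "unclassified")])
  w <- within_module_corr

  # ---- design counts for calibration -------------------------------------
  slots <- 2L * cnt[["I"]] + 2L * cnt[["IV"]] + cnt[["V"]]
  n_bg <- max(2L, ceiling(slots / sz$bg_module))
  n_tri <- ceiling(cnt[["II"]] / sz$ii_pairs_per_cluster)
  tri_pairs <- diff(round(seq(0, cnt[["II"]], length.out = n_tri + 1L)))
  n_uc <- if (cnt[["unclassified"]] > 0)
    ceiling(cnt[["unclassified"]] / sz$uc_pairs_per_cluster) else 0L
  uc_pairs <- if (n_uc > 0)
    diff(round(seq(0, cnt[["unclassified"]], length.out = n_uc + 1L)))
  else integer(0)

  F_min <- cnt[["V"]] + 2L * cnt[["VI"]] + 50L
  # Designed pair classes and their population Fisher scores.  The pair
  # members planted for types II/III/unclassified ("tester" genes) carry
  # exact mixed profiles, so a tester-group edge has correlation
  # sqrt(w)/sqrt(2) (only the group gene is noisy), tester siblings are
  # perfect copies, and tester-tester pairs across a cluster sit at 0.5.
  f_group <- atanh(min(w, 1 - 1e-12))      # same-latent group pairs
  f_clamp <- atanh(1 - 1e-12)              # identical tester siblings
  f_mix <- atanh(sqrt(w) / sqrt(2))        # tester-group designed edges
  f_cross <- atanh(0.5)                    # tester-tester across a cluster
  # At w < 1 a designed edge is missed with probability m; a shared-group
  # gene survives in both neighbor sets with the orthant probability
  # p_both (its two edge noises share the group-direction component,
  # correlation 0.5).  Overlap ratios are biased by p_both/(1-m), so the
  # private groups are widened to land the post-thinning overlap back on
  # the classifier centers.  m, p_both and the background solve depend on
  # each other; a fixed-point loop settles them.
  sigma_edge <- if (w < 1)
    sqrt(1 - w) / sqrt(n_tissues - 1) / (1 - w / 2) else 0
  m_est <- 0; p_both <- 1
  for (iter in 1:4) {
    comp_ii <- p_both / (0.5 * (1 - m_est))
    comp_uc <- p_both / (0.3 * (1 - m_est))
    ii_priv <- max(1L, as.integer(round(sz$ii_group * (comp_ii - 1))))
    uc_priv <- max(1L, as.integer(round(sz$uc_shared * (comp_uc - 1))))
    cnts <- c(group = n_bg * .choose2(sz$bg_module) +
                n_tri * (.choose2(sz$ii_group) + 2 * .choose2(ii_priv)) +
                cnt[["III"]] * (.choose2(sz$iii_shared) +
                                  .choose2(sz$iii_private)) +
                n_uc * (.choose2(sz$uc_shared) + 2 * .choose2(uc_priv)),
              clamp = sum(.choose2(tri_pairs)) * 2 +
                sum(.choose2(uc_pairs)) * 2,
              mix = sum(tri_pairs) * 2 * (sz$ii_group + ii_priv) +
                cnt[["III"]] * (sz$iii_shared + sz$iii_private) +
                sum(uc_pairs) * 2 * (sz$uc_shared + uc_priv),
              cross = sum(tri_pairs^2) + sum(uc_pairs^2))
    fs <- c(f_group, f_clamp, f_mix, f_cross)
    n0 <- n_bg * sz$bg_module +
      n_tri * (sz$ii_group + 2L * ii_priv) + 2L * cnt[["II"]] +
      cnt[["III"]] * (sz$iii_shared + sz$iii_private + 1L) +
      n_uc * (sz$uc_shared + 2L * uc_priv) + 2L * cnt[["unclassified"]]
    cal <- .calibrate_background(cnts, fs, f_group, n0, n_tissues,
                                 z_cutoff, target = t_frac * f_mix,
                                 F_min = F_min)
    m_new <- if (w < 1)
      stats::pnorm((cal$f_star_pred - f_mix) / sigma_edge) else 0
    p_both <- .orthant_both(stats::qnorm(m_new), rho = 0.5)
    if (abs(m_new - m_est) < 0.002) { m_est <- m_new; break }
    m_est <- m_new
  }
  cal$edge_miss_rate <- m_est
  cal$p_both <- p_both
  cal$f_edge <- f_mix
  cal$ii_private <- ii_priv
  cal$uc_private <- uc_priv

  # ---- build profiles and the gene plan ----------------------------------
  set.seed(seed)
  n_genes <- n0 + cal$s_boost + cal$n_filler
  n_prof_total <- n_bg + (cal$s_boost > 0L) + n_tri * 5L + cnt[["III"]] * 3L +
    n_uc * 5L + cal$n_filler
  profiles <- matrix(0, n_prof_total, n_tissues)
  n_prof <- 0L
  gene_profile <- integer(n_genes); module_label <- rep(NA_integer_, n_genes)
  role <- character(n_genes)
  n_used <- 0L
  add_profile <- function(k = 1L) {
    m <- matrix(0, k, n_tissues)
    for (i in seq_len(k)) m[i, ] <- .random_profile(n_tissues)
    if (k > 1L) m <- .orthonormalize_rows(m)
    profiles[n_prof + seq_len(k), ] <<- m
    n_prof <<- n_prof + k
    n_prof - k + seq_len(k)
  }
  add_mix <- function(i, j) {
    profiles[n_prof + 1L, ] <<- (profiles[i, ] + profiles[j, ]) / sqrt(2)
    n_prof <<- n_prof + 1L
    n_prof
  }
  module_counter <- 0L
  add_genes <- function(prof, k, what, module = NA_integer_) {
    idx <- n_used + seq_len(k)
    gene_profile[idx] <<- prof
    module_label[idx] <<- module
    role[idx] <<- what
    n_used <<- n_used + k
    idx
  }
  new_module <- function() { module_counter <<- module_counter + 1L; module_counter }

  bg_members <- vector("list", n_bg)
  for (b in seq_len(n_bg)) {
    p <- add_profile()
    bg_members[[b]] <- add_genes(p, sz$bg_module, "background", new_module())
  }
  if (cal$s_boost > 0L) {
    p <- add_profile()
    add_genes(p, cal$s_boost, "booster", new_module())
  }

  pair_g1 <- integer(0); pair_g2 <- integer(0); pair_lab <- character(0)
  add_pair <- function(i1, i2, lab) {
    pair_g1 <<- c(pair_g1, i1); pair_g2 <<- c(pair_g2, i2)
    pair_lab <<- c(pair_lab, lab)
  }

  # II clusters: shared + two private groups, mixed genes overlap 0.5/0.5
  for (t in seq_len(n_tri)) {
    ps <- add_profile(3L)
    add_genes(ps[1], sz$ii_group, "ii_group", new_module())
    add_genes(ps[2], ii_priv, "ii_group", new_module())
    add_genes(ps[3], ii_priv, "ii_group", new_module())
    m1 <- add_mix(ps[1], ps[2]); m2 <- add_mix(ps[1], ps[3])
    k <- tri_pairs[t]
    i1 <- add_genes(m1, k, "ii_gene"); i2 <- add_genes(m2, k, "ii_gene")
    for (q in seq_len(k)) add_pair(i1[q], i2[q], "II")
  }
  # III clusters: g1 inside the shared group, g2 mixed into a large
  # private group -> overlap (1, s/(s+p))
  for (q in seq_len(cnt[["III"]])) {
    ps <- add_profile(2L)
    s_genes <- add_genes(ps[1], sz$iii_shared, "iii_shared", new_module())
    add_genes(ps[2], sz$iii_private, "iii_private", new_module())
    m2 <- add_mix(ps[1], ps[2])
    g2 <- add_genes(m2, 1L, "iii_gene")
    add_pair(s_genes[1], g2, "III")
  }
  # unclassified clusters: like II but private groups much larger than the
  # shared one -> overlap 0.3/0.3, outside every classifier disc
  for (t in seq_len(n_uc)) {
    ps <- add_profile(3L)
    add_genes(ps[1], sz$uc_shared, "uc_group", new_module())
    add_genes(ps[2], uc_priv, "uc_group", new_module())
    add_genes(ps[3], uc_priv, "uc_group", new_module())
    m1 <- add_mix(ps[1], ps[2]); m2 <- add_mix(ps[1], ps[3])
    k <- uc_pairs[t]
    i1 <- add_genes(m1, k, "uc_gene"); i2 <- add_genes(m2, k, "uc_gene")
    for (q in seq_len(k)) add_pair(i1[q], i2[q], "unclassified")
  }
  # fillers: independent singleton genes; the first ones host V/VI members
  filler_idx <- integer(cal$n_filler)
  for (i in seq_len(cal$n_filler)) {
    p <- add_profile()
    filler_idx[i] <- add_genes(p, 1L, "filler")
  }
  # I: two seats in one background module; IV: seats in two different
  # modules; V: one module seat plus one filler
  seat <- rep(1L, n_bg)
  take_seat <- function(b, k) {
    out <- bg_members[[b]][seat[b] - 1L + seq_len(k)]
    seat[b] <<- seat[b] + k
    out
  }
  bsel <- rep(seq_len(n_bg), length.out = cnt[["I"]])
  for (q in seq_len(cnt[["I"]])) {
    s <- take_seat(bsel[q], 2L); add_pair(s[1], s[2], "I")
  }
  ba <- rep(seq_len(n_bg), length.out = cnt[["IV"]])
  bb <- rep(c(seq_len(n_bg)[-1], 1L), length.out = cnt[["IV"]])
  for (q in seq_len(cnt[["IV"]]))
    add_pair(take_seat(ba[q], 1L), take_seat(bb[q], 1L), "IV")
  nf <- 0L
  bsel <- rep(seq_len(n_bg), length.out = cnt[["V"]])
  for (q in seq_len(cnt[["V"]])) {
    nf <- nf + 1L
    add_pair(take_seat(bsel[q], 1L), filler_idx[nf], "V")
  }
  for (q in seq_len(cnt[["VI"]])) {
    add_pair(filler_idx[nf + 1L], filler_idx[nf + 2L], "VI")
    nf <- nf + 2L
  }

  stopifnot(n_used == n_genes, n_prof == n_prof_total)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  # tester genes (mixed profiles) are exact: their planted overlap is a
  # designed property, noise lives in the group genes around them
  exact <- which(role %in% c("ii_gene", "iii_gene", "uc_gene"))
  atlas <- .build_atlas_from_plan(profiles, gene_profile, gene_ids,
                                  w, noise_sd, n_tissues,
                                  replicates_per_tissue,
                                  exact_genes = exact)
  dup <- .draw_dup_types(length(pair_g1), type_proportions, ds_params)
  cp <- .canonical_pairs(gene_ids[pair_g1], gene_ids[pair_g2])
  pairs <- data.table::data.table(gene1 = cp$gene1, gene2 = cp$gene2,
                                  dup_type = dup$dup_type, dS = dup$dS,
                                  planted_divergence = pair_lab)
  labels <- stats::setNames(module_label, gene_ids)
  list(atlas = atlas, pairs = pairs, module_labels = labels,
       calibration = c(cal, list(n_genes = n_genes,
                                 pair_classes = as.list(cnts),
                                 z_cutoff = z_cutoff)),
       roles = stats::setNames(role, gene_ids))
}

#' Recover planted divergence labels from a benchmark
#'
#' Runs the real analysis path on a [generate_divergence_benchmark()]
#' object -- replicate averaging, expression filter, asinh transform,
#' standardized Fisher-z network restricted to the pair genes, neighbor
#' overlap, geometric classification -- and compares recovered labels to
#' the planted ones.
#'
#' @param bench output of [generate_divergence_benchmark()].
#' @param block_size row block size for the network pass.
#' @param radius,min_neighbors classifier settings (defaults 0.1 and 10).
#' @return list with `records` (classified pair table including
#'   `planted_divergence`), `accuracy`, and `confusion` (table of
#'   planted x recovered labels).
#' @export
evaluate_divergence_recovery <- function(bench, block_size = 1024L,
                                         radius = 0.1,
                                         min_neighbors = 10L) {
  x <- preprocess_atlas(bench$atlas)$matrix
  genes <- unique(c(bench$pairs$gene1, bench$pairs$gene2))
  net <- build_network(x, cutoff = bench$calibration$z_cutoff,
                       block_size = block_size, restrict_to = genes)
  rec <- classify_divergence(net, bench$pairs, radius = radius,
                             min_neighbors = min_neighbors)
  acc <- mean(rec$type_label == rec$planted_divergence)
  list(records = rec, accuracy = acc,
       confusion = table(planted = rec$planted_divergence,
                         recovered = rec$type_label))
}
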