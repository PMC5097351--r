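#' Specification objects for the synthetic-data generators
#'
#' `atlas_spec()` describes a synthetic tissue expression atlas with planted
#' co-expression modules; `pair_spec()` describes a set of duplicate pairs
#' with controlled duplication-type proportions, dS distributions and
#' planted divergence labels; `subgenome_spec()` describes a post-WGD
#' genome with two subgenomes, fractionation and pathway gene sets.
#' Each constructor validates its invariants and fails naming the field.
#'
#' @param n_genes total number of genes.
#' @param n_tissues number of tissues/stages (the atlas emulated here has
#'   64).
#' @param replicates_per_tissue biological replicates per tissue, 2 or 3.
#' @param n_modules number of planted co-expression modules.
#' @param module_sizes integer vector of module sizes (defaults to equal
#'   sizes of 20); `sum(module_sizes) <= n_genes`, remaining genes are
#'   unassigned singletons.
#' @param within_module_corr target Pearson correlation between genes of
#'   the same module, in `[0, 1]`; 1 means module members share an
#'   identical expression program.
#' @param noise_sd standard deviation of additive per-replicate
#'   measurement noise, on the TPM scale.
#' @param seed integer random seed.
#' @return a validated spec list of the corresponding class.
#' @export
atlas_spec <- function(n_genes, n_tissues = 64, replicates_per_tissue = 3,
                       n_modules = 10, module_sizes = NULL,
                       within_module_corr = 1, noise_sd = 0, seed = 1) {
  n_genes <- .check_count(n_genes, "n_genes", 1L)
  n_tissues <- .check_count(n_tissues, "n_tissues", 3L)
  replicates_per_tissue <- .check_count(replicates_per_tissue,
                                        "replicates_per_tissue", 2L)
  if (!replicates_per_tissue %in% c(2L, 3L))
    .fail_field("replicates_per_tissue", "must be 2 or 3")
  within_module_corr <- .check_prob(within_module_corr, "within_module_corr")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || is.na(noise_sd) ||
      noise_sd < 0)
    .fail_field("noise_sd", "must be a non-negative real")
  n_modules <- .check_count(n_modules, "n_modules", 0L)
  if (is.null(module_sizes))
    module_sizes <- rep(min(20L, max(1L, n_genes %/% max(n_modules, 1L))),
                        n_modules)
  if (length(module_sizes) != n_modules)
    .fail_field("module_sizes", "length must equal n_modules")
  module_sizes <- vapply(seq_along(module_sizes), function(i)
    .check_count(module_sizes[i], "module_sizes", 1L), integer(1))
  if (sum(module_sizes) > n_genes)
    .fail_field("module_sizes", "sum(module_sizes) exceeds n_genes")
  seed <- .check_count(seed, "seed", 0L)
  structure(list(n_genes = n_genes, n_tissues = n_tissues,
                 replicates_per_tissue = replicates_per_tissue,
                 n_modules = n_modules, module_sizes = module_sizes,
                 within_module_corr = within_module_corr,
                 noise_sd = noise_sd, seed = seed),
            class = "atlas_spec")
}

#' @rdname atlas_spec
#' @param n_pairs number of duplicate pairs to plant.
#' @param type_proportions named probabilities over duplication types
#'   `WGD`, `tandem`, `inserted`; must sum to 1.
#' @param ds_params named list with per-type `mean` and `sd` of the
#'   synonymous substitution rate dS (substitutions per synonymous site);
#'   values are drawn truncated at 0 by resampling.
#' @param divergence_mix named probabilities over planted divergence types
#'   (`I`, `IV`, `V`, `VI` for [generate_duplicate_pairs()]; the full
#'   I--VI plus `unclassified` for [generate_divergence_benchmark()]).
#' @export
pair_spec <- function(n_pairs,
                      type_proportions = c(WGD = 0.15, tandem = 0.10,
                                           inserted = 0.75),
                      ds_params = list(
                        WGD = c(mean = 0.15, sd = 0.05),
                        tandem = c(mean = 0.30, sd = 0.25),
                        inserted = c(mean = 0.45, sd = 0.15)),
                      divergence_mix = c(I = 0.25, IV = 0.45,
                                         V = 0.15, VI = 0.15),
                      seed = 1) {
  n_pairs <- .check_count(n_pairs, "n_pairs", 1L)
  if (!setequal(names(type_proportions), c("WGD", "tandem", "inserted")))
    .fail_field("type_proportions", "must be named WGD, tandem, inserted")
  if (any(type_proportions < 0) || abs(sum(type_proportions) - 1) > 1e-8)
    .fail_field("type_proportions", "must be non-negative and sum to 1")
  for (ty in names(ds_params)) {
    p <- ds_params[[ty]]
    if (!all(c("mean", "sd") %in% names(p)) || p[["mean"]] < 0 || p[["sd"]] < 0)
      .fail_field("ds_params", paste0(ty, " needs non-negative mean and sd"))
  }
  if (any(divergence_mix < 0) || abs(sum(divergence_mix) - 1) > 1e-8)
    .fail_field("divergence_mix", "must be non-negative and sum to 1")
  seed <- .check_count(seed, "seed", 0L)
  structure(list(n_pairs = n_pairs,
                 type_proportions = type_proportions[c("WGD", "tandem",
                                                       "inserted")],
                 ds_params = ds_params, divergence_mix = divergence_mix,
                 seed = seed),
            class = "pair_spec")
}

#' @rdname atlas_spec
#' @param n_maize1,n_maize2 exact numbers of genes labeled maize1 and
#'   maize2 (`n_maize2` may be `NULL`, in which case it is determined by
#'   binomial fractionation of the maize1 slots).
#' @param fractionation_rate probability that the maize2 member of an
#'   ancestral homeolog pair has been lost.
#' @param n_pathways number of pathway gene sets to emit.
#' @param pathway_size_range integer interval of pathway sizes.
#' @param n_tandem,n_inserted numbers of planted tandem and inserted
#'   duplicate genes.
#' @export
subgenome_spec <- function(n_maize1, n_maize2 = NULL,
                           fractionation_rate = 0.35,
                           n_pathways = 30, pathway_size_range = c(12L, 30L),
                           n_tandem = 0, n_inserted = 0, seed = 1) {
  n_maize1 <- .check_count(n_maize1, "n_maize1", 2L)
  if (!is.null(n_maize2)) {
    n_maize2 <- .check_count(n_maize2, "n_maize2", 1L)
    if (n_maize2 > n_maize1)
      .fail_field("n_maize2", "cannot exceed n_maize1")
  }
  fractionation_rate <- .check_prob(fractionation_rate, "fractionation_rate")
  n_pathways <- .check_count(n_pathways, "n_pathways", 0L)
  if (length(pathway_size_range) != 2L ||
      pathway_size_range[1] > pathway_size_range[2] ||
      pathway_size_range[1] < 4L)
    .fail_field("pathway_size_range",
                "must be an increasing interval with lower end >= 4")
  n_tandem <- .check_count(n_tandem, "n_tandem", 0L)
  n_inserted <- .check_count(n_inserted, "n_inserted", 0L)
  seed <- .check_count(seed, "seed", 0L)
  structure(list(n_maize1 = n_maize1, n_maize2 = n_maize2,
                 fractionation_rate = fractionation_rate,
                 n_pathways = n_pathways,
                 pathway_size_range = as.integer(pathway_size_range),
                 n_tandem = n_tandem, n_inserted = n_inserted, seed = seed),
            class = "subgenome_spec")
}
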