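# End-to-end orchestration: simulate -> preprocess -> network ->
# paralogs -> divergence -> subgenome, with one config, per-stage seed
# substreams and a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its standard default:
#' Z cutoff 2.5, classifier radius 0.1, minimum 10 neighbors, coverage
#' 0.4, at least 7 pathway edges and 2 WGD pairs, at least 20 labeled
#' genes per tested module, alpha 0.05, 1000 permutations.  One base
#' seed feeds deterministic per-stage substreams via [stage_seed()].
#'
#' @param n_pairs planted duplicate pairs in the simulated benchmark.
#' @param within_module_corr,noise_sd atlas noise model.
#' @param z_cutoff,radius,min_neighbors,min_coverage,min_score,
#'   tandem_window,min_edges,min_wgd_pairs,min_labeled,alpha,n_perm,
#'   inflation stage thresholds (defaults as above).
#' @param frac_maize1,frac_maize2 fractions of atlas genes anchored to
#'   each subgenome (the rest stay unanchored), mirroring the maize1 >
#'   maize2 retention asymmetry.
#' @param seed base seed.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_pairs = 60L, within_module_corr = 0.9,
                            noise_sd = 0.02, z_cutoff = 2.5, radius = 0.1,
                            min_neighbors = 10L, min_coverage = 0.4,
                            min_score = 50, tandem_window = 5L,
                            min_edges = 7L, min_wgd_pairs = 2L,
                            min_labeled = 20L, alpha = 0.05,
                            n_perm = 1000L, inflation = 2,
                            frac_maize1 = 0.5, frac_maize2 = 0.32,
                            seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a key=value config file
#'
#' Plain text, one `key = value` per line, `#` comments allowed; keys
#' are [pipeline_config()] arguments.
#'
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- list()
  for (p in kv) args[[p[1]]] <- as.numeric(p[2])
  do.call(pipeline_config, args)
}

.stage_files <- list(
  simulate  = c("expression.tsv", "replicate_map.tsv", "pairs.tsv",
                "subgenome_map.tsv", "pathways.gmt", "proteome.fasta",
                "lost_genes.tsv"),
  preprocess = "expression_transformed.tsv",
  network    = c("edges.tsv", "modules.tsv"),
  paralogs   = c("paralog_candidates.tsv", "pairs_typed.tsv"),
  divergence = c("divergence.tsv", "enrichment.tsv", "ds_summary.tsv"),
  subgenome  = c("fractionation.tsv", "pathway_tests.tsv",
                 "module_enrichment.tsv", "hubs.tsv"))

.require_inputs <- function(outdir, stage, files) {
  miss <- files[!file.exists(file.path(outdir, files))]
  if (length(miss))
    stop(sprintf("stage '%s' is missing upstream output(s): %s",
                 stage, paste(miss, collapse = ", ")))
}

#' Run the full pipeline
#'
#' Executes the requested stages in dependency order inside `outdir` and
#' writes a `manifest.json` recording the config, per-stage output row
#' counts, file checksums and an overall manifest hash; a rerun with the
#' same config and seed is bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param stages character vector of stages to run, in the fixed order
#'   `simulate`, `preprocess`, `network`, `paralogs`, `divergence`,
#'   `subgenome`.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         stages = names(.stage_files)) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, names(.stage_files), several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pt <- function(f) file.path(outdir, f)
  counts <- list()
  log_stage <- function(stage, msg)
    message(sprintf("[coexdiv:%s] %s", stage, msg))

  if ("simulate" %in% stages) {
    bench <- generate_divergence_benchmark(
      n_pairs = config$n_pairs,
      within_module_corr = config$within_module_corr,
      noise_sd = config$noise_sd, z_cutoff = config$z_cutoff,
      seed = stage_seed(config$seed, "simulate"))
    gene_ids <- rownames(bench$atlas$tpm)
    n <- length(gene_ids)
    n1 <- floor(config$frac_maize1 * n)
    n2 <- floor(config$frac_maize2 * n)
    sub <- generate_subgenome_structure(
      subgenome_spec(n_maize1 = n1, n_maize2 = n2,
                     n_tandem = max(2L, n %/% 200L),
                     n_inserted = max(2L, n %/% 200L),
                     n_pathways = 32L, pathway_size_range = c(12L, 30L),
                     seed = stage_seed(config$seed, "subgenome_structure")),
      gene_ids = gene_ids)
    # pair table = planted benchmark pairs + homeolog pairs from the
    # synteny structure (dS drawn from the WGD age distribution)
    set.seed(stage_seed(config$seed, "homeolog_ds"))
    extra <- data.table::copy(sub$pairs)
    ds_mean <- c(WGD = 0.15, tandem = 0.30, inserted = 0.45)
    ds_sd <- c(WGD = 0.05, tandem = 0.25, inserted = 0.15)
    extra[, dS := .rtruncnorm0(.N, ds_mean[dup_type], ds_sd[dup_type])]
    extra[, planted_divergence := NA_character_]
    pairs <- unique(rbind(bench$pairs, extra), by = c("gene1", "gene2"))
    prot <- generate_protein_families(
      seed = stage_seed(config$seed, "proteins"))
    write_expression_tsv(bench$atlas$tpm, pt("expression.tsv"))
    write_replicate_map(bench$atlas$replicate_map, pt("replicate_map.tsv"))
    write_pair_table(pairs, pt("pairs.tsv"))
    write_subgenome_map(sub$map, pt("subgenome_map.tsv"))
    write_gmt(sub$pathways, pt("pathways.gmt"))
    write_protein_fasta(Biostrings::AAStringSet(prot$proteome),
                        pt("proteome.fasta"))
    data.table::fwrite(data.table::data.table(gene_id = sub$lost_genes),
                       pt("lost_genes.tsv"), sep = "\t")
    counts$simulate <- c(genes = n, pairs = nrow(pairs))
    log_stage("simulate", sprintf("%d genes, %d pairs", n, nrow(pairs)))
  }

  if ("preprocess" %in% stages) {
    .require_inputs(outdir, "preprocess",
                    c("expression.tsv", "replicate_map.tsv"))
    atlas <- expression_atlas(read_expression_tsv(pt("expression.tsv")),
                              read_replicate_map(pt("replicate_map.tsv")))
    prep <- preprocess_atlas(atlas)
    write_expression_tsv(prep$matrix, pt("expression_transformed.tsv"))
    counts$preprocess <- c(genes = nrow(prep$matrix),
                           removed = length(prep$removed))
    log_stage("preprocess", sprintf("%d genes kept, %d removed",
                                    nrow(prep$matrix), length(prep$removed)))
  }

  if ("network" %in% stages) {
    .require_inputs(outdir, "network", "expression_transformed.tsv")
    x <- read_expression_tsv(pt("expression_transformed.tsv"))
    net <- build_network(x, cutoff = config$z_cutoff)
    write_edge_list(net$edges, pt("edges.tsv"))
    mods <- detect_modules_mcl(net, inflation = config$inflation)
    write_module_table(mods$assignment, pt("modules.tsv"))
    counts$network <- c(edges = nrow(net$edges),
                        modules = mods$n_modules,
                        modules_ge10 = mods$n_modules_large)
    log_stage("network", sprintf("%d edges (z > %g), %d modules",
                                 nrow(net$edges), config$z_cutoff,
                                 mods$n_modules))
  }

  if ("paralogs" %in% stages) {
    .require_inputs(outdir, "paralogs",
                    c("proteome.fasta", "pairs.tsv", "subgenome_map.tsv"))
    prot <- read_protein_fasta(pt("proteome.fasta"))
    cand <- detect_paralog_pairs(prot, min_coverage = config$min_coverage,
                                 min_score = config$min_score)
    data.table::fwrite(cand, pt("paralog_candidates.tsv"), sep = "\t")
    typed <- classify_duplication_type(read_pair_table(pt("pairs.tsv")),
                                       read_subgenome_map(pt("subgenome_map.tsv")),
                                       tandem_window = config$tandem_window)
    data.table::fwrite(typed, pt("pairs_typed.tsv"), sep = "\t")
    counts$paralogs <- c(candidates = nrow(cand), typed = nrow(typed))
    log_stage("paralogs", sprintf("%d candidate pairs", nrow(cand)))
  }

  if ("divergence" %in% stages) {
    .require_inputs(outdir, "divergence",
                    c("edges.tsv", "pairs.tsv", "expression_transformed.tsv"))
    net <- structure(list(gene_ids = rownames(read_expression_tsv(
      pt("expression_transformed.tsv"))),
      edges = read_edge_list(pt("edges.tsv")),
      cutoff = config$z_cutoff), class = "coexpression_network")
    pairs <- read_pair_table(pt("pairs.tsv"))
    rec <- classify_divergence(net, pairs, radius = config$radius,
                               min_neighbors = config$min_neighbors)
    data.table::fwrite(rec, pt("divergence.tsv"), sep = "\t")
    enr <- type_by_duptype_enrichment(rec)
    data.table::fwrite(enr, pt("enrichment.tsv"), sep = "\t")
    dss <- ds_by_type_summary(rec)
    data.table::fwrite(dss$summary, pt("ds_summary.tsv"), sep = "\t")
    counts$divergence <- c(pairs = nrow(rec),
                           classified = sum(rec$type_label != "excluded"))
    log_stage("divergence",
              sprintf("%d pairs classified (age test p = %.3g)",
                      nrow(rec),
                      if (is.null(dss$test)) NA else dss$test$p.value))
  }

  if ("subgenome" %in% stages) {
    .require_inputs(outdir, "subgenome",
                    c("edges.tsv", "modules.tsv", "subgenome_map.tsv",
                      "pathways.gmt", "pairs.tsv"))
    edges <- read_edge_list(pt("edges.tsv"))
    map <- read_subgenome_map(pt("subgenome_map.tsv"))
    pairs <- read_pair_table(pt("pairs.tsv"))
    pathways <- read_gmt(pt("pathways.gmt"))
    lost <- data.table::fread(pt("lost_genes.tsv"))$gene_id
    net <- structure(list(gene_ids = unique(c(edges$gene1, edges$gene2)),
                          edges = edges, cutoff = config$z_cutoff),
                     class = "coexpression_network")
    # genome-wide fractionation: all genes, retained-pair genes, and
    # genes whose homeolog was lost
    wgd <- pairs[dup_type == "WGD"]
    sets <- list(
      all = NULL,
      retained = unique(c(wgd$gene1, wgd$gene2)),
      lost_side = lost)
    fr_rows <- list()
    for (nm in names(sets)) {
      fr <- tryCatch(count_subgenome_edges(net, map, sets[[nm]]),
                     error = function(e) NULL)
      if (is.null(fr)) next
      fr_rows[[nm]] <- data.table::data.table(
        set = nm, m1_intra = fr$m1_intra, m2_intra = fr$m2_intra,
        inter = fr$inter, d_m1 = fr$densities[["m1"]],
        d_m2 = fr$densities[["m2"]], d_inter = fr$densities[["inter"]])
      if (nm == "all") {
        perm <- permute_edge_null(
          fr$n_maize1, fr$n_maize2,
          fr$m1_intra + fr$m2_intra + fr$inter, fr$inter,
          n_perm = config$n_perm,
          seed = stage_seed(config$seed, "edge_null"))
        cont <- contingency_edge_test(fr)
        fr_rows[[nm]][, `:=`(perm_p = perm$p.value,
                             contingency_p = cont$p.value)]
      }
    }
    data.table::fwrite(data.table::rbindlist(fr_rows, fill = TRUE),
                       pt("fractionation.tsv"), sep = "\t")
    pw <- tryCatch(
      pathway_fractionation(net, map, pathways, pairs,
                            min_edges = config$min_edges,
                            min_wgd_pairs = config$min_wgd_pairs),
      error = function(e) NULL)
    if (!is.null(pw)) {
      tests <- data.table::rbindlist(lapply(names(pw$tests), function(nm)
        data.table::data.table(test = nm,
                               statistic = pw$tests[[nm]]$statistic,
                               p_value = pw$tests[[nm]]$p.value)))
      data.table::fwrite(tests, pt("pathway_tests.tsv"), sep = "\t")
    } else {
      data.table::fwrite(data.table::data.table(test = character(0),
                                                statistic = numeric(0),
                                                p_value = numeric(0)),
                         pt("pathway_tests.tsv"), sep = "\t")
    }
    mods <- read_module_table(pt("modules.tsv"))
    enr <- module_subgenome_enrichment(mods, map,
                                       min_labeled = config$min_labeled)
    data.table::fwrite(enr, pt("module_enrichment.tsv"), sep = "\t")
    hubs <- detect_hub_genes(net, n_perm = min(config$n_perm, 200L),
                             alpha = config$alpha,
                             seed = stage_seed(config$seed, "hub_null"))
    bias <- tryCatch(hub_subgenome_bias(hubs, map), error = function(e) NULL)
    hub_dt <- data.table::data.table(gene_id = hubs$hub_genes)
    hub_dt[, degree := hubs$degrees[gene_id]]
    data.table::fwrite(hub_dt, pt("hubs.tsv"), sep = "\t")
    counts$subgenome <- c(hubs = length(hubs$hub_genes),
                          hub_cutoff = hubs$cutoff,
                          modules_tested = nrow(enr))
    log_stage("subgenome",
              sprintf("%d hubs (degree > %d)%s", length(hubs$hub_genes),
                      hubs$cutoff,
                      if (is.null(bias)) "" else
                        sprintf(", bias p = %.3g", bias$p.value)))
  }

  # manifest: config, row counts, file checksums, overall hash
  files <- sort(unlist(.stage_files[stages], use.names = FALSE))
  files <- files[file.exists(file.path(outdir, files))]
  sums <- tools::md5sum(file.path(outdir, files))
  names(sums) <- files
  manifest <- list(package = "coexdiv",
                   version = as.character(utils::packageVersion("coexdiv")),
                   config = unclass(config), stages = stages,
                   row_counts = counts, file_md5 = as.list(sums))
  tmp <- tempfile()
  jsonlite::write_json(manifest$file_md5, tmp, auto_unbox = TRUE)
  manifest$manifest_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

utils::globalVariables(c("planted_divergence", "degree", "set"))
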