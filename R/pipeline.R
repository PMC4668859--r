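# End-to-end orchestration: phenotype scan -> eQTLs -> c3 screen ->
# causality triads -> co-expression network -> module QTLs/CDD classes ->
# structural-variant profiles, with TSV reports and a JSON run manifest.

#' Run the full analysis pipeline
#'
#' @param config A `pipeline_config`.
#' @param genotypes A `ris_genotypes` panel.
#' @param expr Strains x genes expression matrix (strain ids must match
#'   the genotype panel).
#' @param annotation Gene annotation (gene_id, chrom, start_Mb).
#' @param phenotype Named phenotype vector over strains.
#' @param variant_track Optional `variant_track` for the SV stage.
#' @param outdir Output directory for TSV reports and the manifest; NULL
#'   skips writing.
#' @param min_module_size Override of the network minimum module size
#'   (NULL keeps `config$network`).
#' @return List with each stage's tables: phenotype_scan, eqtls, c3,
#'   triads, network, modules, sv (or NULL), manifest.
#' @export
run_pipeline <- function(config, genotypes, expr, annotation, phenotype,
                         variant_track = NULL, outdir = NULL,
                         min_module_size = NULL) {
  strains <- genotypes$strain_ids
  bad <- c(setdiff(rownames(expr), strains), setdiff(names(phenotype), strains),
           setdiff(strains, rownames(expr)), setdiff(strains, names(phenotype)))
  if (length(bad))
    .stopf("strain-id mismatch between inputs: %s",
           paste(unique(bad), collapse = ", "))
  expr <- expr[strains, , drop = FALSE]
  phenotype <- phenotype[strains]
  net_params <- config$network
  if (!is.null(min_module_size)) net_params$min_cluster_size <- min_module_size
  net_params <- do.call(network_params, net_params[c("beta", "deep_split",
                                                     "min_cluster_size",
                                                     "cut_height", "signed")])

  message("[scan] phenotype genome scan")
  pheno_scan <- genome_scan(phenotype, genotypes)
  pheno_interval <- lod_support_interval(pheno_scan)

  message("[eqtl] mapping ", ncol(expr), " genes")
  eqtls <- map_all_eqtls(expr, genotypes, annotation,
                         lod_threshold = config$lod_threshold,
                         cis_window_Mb = config$cis_window_Mb)
  cis <- eqtls[eqtls$cis, , drop = FALSE]
  message("[eqtl] ", nrow(eqtls), " eQTLs, ", nrow(cis), " cis")

  c3 <- NULL
  triads <- NULL
  if (nrow(cis) > 0) {
    corr <- correlate_with_trait_wy(expr[, unique(cis$gene_id), drop = FALSE],
                                    phenotype, n_perm = max(config$n_perm, 1000),
                                    seed = config$seed)
    c3 <- select_c3(eqtls, corr, pheno_interval, fdr = config$fdr)
    message("[c3] ", sum(c3$c3), " c3-eQTLs of ", nrow(c3), " cis genes")
    c3_genes <- c3$gene_id[c3$c3]
    if (length(c3_genes) > 0) {
      triads <- triad_table(expr[, c3_genes, drop = FALSE], phenotype,
                            genotypes, locus_chrom = pheno_interval$chrom,
                            threshold = config$lod_threshold)
    }
  }

  message("[network] building co-expression network")
  model <- build_network(expr, net_params)
  modules <- module_report(model, genotypes, annotation, phenotype,
                           cis_gene_ids = unique(cis$gene_id),
                           threshold = config$lod_threshold)

  sv <- NULL
  best <- modules[which.max(abs(modules$trait_r)), ]
  if (!is.null(variant_track) && is.finite(best$main_mqtl_lod)) {
    center <- list(chrom = best$main_mqtl_chrom, Mb = best$main_mqtl_Mb)
    prof <- binned_profile(variant_track, center,
                           bin_width_Mb = config$sv_bin_Mb,
                           extent_Mb = config$sv_extent_Mb)
    bg <- random_background(variant_track, genotypes$map,
                            n_sites = config$sv_n_background,
                            seed = config$seed,
                            bin_width_Mb = config$sv_bin_Mb,
                            extent_Mb = config$sv_extent_Mb)
    sv <- list(center = center, profile = prof, background = bg)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cddnet")),
    seed = config$seed,
    config = unclass(config),
    n_strains = length(strains), n_genes = ncol(expr),
    n_markers = nrow(genotypes$map),
    phenotype_peak = attr(pheno_scan, "peak"),
    phenotype_interval = unclass(pheno_interval),
    n_eqtls = nrow(eqtls), n_cis_eqtls = nrow(cis),
    n_c3_eqtls = if (is.null(c3)) 0L else sum(c3$c3),
    n_modules = length(setdiff(unique(model$labels), "grey")),
    best_module = best$module,
    recovered_domain = list(chrom = best$main_mqtl_chrom,
                            lo_Mb = best$main_mqtl_lo_Mb,
                            hi_Mb = best$main_mqtl_hi_Mb)
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(as.data.frame(pheno_scan), file.path(outdir, "phenotype_scan.tsv"),
               "chrom, pos_Mb, LOD")
    .write_tsv(eqtls, file.path(outdir, "eqtls.tsv"), "eQTL records")
    if (!is.null(c3)) .write_tsv(c3, file.path(outdir, "c3_eqtls.tsv"),
                                 "cis-eQTL x phenotype screen")
    if (!is.null(triads)) .write_tsv(triads, file.path(outdir, "triads.tsv"),
                                     "reciprocal covariate scans")
    .write_tsv(modules, file.path(outdir, "modules.tsv"), "module report")
    export_cytoscape(model, annotation, file.path(outdir, "network_edges.tsv"),
                     file.path(outdir, "network_nodes.tsv"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  list(phenotype_scan = pheno_scan, phenotype_interval = pheno_interval,
       eqtls = eqtls, c3 = c3, triads = triads, network = model,
       modules = modules, sv = sv, manifest = manifest)
}
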