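# Tabular readers/writers (GeneNetwork-style TSV, `#` comment headers),
# preprocessing and configuration.

.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

.write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a genotype panel as TSV (+ marker map TSV)
#'
#' Genotypes are strains x markers with A/B codes, first column `strain`.
#'
#' @param genotypes A `ris_genotypes` panel.
#' @param geno_file,map_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_genotypes <- function(genotypes, geno_file, map_file) {
  g <- data.frame(strain = genotypes$strain_ids,
                  genotypes$codes, check.names = FALSE)
  .write_tsv(g, geno_file, "RIS genotypes, biallelic codes A/B")
  .write_tsv(genotypes$map, map_file,
             "marker map: chrom, pos_cM (centimorgan), pos_Mb (megabase)")
  invisible(c(geno_file, map_file))
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(geno_file, map_file) {
  g <- .read_tsv(geno_file)
  map <- .read_tsv(map_file)
  class(map) <- c("marker_map", "data.frame")
  .validate_map(map)
  codes <- as.matrix(g[, -1, drop = FALSE])
  rownames(codes) <- g$strain
  codes <- codes[, map$marker_id, drop = FALSE]
  structure(list(strain_ids = g$strain, map = map, codes = codes),
            class = "ris_genotypes")
}

#' Write / read an expression matrix and gene annotation as TSV
#'
#' @param expr Strains x genes matrix.
#' @param annotation data.frame gene_id, chrom, start_Mb.
#' @param expr_file,ann_file Output paths.
#' @return Invisibly, the paths.
#' @export
write_expression <- function(expr, annotation, expr_file, ann_file) {
  e <- data.frame(strain = rownames(expr), expr, check.names = FALSE)
  .write_tsv(e, expr_file, "strain-level expression (log2 scale)")
  .write_tsv(annotation, ann_file, "gene annotation: chrom, start_Mb")
  invisible(c(expr_file, ann_file))
}

#' @rdname write_expression
#' @export
read_expression <- function(expr_file, ann_file) {
  e <- .read_tsv(expr_file)
  ann <- .read_tsv(ann_file)
  expr <- as.matrix(e[, -1, drop = FALSE])
  rownames(expr) <- e$strain
  list(expr = expr, annotation = ann)
}

#' Write / read a per-strain phenotype vector as TSV
#'
#' @param phenotype Named numeric vector over strains.
#' @param file Path.
#' @return Invisibly, the path / the named vector.
#' @export
write_phenotype <- function(phenotype, file) {
  .write_tsv(data.frame(strain = names(phenotype), value = unname(phenotype)),
             file, "normalized phenotype per strain")
}

#' @rdname write_phenotype
#' @export
read_phenotype <- function(file) {
  d <- .read_tsv(file)
  stats::setNames(d$value, d$strain)
}

#' Write / read a variant track as BED-like TSV
#'
#' Columns: chrom, start_Mb, end_Mb, kind (points get end = start).
#'
#' @param track A `variant_track`.
#' @param file Path.
#' @return Invisibly, the path / the track.
#' @export
write_variant_track <- function(track, file) {
  .write_tsv(data.frame(chrom = track$chrom, start_Mb = track$pos_Mb,
                        end_Mb = track$pos_Mb, kind = track$kind),
             file, "structural variant track (positions in Mb)")
}

#' @rdname write_variant_track
#' @export
read_variant_track <- function(file) {
  d <- .read_tsv(file)
  out <- data.frame(chrom = d$chrom, pos_Mb = d$start_Mb, kind = d$kind,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos_Mb), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_track", "data.frame")
  out
}

#' Remove probes flagged for SNPs within their sequence
#'
#' @param expr Strains x genes matrix.
#' @param flagged_probe_ids Probe/gene ids to remove; unknown ids are
#'   ignored with a notice.
#' @return Filtered matrix.
#' @export
filter_probes_with_snps <- function(expr, flagged_probe_ids) {
  if (length(flagged_probe_ids) == 0) return(expr)
  known <- intersect(flagged_probe_ids, colnames(expr))
  unknown <- setdiff(flagged_probe_ids, colnames(expr))
  if (length(unknown))
    warning(length(unknown), " flagged id(s) not present in the matrix; ignored")
  if (length(known) == ncol(expr))
    .stopf("all probes flagged: empty expression matrix")
  message("removed ", length(known), " probe(s) flagged for SNPs")
  expr[, setdiff(colnames(expr), known), drop = FALSE]
}

#' Average individual-level expression into strain means
#'
#' @param individual_expr Individuals x genes matrix.
#' @param strain_assignment Strain id per individual (row).
#' @param strain_order Optional strain ordering for the output (e.g. the
#'   genotype file's order); default: first appearance.
#' @return Strains x genes matrix of per-gene arithmetic means.
#' @export
average_replicates <- function(individual_expr, strain_assignment,
                               strain_order = NULL) {
  stopifnot(nrow(individual_expr) == length(strain_assignment))
  if (is.null(strain_order)) strain_order <- unique(strain_assignment)
  missing <- setdiff(strain_order, strain_assignment)
  if (length(missing))
    .stopf("strain(s) with zero individuals: %s", paste(missing, collapse = ", "))
  out <- t(vapply(strain_order, function(s) {
    colMeans(individual_expr[strain_assignment == s, , drop = FALSE])
  }, numeric(ncol(individual_expr))))
  rownames(out) <- strain_order
  out
}

#' Pipeline configuration
#'
#' Collects the analysis constants: LOD threshold 3.3, 1 Mb cis window,
#' FDR 0.1 on q-values, permutation count, network parameters, variant
#' profile geometry (2 Mb bins to +/-18 Mb, 20 Mb comparison window, 500
#' background sites) and the master seed. Serializes losslessly to JSON.
#'
#' @param lod_threshold,cis_window_Mb,fdr,n_perm Scalars.
#' @param network A `network_params`.
#' @param sv_bin_Mb,sv_extent_Mb,sv_window_Mb,sv_n_background Variant
#'   profile geometry.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(lod_threshold = 3.3, cis_window_Mb = 1,
                            fdr = 0.1, n_perm = 10000,
                            network = network_params(),
                            sv_bin_Mb = 2, sv_extent_Mb = 18,
                            sv_window_Mb = 20, sv_n_background = 500,
                            seed = 1) {
  stopifnot(lod_threshold > 0, cis_window_Mb > 0, fdr > 0, n_perm >= 0)
  structure(list(lod_threshold = lod_threshold, cis_window_Mb = cis_window_Mb,
                 fdr = fdr, n_perm = n_perm, network = unclass(network),
                 sv_bin_Mb = sv_bin_Mb, sv_extent_Mb = sv_extent_Mb,
                 sv_window_Mb = sv_window_Mb,
                 sv_n_background = sv_n_background, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param file JSON path.
#' @export
write_config <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname pipeline_config
#' @export
read_config <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  net <- do.call(network_params, x$network)
  x$network <- NULL
  do.call(pipeline_config, c(x, list(network = net)))
}
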