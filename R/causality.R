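# Reciprocal covariate-scan "triad" analysis: given a locus, a cis-eQTL
# gene and a phenotype that share linkage, decide whether the gene's
# expression leans causal or reactive to the phenotype.

#' Reciprocal covariate scans for one gene/trait/locus triad
#'
#' Four genome scans are run: the trait with and without the gene as a
#' covariate, and the gene with and without the trait as a covariate. LODs
#' are read at the fixed peak markers of the two unconditional scans on
#' the locus chromosome, so drops are comparable across genes. The
#' convenience call is: *causal-leaning* when conditioning on the gene
#' removes at least `drop_fraction` of the phenotype LOD while the gene's
#' eQTL stays detectable given the trait; *reactive-leaning* when
#' conditioning on the trait pushes a detectable eQTL below the threshold;
#' *undetermined* otherwise. The call labels are a convenience layer over
#' the reported LODs.
#'
#' @param gene Expression vector over strains.
#' @param trait Phenotype vector over strains.
#' @param genotypes A `ris_genotypes` panel.
#' @param locus_chrom Chromosome of the shared locus.
#' @param threshold Detection threshold (default 3.3).
#' @param drop_fraction Fraction of the phenotype LOD that must vanish for
#'   a causal-leaning call (default 0.5).
#' @return A `triad_result` list: gene/pheno LODs, conditional LODs, drop,
#'   residual_detectable, call.
#' @export
triad_scan <- function(gene, trait, genotypes, locus_chrom, threshold = 3.3,
                       drop_fraction = 0.5) {
  if (!(locus_chrom %in% genotypes$map$chrom))
    .stopf("chromosome %s not present in map", locus_chrom)
  if (.is_constant(gene) || .is_constant(trait))
    .stopf("degenerate gene or trait: zero variance")

  sp <- genome_scan(trait, genotypes)
  sg <- genome_scan(gene, genotypes)
  at_chrom <- function(scan, chrom) {
    sub <- scan[scan$chrom == chrom, , drop = FALSE]
    sub$marker_id[which.max(sub$lod)]
  }
  mk_p <- at_chrom(sp, locus_chrom)
  mk_g <- at_chrom(sg, locus_chrom)
  lod_at <- function(scan, mk) {
    v <- scan$lod[scan$marker_id == mk]
    if (length(v) == 0) 0 else v
  }
  sp_g <- genome_scan(trait, genotypes, covariate = gene)
  sg_p <- genome_scan(gene, genotypes, covariate = trait)

  lod_pheno <- lod_at(sp, mk_p)
  lod_pheno_given_expr <- lod_at(sp_g, mk_p)
  lod_expr <- lod_at(sg, mk_g)
  lod_expr_given_pheno <- lod_at(sg_p, mk_g)
  drop <- lod_pheno - lod_pheno_given_expr
  residual_detectable <- lod_expr_given_pheno >= threshold

  call <- "undetermined"
  if (lod_expr >= threshold && !residual_detectable) {
    call <- "reactive-leaning"
  } else if (drop >= drop_fraction * lod_pheno && residual_detectable &&
             lod_pheno > 0) {
    call <- "causal-leaning"
  }
  structure(list(
    lod_pheno = lod_pheno, lod_pheno_given_expr = lod_pheno_given_expr,
    drop = drop, lod_expr = lod_expr,
    lod_expr_given_pheno = lod_expr_given_pheno,
    residual_detectable = residual_detectable,
    peak_marker_pheno = mk_p, peak_marker_expr = mk_g,
    call = call), class = "triad_result")
}

#' Run triads for many genes and rank by LOD drop
#'
#' @param expr Strains x genes matrix of candidate cis-eQTL genes.
#' @param trait Phenotype vector.
#' @param genotypes A `ris_genotypes` panel.
#' @param locus_chrom Shared locus chromosome.
#' @param ... Passed to [triad_scan()].
#' @return data.frame of triad results, one row per gene, sorted by
#'   descending drop (ties broken by gene id).
#' @export
triad_table <- function(expr, trait, genotypes, locus_chrom, ...) {
  rows <- lapply(colnames(expr), function(g) {
    tr <- triad_scan(expr[, g], trait, genotypes, locus_chrom, ...)
    data.frame(gene_id = g, lod_pheno = tr$lod_pheno,
               lod_pheno_given_expr = tr$lod_pheno_given_expr,
               drop = tr$drop, lod_expr = tr$lod_expr,
               lod_expr_given_pheno = tr$lod_expr_given_pheno,
               residual_detectable = tr$residual_detectable,
               call = tr$call, stringsAsFactors = FALSE)
  })
  rank_by_drop(do.call(rbind, rows))
}

#' Order triad results by descending LOD drop
#'
#' Ties are broken lexicographically by gene id for determinism.
#'
#' @param triads data.frame with columns `gene_id` and `drop`.
#' @return The same data.frame, reordered.
#' @export
rank_by_drop <- function(triads) {
  stopifnot(nrow(triads) >= 1)
  out <- triads[order(-triads$drop, triads$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
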