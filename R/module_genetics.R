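# Module QTLs and chromosome-domain-driven (CDD) classification: map each
# module eigengene, find its predominant chromosome, compute domain
# statistics and compare module classes.

#' Map mQTLs for a module eigengene
#'
#' Genome scan on the eigengene; one mQTL per chromosome whose maximum LOD
#' reaches the threshold. The main mQTL is the highest-LOD entry, ties
#' broken toward the lower chromosome number.
#'
#' @param eigengene Strain-length eigengene vector.
#' @param genotypes A `ris_genotypes` panel.
#' @param threshold LOD threshold (default 3.3, as for eQTLs).
#' @param drop LOD drop for support intervals.
#' @return data.frame (chrom, Mb, lod, lo_Mb, hi_Mb) sorted by descending
#'   LOD then chromosome; zero rows when no linkage.
#' @export
map_mqtls <- function(eigengene, genotypes, threshold = 3.3, drop = 1.5) {
  scan <- genome_scan(eigengene, genotypes)
  rows <- lapply(unique(scan$chrom), function(ch) {
    sub <- scan[scan$chrom == ch, , drop = FALSE]
    pk <- which.max(sub$lod)
    if (sub$lod[pk] < threshold) return(NULL)
    si <- lod_support_interval(scan, chrom = ch, drop = drop)
    data.frame(chrom = ch, Mb = sub$pos_Mb[pk], lod = sub$lod[pk],
               lo_Mb = si$lo_Mb, hi_Mb = si$hi_Mb)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = integer(0), Mb = numeric(0), lod = numeric(0),
               lo_Mb = numeric(0), hi_Mb = numeric(0))
  out <- out[order(-out$lod, out$chrom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a module as CDD, genetic non-CDD or non-genetic
#'
#' Non-genetic when no mQTL reaches threshold; otherwise CDD when the main
#' mQTL chromosome equals the module's predominant chromosome (the
#' chromosome contributing the most member genes; ties broken toward the
#' mQTL chromosome, with a notice); else genetic non-CDD.
#'
#' @param mqtls mQTL table from [map_mqtls()].
#' @param gene_chroms Chromosome of each member gene (annotation).
#' @return List: class, predominant_chrom, pct_genes_predominant,
#'   main_mqtl (row or NULL).
#' @export
classify_module <- function(mqtls, gene_chroms) {
  if (mean(is.na(gene_chroms)) > 0.1)
    .stopf("annotation missing for more than 10%% of module genes")
  tab <- table(gene_chroms[!is.na(gene_chroms)])
  top <- names(tab)[tab == max(tab)]
  if (nrow(mqtls) == 0) {
    return(list(class = "non-genetic", predominant_chrom = top[1],
                pct_genes_predominant = 100 * max(tab) / sum(tab),
                main_mqtl = NULL))
  }
  main <- mqtls[1, ]
  pred <- if (length(top) > 1) {
    if (as.character(main$chrom) %in% top) {
      message("predominant-chromosome tie broken toward the mQTL chromosome")
      as.character(main$chrom)
    } else top[1]
  } else top[1]
  cls <- if (as.character(main$chrom) == pred) "CDD" else "genetic-non-CDD"
  list(class = cls, predominant_chrom = pred,
       pct_genes_predominant = 100 * max(tab) / sum(tab),
       main_mqtl = main)
}

#' Domain statistics for a module
#'
#' Mean pairwise physical distance (Mb) among genes on the predominant
#' chromosome; percentage of module genes that are cis-eQTLs; relative
#' connectivity of predominant-chromosome genes (their mean connectivity
#' divided by that of the remaining module genes; NA when the module has a
#' single chromosome).
#'
#' @param member_genes Module gene ids.
#' @param annotation Gene annotation (gene_id, chrom, start_Mb).
#' @param cis_gene_ids Gene ids classified as cis-eQTLs.
#' @param connectivity Named connectivity vector over network genes.
#' @param predominant_chrom Predominant chromosome label.
#' @return List: mean_pairwise_distance_Mb, pct_cis_eqtl_genes,
#'   relative_connectivity.
#' @export
domain_stats <- function(member_genes, annotation, cis_gene_ids,
                         connectivity, predominant_chrom) {
  ann <- annotation[match(member_genes, annotation$gene_id), ]
  on_pred <- !is.na(ann$chrom) &
    as.character(ann$chrom) == as.character(predominant_chrom)
  pos <- ann$start_Mb[on_pred]
  mpd <- if (length(pos) >= 2) mean(stats::dist(pos)) else NA_real_
  pct_cis <- 100 * mean(member_genes %in% cis_gene_ids)
  rel_k <- if (any(on_pred) && any(!on_pred)) {
    mean(connectivity[member_genes[on_pred]]) /
      mean(connectivity[member_genes[!on_pred]])
  } else NA_real_
  list(mean_pairwise_distance_Mb = mpd, pct_cis_eqtl_genes = pct_cis,
       relative_connectivity = rel_k)
}

#' Expected number of module genes from one chromosome
#'
#' Under random sampling of genes, module_size * chrom_gene_count /
#' genome_gene_count; reported with one decimal alongside an exact
#' binomial tail p-value for an observed count.
#'
#' @param module_size Number of genes in the module.
#' @param chrom_gene_count Genes on the chromosome, genome-wide.
#' @param genome_gene_count Total genes in the genome inventory.
#' @param observed Optional observed count for the binomial tail test.
#' @return List: expected (1-decimal), expected_raw, p_value (or NA).
#' @export
expected_chromosome_count <- function(module_size, chrom_gene_count,
                                      genome_gene_count, observed = NULL) {
  if (genome_gene_count <= 0) .stopf("genome gene count must be positive")
  stopifnot(module_size >= 0, chrom_gene_count >= 0,
            chrom_gene_count <= genome_gene_count)
  pr <- chrom_gene_count / genome_gene_count
  exp_raw <- module_size * pr
  p <- if (!is.null(observed))
    stats::pbinom(observed - 1, module_size, pr, lower.tail = FALSE) else NA_real_
  list(expected = round(exp_raw, 1), expected_raw = exp_raw, p_value = p)
}

#' Per-module report over a whole network
#'
#' Combines mQTL mapping, classification, domain statistics, the expected
#' predominant-chromosome count and the eigengene-trait correlation into
#' one table row per module.
#'
#' @param model A `network_model`.
#' @param genotypes A `ris_genotypes` panel.
#' @param annotation Gene annotation (gene_id, chrom, start_Mb).
#' @param trait Phenotype vector.
#' @param cis_gene_ids Gene ids of cis-eQTLs (from [map_all_eqtls()]).
#' @param threshold mQTL LOD threshold (default 3.3).
#' @return A `module_report` data.frame, one row per module.
#' @export
module_report <- function(model, genotypes, annotation, trait,
                          cis_gene_ids = character(0), threshold = 3.3) {
  mods <- colnames(model$eigengenes)
  mtc <- module_trait_correlation(model$eigengenes, trait)
  rows <- lapply(mods, function(m) {
    members <- names(model$labels)[model$labels == m]
    mq <- map_mqtls(model$eigengenes[, m], genotypes, threshold)
    cls <- classify_module(mq, annotation$chrom[match(members, annotation$gene_id)])
    ds <- domain_stats(members, annotation, cis_gene_ids,
                       model$connectivity, cls$predominant_chrom)
    genome_n <- nrow(annotation)
    chrom_n <- sum(as.character(annotation$chrom) ==
                     as.character(cls$predominant_chrom), na.rm = TRUE)
    obs_n <- round(length(members) * cls$pct_genes_predominant / 100)
    ec <- expected_chromosome_count(length(members), chrom_n, genome_n,
                                    observed = obs_n)
    data.frame(
      module = m, n_genes = length(members), class = cls$class,
      main_mqtl_chrom = if (is.null(cls$main_mqtl)) NA else cls$main_mqtl$chrom,
      main_mqtl_Mb = if (is.null(cls$main_mqtl)) NA else cls$main_mqtl$Mb,
      main_mqtl_lod = if (is.null(cls$main_mqtl)) NA else cls$main_mqtl$lod,
      main_mqtl_lo_Mb = if (is.null(cls$main_mqtl)) NA else cls$main_mqtl$lo_Mb,
      main_mqtl_hi_Mb = if (is.null(cls$main_mqtl)) NA else cls$main_mqtl$hi_Mb,
      n_mqtls = nrow(mq),
      predominant_chrom = cls$predominant_chrom,
      pct_genes_predominant = cls$pct_genes_predominant,
      expected_genes_predominant = ec$expected_raw,
      enrichment_p = ec$p_value,
      mean_pairwise_distance_Mb = ds$mean_pairwise_distance_Mb,
      pct_cis_eqtl_genes = ds$pct_cis_eqtl_genes,
      relative_connectivity = ds$relative_connectivity,
      trait_r = mtc$r[mtc$module == m], trait_p = mtc$p[mtc$module == m],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("module_report", "data.frame")
  out
}

#' Compare module classes by ANOVA and Tukey HSD
#'
#' One-way ANOVA of each statistic across module classes, followed by all
#' pairwise Tukey honest-significant-difference p-values, formatted like a
#' module-properties table. Classes with fewer than two modules are
#' excluded with a warning.
#'
#' @param reports A `module_report` data.frame.
#' @param statistics Columns to compare.
#' @return Named list per statistic: list(anova_p, tukey (data.frame
#'   comparison, diff, p_adj), group_means).
#' @export
compare_module_classes <- function(reports,
                                   statistics = c("mean_pairwise_distance_Mb",
                                                  "pct_cis_eqtl_genes",
                                                  "pct_genes_predominant",
                                                  "relative_connectivity")) {
  counts <- table(reports$class)
  keep <- names(counts)[counts >= 2]
  if (length(setdiff(names(counts), keep)))
    warning("class(es) with fewer than 2 modules excluded: ",
            paste(setdiff(names(counts), keep), collapse = ", "))
  if (length(keep) < 2) .stopf("need at least 2 classes with >= 2 modules")
  sub <- reports[reports$class %in% keep, , drop = FALSE]
  sub$class <- factor(sub$class)
  out <- lapply(statistics, function(s) {
    df <- sub[is.finite(sub[[s]]), c("class", s)]
    if (length(unique(df$class)) < 2 || nrow(df) < 4)
      return(list(anova_p = NA_real_, tukey = NULL, group_means = NULL))
    names(df)[2] <- "value"
    fit <- stats::aov(value ~ class, data = df)
    an_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$class
    list(anova_p = an_p,
         tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                            p_adj = tk[, "p adj"], row.names = NULL),
         group_means = tapply(df$value, df$class, mean))
  })
  names(out) <- statistics
  out
}
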