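# Genome-wide eQTL mapping, cis/trans classification and c3-eQTL screening
# (cis-eQTLs colocalizing with a phenotypic QTL whose gene expression
# correlates with the phenotype) with Westfall-Young maxT control.

#' Map eQTLs for every gene
#'
#' Runs a marker-regression genome scan for each gene and emits one eQTL
#' record per (gene, chromosome) whose maximum LOD reaches the threshold,
#' so one gene can yield several eQTLs. A record is cis when its peak lies
#' within `cis_window_Mb` of the annotated gene start on the same
#' chromosome, trans otherwise. Constant genes are skipped with a notice.
#'
#' @param expr Strains x genes expression matrix (column names = gene ids).
#' @param genotypes A `ris_genotypes` panel (strains in matching order).
#' @param annotation data.frame with gene_id, chrom, start_Mb.
#' @param lod_threshold Detection threshold (default 3.3).
#' @param cis_window_Mb Cis window half-width (default 1 Mb).
#' @param drop LOD drop for support intervals (default 1.5).
#' @return data.frame of eQTL records: gene_id, gene_chrom, gene_start_Mb,
#'   peak_chrom, peak_Mb, peak_marker, lod, cis, lo_Mb, hi_Mb.
#' @export
map_all_eqtls <- function(expr, genotypes, annotation, lod_threshold = 3.3,
                          cis_window_Mb = 1, drop = 1.5) {
  stopifnot(nrow(expr) == length(genotypes$strain_ids))
  map <- genotypes$map
  X <- .geno_numeric(genotypes)
  vars <- apply(expr, 2, stats::var)
  const <- vars < 1e-12
  if (any(const))
    message(sum(const), " constant gene(s) skipped in eQTL mapping")
  genes <- colnames(expr)[!const]
  lod <- .lod_matrix(expr[, genes, drop = FALSE], X)   # markers x genes
  lod[is.na(lod)] <- 0
  lod <- pmax(lod, 0)
  ann <- annotation[match(genes, annotation$gene_id), ]

  recs <- list()
  chrom_idx <- split(seq_len(nrow(map)), map$chrom)
  for (gi in seq_along(genes)) {
    lg <- lod[, gi]
    for (ch in names(chrom_idx)) {
      idx <- chrom_idx[[ch]]
      mx <- max(lg[idx])
      if (mx < lod_threshold) next
      # tightly linked markers can carry identical genotype columns and tie
      # exactly; the peak location is then ambiguous and is resolved toward
      # the marker nearest the gene start (lowest position otherwise)
      tied <- idx[lg[idx] >= mx - 1e-9]
      pk <- if (!is.na(ann$chrom[gi]) &&
                as.character(ann$chrom[gi]) == ch && length(tied) > 1) {
        tied[which.min(abs(map$pos_Mb[tied] - ann$start_Mb[gi]))]
      } else tied[1]
      # support interval on this chromosome
      keep <- which(lg[idx] >= mx - drop)
      lo_i <- idx[max(min(keep) - 1L, 1L)]
      hi_i <- idx[min(max(keep) + 1L, length(idx))]
      cis <- !is.na(ann$chrom[gi]) &&
        as.character(ann$chrom[gi]) == as.character(map$chrom[pk]) &&
        abs(map$pos_Mb[pk] - ann$start_Mb[gi]) < cis_window_Mb
      recs[[length(recs) + 1L]] <- data.frame(
        gene_id = genes[gi], gene_chrom = ann$chrom[gi],
        gene_start_Mb = ann$start_Mb[gi],
        peak_chrom = map$chrom[pk], peak_Mb = map$pos_Mb[pk],
        peak_marker = map$marker_id[pk], lod = lg[pk], cis = cis,
        lo_Mb = map$pos_Mb[lo_i], hi_Mb = map$pos_Mb[hi_i],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(gene_id = character(0), gene_chrom = integer(0),
               gene_start_Mb = numeric(0), peak_chrom = integer(0),
               peak_Mb = numeric(0), peak_marker = character(0),
               lod = numeric(0), cis = logical(0), lo_Mb = numeric(0),
               hi_Mb = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "lod_threshold") <- lod_threshold
  attr(out, "cis_window_Mb") <- cis_window_Mb
  out
}

#' Westfall-Young adjusted gene-trait correlations
#'
#' The per-gene statistic is |Pearson r| between expression and the trait.
#' For each trait permutation the step-down maxT successive maxima are
#' recorded; adjusted_p(g) = (1 + #\{perm >= observed\}) / (n_perm + 1),
#' with monotonicity enforced down the ordered statistics. q-values are
#' computed from the adjusted p-values with the Storey pi0 smoothing
#' estimator. A single-step (plain maxT) variant is available.
#'
#' @param expr Strains x genes matrix (the cis-eQTL gene subset).
#' @param trait Numeric trait vector (nonconstant).
#' @param n_perm Number of permutations (>= 1000 recommended for
#'   production; smaller values are accepted for testing).
#' @param seed Integer seed.
#' @param step_down Use step-down maxT (default TRUE).
#' @return data.frame: gene_id, r, adjusted_p, q_value.
#' @export
correlate_with_trait_wy <- function(expr, trait, n_perm = 10000, seed = 1,
                                    step_down = TRUE) {
  if (is.null(dim(expr))) expr <- cbind(gene = expr)
  stopifnot(ncol(expr) >= 1)
  .check_numeric_vector(trait, "trait", nrow(expr))
  if (.is_constant(trait)) .stopf("degenerate trait: zero variance")
  n <- nrow(expr)
  m <- ncol(expr)
  obs <- abs(as.vector(stats::cor(expr, trait)))

  set.seed(.seed_from(seed, 6L))
  P <- vapply(seq_len(n_perm), function(i) sample(trait), numeric(n))
  R <- abs(stats::cor(expr, P))            # m x n_perm

  ord <- order(obs, decreasing = TRUE)
  if (step_down && m > 1) {
    # successive maxima over genes ranked at or below each observed statistic
    Rord <- R[ord, , drop = FALSE]
    step_max <- apply(Rord[rev(seq_len(m)), , drop = FALSE], 2, cummax)
    step_max <- step_max[rev(seq_len(m)), , drop = FALSE]   # m x n_perm
  } else {
    mx <- apply(R, 2, max)
    step_max <- matrix(mx, m, n_perm, byrow = TRUE)
  }
  p_ord <- (1 + rowSums(step_max >= obs[ord])) / (n_perm + 1)
  p_ord <- cummax(p_ord)                   # enforce step-down monotonicity
  adj_p <- numeric(m)
  adj_p[ord] <- p_ord

  data.frame(gene_id = colnames(expr), r = as.vector(stats::cor(expr, trait)),
             adjusted_p = adj_p, q_value = compute_qvalues(adj_p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' q-values from p-values (Storey pi0 smoothing estimator)
#'
#' pi0 is estimated on the lambda grid 0.05, 0.10, ..., 0.95 by a cubic
#' smoothing spline evaluated at the largest lambda (falling back to the
#' most conservative tail estimate when too few p-values are available to
#' smooth), then q(i) = min over j >= i of pi0 * m * p(j) / j on the
#' sorted p-values.
#'
#' @param p Vector of p-values.
#' @return Vector of q-values, same order as `p`.
#' @export
compute_qvalues <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  lambda <- seq(0.05, 0.95, 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  if (m >= 20 && length(unique(p)) > 4) {
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
  } else {
    pi0 <- min(pi0_l[lambda >= 0.5])
  }
  pi0 <- min(max(pi0, 0), 1)
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Select c3-eQTLs
#'
#' From the eQTL records and gene-trait correlations, keep cis-eQTL genes
#' with q-value at or below the FDR target, and flag those whose eQTL
#' support interval intersects the phenotype QTL support interval on the
#' same chromosome. c3-eQTLs are the genes passing both screens.
#'
#' @param records eQTL records from [map_all_eqtls()].
#' @param correlations Output of [correlate_with_trait_wy()].
#' @param phenotype_interval A `support_interval` for the phenotype QTL
#'   (from [lod_support_interval()]), or NULL (no overlap flags).
#' @param fdr FDR target on q-values (default 0.1).
#' @return data.frame: gene_id, peak_chrom, peak_Mb, lod, r, adjusted_p,
#'   q_value, q_pass, overlaps_phenotype_qtl, c3. All cis genes with
#'   correlations are reported; the c3 set is the rows with `c3 == TRUE`.
#' @export
select_c3 <- function(records, correlations, phenotype_interval = NULL,
                      fdr = 0.1) {
  cis <- records[records$cis, , drop = FALSE]
  out <- merge(cis, correlations, by = "gene_id")
  if (nrow(out) == 0) {
    out <- cbind(out, q_pass = logical(0), overlaps_phenotype_qtl = logical(0),
                 c3 = logical(0))
    return(out)
  }
  out$q_pass <- out$q_value <= fdr
  out$overlaps_phenotype_qtl <- vapply(seq_len(nrow(out)), function(i) {
    gi <- list(chrom = out$peak_chrom[i], lo_Mb = out$lo_Mb[i],
               hi_Mb = out$hi_Mb[i])
    .intervals_overlap(gi, phenotype_interval)
  }, logical(1))
  out$c3 <- out$q_pass & out$overlaps_phenotype_qtl
  out <- out[order(out$q_value, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
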