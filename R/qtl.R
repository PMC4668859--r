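# Single-trait genome scans on RIS panels: marker regression LOD curves,
# permutation thresholds and LOD support intervals. The engine reused by
# the eQTL, mQTL and causality stages.

# Vectorized LOD for many traits against many 0/1 markers, no covariate.
# Y: n x T matrix of traits; X: n x M matrix of 0/1 genotype codings.
# Returns M x T matrix of LOD = (n/2) log10(SST / RSS); markers with an
# empty genotype class give NA rows.
.lod_matrix <- function(Y, X) {
  n <- nrow(Y)
  nB <- colSums(X)
  nA <- n - nB
  ok <- nB > 0 & nA > 0
  Yc <- sweep(Y, 2, colMeans(Y))
  SST <- colSums(Yc^2)
  SB <- crossprod(X, Yc)                       # M x T: per-marker B-group sums
  between <- SB^2 * (1 / nB + 1 / nA)
  RSS <- pmax(sweep(-between, 2, SST, "+"), .Machine$double.eps)
  lod <- (n / 2) * log10(sweep(RSS, 2, SST, FUN = function(r, s) s / r))
  lod[!ok, ] <- NA_real_
  lod
}

#' Marker-regression genome scan
#'
#' At each marker the trait is regressed on the 0/1 genotype coding (plus
#' an optional covariate); LOD = (n/2) log10(RSS_null / RSS_full), where
#' the null model omits the genotype but keeps the covariate. n is the
#' number of strains (the panel maps strain means, not individuals).
#' Markers where one genotype class is empty are skipped with a notice.
#'
#' @param trait Numeric vector over strains (nonconstant).
#' @param genotypes A `ris_genotypes` panel.
#' @param covariate Optional numeric vector over strains.
#' @return A `scan_result`: data.frame (marker_id, chrom, pos_Mb, lod) with
#'   attributes `peak` (list chrom, Mb, lod, marker_id), `n`, and
#'   `covariate_used`.
#' @export
genome_scan <- function(trait, genotypes, covariate = NULL) {
  n <- length(genotypes$strain_ids)
  .check_numeric_vector(trait, "trait", n)
  if (.is_constant(trait)) .stopf("degenerate trait: zero variance")
  X <- .geno_numeric(genotypes)
  map <- genotypes$map

  if (is.null(covariate)) {
    lod <- drop(.lod_matrix(matrix(trait, ncol = 1), X))
  } else {
    .check_numeric_vector(covariate, "covariate", n)
    if (.is_constant(covariate))
      .stopf("covariate error: covariate is collinear with the intercept")
    null_fit <- stats::lm.fit(cbind(1, covariate), trait)
    rss0 <- sum(null_fit$residuals^2)
    lod <- vapply(seq_len(ncol(X)), function(j) {
      x <- X[, j]
      if (all(x == 0) || all(x == 1)) return(NA_real_)
      rss1 <- sum(stats::lm.fit(cbind(1, covariate, x), trait)$residuals^2)
      (n / 2) * log10(rss0 / max(rss1, .Machine$double.eps))
    }, numeric(1))
  }

  skipped <- is.na(lod)
  if (any(skipped))
    message(sum(skipped), " marker(s) with an empty genotype class skipped")
  res <- data.frame(marker_id = map$marker_id, chrom = map$chrom,
                    pos_Mb = map$pos_Mb, lod = lod,
                    stringsAsFactors = FALSE)[!skipped, , drop = FALSE]
  rownames(res) <- NULL
  res$lod <- pmax(res$lod, 0)
  pk <- which.max(res$lod)
  attr(res, "peak") <- list(chrom = res$chrom[pk], Mb = res$pos_Mb[pk],
                            lod = res$lod[pk], marker_id = res$marker_id[pk])
  attr(res, "n") <- n
  attr(res, "covariate_used") <- if (is.null(covariate)) NA_character_ else "covariate"
  class(res) <- c("scan_result", "data.frame")
  res
}

#' Genome-wide significance threshold
#'
#' With `n_perm = 0` (permutations disabled) returns the fixed pipeline
#' default of LOD 3.3. Otherwise permutes the trait across strains and
#' returns the (1 - alpha) empirical quantile of the genome-wide maximum
#' LOD over permutations.
#'
#' @param trait Numeric trait vector.
#' @param genotypes A `ris_genotypes` panel.
#' @param n_perm Number of permutations (>= 100), or 0 to disable.
#' @param alpha Genome-wide type-I error rate.
#' @param seed Integer seed.
#' @return Threshold LOD (numeric scalar).
#' @export
permutation_threshold <- function(trait, genotypes, n_perm = 0, alpha = 0.05,
                                  seed = 1) {
  if (n_perm == 0) return(3.3)
  if (n_perm < 100) .stopf("n_perm must be >= 100 (or 0 to disable)")
  n <- length(genotypes$strain_ids)
  .check_numeric_vector(trait, "trait", n)
  set.seed(.seed_from(seed, 5L))
  Y <- vapply(seq_len(n_perm), function(i) sample(trait), numeric(n))
  lod <- .lod_matrix(Y, .geno_numeric(genotypes))
  maxlod <- apply(lod, 2, max, na.rm = TRUE)
  sorted <- sort(maxlod)
  sorted[ceiling((1 - alpha) * n_perm)]
}

#' LOD support interval on one chromosome
#'
#' The smallest contiguous scanned range containing the chromosome peak
#' such that every scanned position outside it (on that chromosome) has
#' LOD < peak - drop; endpoints are then extended to the nearest flanking
#' scanned positions.
#'
#' @param scan A `scan_result`.
#' @param chrom Chromosome to summarize (default: the peak chromosome).
#' @param drop LOD drop defining the interval (default 1.5).
#' @return A `support_interval` list: chrom, lo_Mb, hi_Mb, peak_Mb,
#'   peak_lod, drop.
#' @export
lod_support_interval <- function(scan, chrom = NULL, drop = 1.5) {
  if (is.null(chrom)) chrom <- attr(scan, "peak")$chrom
  sub <- scan[scan$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0) .stopf("chromosome %s not present in scan", chrom)
  pk <- which.max(sub$lod)
  keep <- which(sub$lod >= sub$lod[pk] - drop)
  lo_i <- max(min(keep) - 1L, 1L)
  hi_i <- min(max(keep) + 1L, nrow(sub))
  structure(list(chrom = chrom, lo_Mb = sub$pos_Mb[lo_i],
                 hi_Mb = sub$pos_Mb[hi_i], peak_Mb = sub$pos_Mb[pk],
                 peak_lod = sub$lod[pk], drop = drop),
            class = "support_interval")
}

.intervals_overlap <- function(a, b) {
  !is.null(a) && !is.null(b) &&
    as.character(a$chrom) == as.character(b$chrom) &&
    a$lo_Mb <= b$hi_Mb && b$lo_Mb <= a$hi_Mb
}

#' @export
print.scan_result <- function(x, ...) {
  pk <- attr(x, "peak")
  if (is.null(pk)) {
    i <- which.max(x$lod)
    pk <- list(chrom = x$chrom[i], Mb = x$pos_Mb[i], lod = x$lod[i])
  }
  cat(sprintf("genome scan: %d positions, peak LOD %.2f at chr%s:%.2f Mb\n",
              nrow(x), pk$lod, pk$chrom, pk$Mb))
  invisible(x)
}
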