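# Shared fixtures and independent oracles. Fixtures are built in code and
# memoized per session; test-scale panels use 19 autosomes x 16 markers
# (~6.6 Mb spacing) and 400 genes.

.fx_env <- new.env(parent = emptyenv())

fx_map <- function(markers_per_chrom = 16) {
  key <- paste0("map", markers_per_chrom)
  if (is.null(.fx_env[[key]]))
    .fx_env[[key]] <- make_marker_map(markers_per_chrom = markers_per_chrom)
  .fx_env[[key]]
}

fx_panel <- function(seed = 7) {
  key <- paste0("panel", seed)
  if (is.null(.fx_env[[key]]))
    .fx_env[[key]] <- simulate_ris_genotypes(24, fx_map(), seed = seed)
  .fx_env[[key]]
}

# One fully simulated study: panel + expression + phenotype.
fx_study <- function(seed = 7, n_genes = 400) {
  key <- paste0("study", seed, "_", n_genes)
  if (is.null(.fx_env[[key]])) {
    geno <- fx_panel(seed)
    des <- default_design(fx_map(), n_genes = n_genes)
    sim <- suppressMessages(simulate_expression(geno, des, seed = seed))
    ph <- simulate_phenotype(geno, sim$truth, heritability = 0.5, seed = seed)
    .fx_env[[key]] <- list(geno = geno, sim = sim, ph = ph, design = des)
  }
  .fx_env[[key]]
}

# Hand-built tiny panel from explicit A/B codes (strains x markers).
make_panel <- function(codes, chrom, pos_Mb, pos_cM = pos_Mb) {
  stopifnot(ncol(codes) == length(chrom))
  map <- data.frame(marker_id = paste0("m", seq_along(chrom)), chrom = chrom,
                    pos_cM = pos_cM, pos_Mb = pos_Mb, stringsAsFactors = FALSE)
  class(map) <- c("marker_map", "data.frame")
  strain_ids <- sprintf("S%02d", seq_len(nrow(codes)))
  dimnames(codes) <- list(strain_ids, map$marker_id)
  structure(list(strain_ids = strain_ids, map = map, codes = codes),
            class = "ris_genotypes")
}

# --- independent oracles -------------------------------------------------

# LOD by explicit least squares at one marker.
oracle_lod <- function(trait, x, covariate = NULL) {
  n <- length(trait)
  if (is.null(covariate)) {
    null_rss <- sum(stats::resid(stats::lm(trait ~ 1))^2)
    full_rss <- sum(stats::resid(stats::lm(trait ~ x))^2)
  } else {
    null_rss <- sum(stats::resid(stats::lm(trait ~ covariate))^2)
    full_rss <- sum(stats::resid(stats::lm(trait ~ covariate + x))^2)
  }
  (n / 2) * log10(null_rss / full_rss)
}

# TOM by triple loop.
oracle_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) s <- s + a[i, u] * a[u, j]
    tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# Support interval by brute force over contiguous windows containing the peak.
oracle_support <- function(pos, lod, drop = 1.5) {
  pk <- which.max(lod)
  best <- NULL
  for (lo in 1:pk) for (hi in pk:length(lod)) {
    outside <- setdiff(seq_along(lod), lo:hi)
    if (all(lod[outside] < lod[pk] - drop)) {
      if (is.null(best) || (hi - lo) < (best[2] - best[1])) best <- c(lo, hi)
    }
  }
  c(pos[max(best[1] - 1, 1)], pos[min(best[2] + 1, length(lod))])
}

# One-way ANOVA + Tukey HSD from textbook sums of squares.
oracle_anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  gm <- tapply(values, groups, mean)
  ni <- tabulate(groups)
  ssb <- sum(ni * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  dfb <- k - 1; dfw <- n - k
  f <- (ssb / dfb) / (ssw / dfw)
  p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  mse <- ssw / dfw
  pairs <- utils::combn(levels(groups), 2)
  tk <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(mse / 2 * (1 / ni[which(levels(groups) == i)] +
                            1 / ni[which(levels(groups) == j)]))
    q <- abs(gm[i] - gm[j]) / se
    stats::ptukey(q, k, dfw, lower.tail = FALSE)
  })
  list(anova_p = p, tukey_p = tk,
       comparison = apply(pairs, 2, function(pr) paste(pr[2], pr[1], sep = "-")))
}

# Prediction strength by explicit pair enumeration.
oracle_prediction_strength <- function(ref, alt) {
  alt <- alt[names(ref)]
  mods <- names(which(table(ref) >= 2))
  ps <- sapply(mods, function(m) {
    idx <- which(ref == m)
    prs <- utils::combn(idx, 2)
    mean(apply(prs, 2, function(p) alt[p[1]] == alt[p[2]]))
  })
  ps
}

adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab)); si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab))); n2 <- comb2(sum(tab))
  (sij - si * sj / n2) / ((si + sj) / 2 - si * sj / n2)
}
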