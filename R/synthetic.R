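# Synthetic RIS panels with a planted chromosome-domain-driven module.
#
# The generator emulates the statistical geometry of a two-parent mouse RIS
# expression-genetics study: 24 inbred strains genotyped at biallelic
# markers on 19 autosomes, strain-level expression for thousands of genes,
# one genomic domain whose local genotypes drive a co-expressed cluster of
# cis genes plus trans satellites and the phenotype, background modules
# driven by non-genetic or trans-acting factors, and a structural-variant
# density gradient centered on the domain.

#' Build an evenly spaced autosomal marker map
#'
#' Markers are laid out at constant physical spacing on each autosome, with
#' genetic positions obtained from a constant cM/Mb expansion factor
#' (default 0.55, close to the genome-wide mouse average).
#'
#' @param n_chrom Number of autosomes (default 19, mouse).
#' @param markers_per_chrom Markers per chromosome.
#' @param chrom_length_Mb Physical length of each chromosome in Mb.
#' @param cM_per_Mb Genetic-to-physical expansion factor.
#' @return A `marker_map` data.frame with columns `marker_id`, `chrom`
#'   (integer), `pos_cM`, `pos_Mb`.
#' @export
make_marker_map <- function(n_chrom = 19, markers_per_chrom = 32,
                            chrom_length_Mb = 100, cM_per_Mb = 0.55) {
  stopifnot(n_chrom >= 1, markers_per_chrom >= 2)
  maps <- lapply(seq_len(n_chrom), function(ch) {
    pos <- seq(1, chrom_length_Mb, length.out = markers_per_chrom)
    data.frame(
      marker_id = sprintf("c%02d.m%02d", ch, seq_len(markers_per_chrom)),
      chrom = ch,
      pos_cM = pos * cM_per_Mb,
      pos_Mb = pos,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  class(map) <- c("marker_map", "data.frame")
  map
}

.validate_map <- function(map) {
  need <- c("marker_id", "chrom", "pos_cM", "pos_Mb")
  if (!all(need %in% names(map))) .stopf("marker map must have columns %s",
                                         paste(need, collapse = ", "))
  if (anyDuplicated(map$marker_id)) .stopf("duplicate marker ids in map")
  if (any(map$pos_Mb < 0)) .stopf("invalid map: negative physical position")
  for (ch in unique(map$chrom)) {
    p <- map$pos_cM[map$chrom == ch]
    if (any(diff(p) < 0))
      .stopf("invalid map: non-increasing positions on chromosome %s", ch)
  }
  invisible(map)
}

#' Simulate genotypes of a recombinant inbred strain panel
#'
#' Each strain's genotype along a chromosome is a two-state Markov chain
#' over the homozygous codes A/B. The per-interval switch probability uses
#' the RIS map expansion for sib-mated lines, R = 4r / (1 + 6r), with the
#' single-meiosis recombination fraction r derived from the cM spacing via
#' the Haldane map function r = (1 - exp(-2d/100)) / 2. The first marker of
#' every chromosome is A or B with probability 1/2 (balanced reciprocal
#' cross). Selfed-line expansion R = 2r/(1+2r) is available for panels bred
#' by selfing.
#'
#' @param n_strains Number of strains (default 24).
#' @param map A `marker_map` (see [make_marker_map()]).
#' @param seed Integer seed; identical seeds give identical panels.
#' @param scheme Breeding scheme for map expansion, "sib" (default) or
#'   "selfing".
#' @return A `ris_genotypes` list: `strain_ids`, `map`, `codes`
#'   (strains x markers character matrix of "A"/"B").
#' @export
simulate_ris_genotypes <- function(n_strains = 24, map = make_marker_map(),
                                   seed = 1, scheme = c("sib", "selfing")) {
  scheme <- match.arg(scheme)
  if (n_strains < 2) .stopf("need at least 2 strains")
  .validate_map(map)
  set.seed(.seed_from(seed))
  strain_ids <- sprintf("S%02d", seq_len(n_strains))
  codes <- matrix("A", n_strains, nrow(map),
                  dimnames = list(strain_ids, map$marker_id))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    d <- diff(map$pos_cM[idx])
    r <- (1 - exp(-2 * d / 100)) / 2
    R <- if (scheme == "sib") 4 * r / (1 + 6 * r) else 2 * r / (1 + 2 * r)
    for (s in seq_len(n_strains)) {
      g <- integer(length(idx))
      g[1] <- stats::rbinom(1, 1, 0.5)
      if (length(idx) > 1) {
        flips <- stats::rbinom(length(R), 1, R)
        for (j in seq_along(R)) g[j + 1] <- if (flips[j]) 1L - g[j] else g[j]
      }
      codes[s, idx] <- c("A", "B")[g + 1L]
    }
  }
  structure(list(strain_ids = strain_ids, map = map, codes = codes),
            class = "ris_genotypes")
}

#' Default design for the planted-domain expression simulation
#'
#' The design emulates the structure recovered from real RIS heart data:
#' one chromosome domain whose tightly linked local genotypes drive a
#' physical cluster of strongly cis-regulated genes plus a handful of
#' trans-regulated satellites on other chromosomes (together the planted
#' CDD module), a few "genetic non-CDD" background modules driven by a
#' single trans locus with members scattered genome wide, several
#' non-genetic background modules driven by shared latent factors, and
#' pure-noise genes. Effect sizes default to values giving per-gene
#' genetic R^2 around 0.85 at the driving marker (strain-mean expression
#' of strongly cis-regulated genes is highly heritable; see the vignette).
#'
#' @param map A `marker_map`.
#' @param n_genes Total genes simulated.
#' @param domain_chrom,domain_center_Mb,domain_span_Mb Planted domain.
#' @param n_cis,n_trans Planted cluster sizes.
#' @param n_weak Weakly coupled domain-module members scattered genome
#'   wide (the published domain module is dominated numerically by such
#'   genes: a ~48-gene module with an 11-gene cis core, 5 trans satellites
#'   and ~32 weakly connected members).
#' @param cis_effect Vector (recycled) of cis genotype effects `a_g`.
#' @param cis_loading Loading of cis genes on the shared domain factor.
#' @param trans_effect,trans_loading Same for trans satellites.
#' @param weak_effect,weak_loading,weak_noise_sd Same for weak members
#'   (effects below the eQTL detection threshold by design).
#' @param noise_sd Residual SD for planted genes.
#' @param n_genetic_bg,n_nongenetic_bg Background module counts.
#' @param bg_module_size Genes per background module.
#' @param bg_loading Background factor loading (noise SD makes within-module
#'   correlations ~0.8).
#' @return A design list consumed by [simulate_expression()].
#' @export
default_design <- function(map = make_marker_map(), n_genes = 2000,
                           domain_chrom = 13, domain_center_Mb = 62,
                           domain_span_Mb = 6,
                           n_cis = 8, n_trans = 5, n_weak = 20,
                           cis_effect = seq(2.2, 3.0, length.out = 8),
                           cis_loading = 0.4,
                           trans_effect = seq(1.6, 2.0, length.out = 5),
                           trans_loading = 0.4,
                           weak_effect = 0.9, weak_loading = 0.5,
                           weak_noise_sd = 0.7,
                           noise_sd = 0.35,
                           n_genetic_bg = 2, n_nongenetic_bg = 3,
                           bg_module_size = 45, bg_loading = 0.9,
                           bg_noise_sd = 0.45) {
  list(map = map, n_genes = n_genes, domain_chrom = domain_chrom,
       domain_center_Mb = domain_center_Mb, domain_span_Mb = domain_span_Mb,
       n_cis = n_cis, n_trans = n_trans, n_weak = n_weak,
       cis_effect = cis_effect, cis_loading = cis_loading,
       trans_effect = trans_effect, trans_loading = trans_loading,
       weak_effect = weak_effect, weak_loading = weak_loading,
       weak_noise_sd = weak_noise_sd,
       noise_sd = noise_sd,
       n_genetic_bg = n_genetic_bg, n_nongenetic_bg = n_nongenetic_bg,
       bg_module_size = bg_module_size, bg_loading = bg_loading,
       bg_noise_sd = bg_noise_sd)
}

#' Simulate strain-level expression with a planted domain module
#'
#' Cis genes are placed inside the declared domain interval, each jittered
#' around a domain marker, and modeled as
#' `mu + a_g * x_g + lambda_g * f + eps`, where `x_g` is the 0/1 coding of
#' the genotype at the gene's local domain marker (tightly linked to the
#' domain locus), `f` a shared latent co-regulation factor and `eps` iid
#' Gaussian noise. Trans satellites sit on other chromosomes, loaded on the
#' domain-center genotype and on `f` with smaller effects. Genetic
#' background modules share a trans locus elsewhere in the genome;
#' non-genetic modules share a latent factor independent of genotype;
#' remaining genes are pure noise.
#'
#' @param genotypes A `ris_genotypes` panel.
#' @param design A design list from [default_design()].
#' @param seed Integer seed.
#' @return List with `expr` (strains x genes matrix), `annotation`
#'   (data.frame gene_id, chrom, start_Mb) and `truth` (a `synthetic_truth`
#'   list: domain locus/interval, planted gene ids, module map, driver
#'   markers).
#' @export
simulate_expression <- function(genotypes, design = default_design(genotypes$map),
                                seed = 1) {
  map <- genotypes$map
  n <- length(genotypes$strain_ids)
  X <- .geno_numeric(genotypes)
  lo <- design$domain_center_Mb - design$domain_span_Mb / 2
  hi <- design$domain_center_Mb + design$domain_span_Mb / 2
  dom_idx <- which(map$chrom == design$domain_chrom &
                     map$pos_Mb >= lo & map$pos_Mb <= hi)
  if (length(dom_idx) == 0)
    .stopf("invalid design: no markers inside the domain interval [%g, %g] Mb on chromosome %s",
           lo, hi, design$domain_chrom)
  stopifnot(design$n_cis >= 1, design$noise_sd >= 0)
  set.seed(.seed_from(seed, 1L))

  center_idx <- dom_idx[which.min(abs(map$pos_Mb[dom_idx] - design$domain_center_Mb))]
  x_center <- X[, center_idx]

  n_bg <- design$n_genetic_bg + design$n_nongenetic_bg
  n_planted <- design$n_cis + design$n_trans + design$n_weak +
    n_bg * design$bg_module_size
  if (design$n_genes < n_planted)
    .stopf("n_genes (%d) smaller than planted gene count (%d)",
           design$n_genes, n_planted)

  gene_id <- sprintf("g%04d", seq_len(design$n_genes))
  expr <- matrix(0, n, design$n_genes,
                 dimnames = list(genotypes$strain_ids, gene_id))
  chrom <- integer(design$n_genes)
  start <- numeric(design$n_genes)
  module <- rep(NA_character_, design$n_genes)

  f <- stats::rnorm(n)                       # shared domain factor
  a_cis <- rep_len(design$cis_effect, design$n_cis)
  a_trans <- rep_len(design$trans_effect, design$n_trans)
  chroms <- unique(map$chrom)
  glen <- max(map$pos_Mb)

  g <- 0L
  # cis cluster: genes assigned round-robin to domain markers, start jittered
  # within +/-0.5 Mb so each gene passes the 1 Mb cis rule at its own marker
  cis_markers <- rep_len(dom_idx, design$n_cis)
  for (k in seq_len(design$n_cis)) {
    g <- g + 1L
    mk <- cis_markers[k]
    chrom[g] <- design$domain_chrom
    start[g] <- min(max(map$pos_Mb[mk] + stats::runif(1, -0.5, 0.5), lo), hi)
    expr[, g] <- a_cis[k] * X[, mk] + design$cis_loading * f +
      stats::rnorm(n, 0, design$noise_sd)
    module[g] <- "domain"
  }
  cis_ids <- gene_id[seq_len(design$n_cis)]

  # trans satellites elsewhere in the genome, driven by the domain center
  other <- setdiff(chroms, design$domain_chrom)
  for (k in seq_len(design$n_trans)) {
    g <- g + 1L
    chrom[g] <- other[1 + (k - 1) %% length(other)]
    start[g] <- stats::runif(1, 1, glen)
    expr[, g] <- a_trans[k] * x_center + design$trans_loading * f +
      stats::rnorm(n, 0, design$noise_sd)
    module[g] <- "domain"
  }
  trans_ids <- gene_id[design$n_cis + seq_len(design$n_trans)]

  # weakly coupled module members: sub-threshold genetic effect plus the
  # shared factor, scattered genome wide (the bulk of a real domain module)
  if (design$n_weak > 0) {
    for (k in seq_len(design$n_weak)) {
      g <- g + 1L
      chrom[g] <- chroms[1 + (g %% length(chroms))]
      start[g] <- stats::runif(1, 1, glen)
      expr[, g] <- design$weak_effect * x_center + design$weak_loading * f +
        stats::rnorm(n, 0, design$weak_noise_sd)
      module[g] <- "domain"
    }
  }

  bg_map <- character(0)
  bg_drivers <- integer(0)
  for (m in seq_len(n_bg)) {
    genetic <- m <= design$n_genetic_bg
    label <- sprintf("bg%02d", m)
    if (genetic) {
      # trans-acting driver far from the planted domain
      cand <- which(map$chrom != design$domain_chrom)
      drv <- cand[1 + ((m * 97) %% length(cand))]
      factor_m <- 1.2 * X[, drv] + 0.6 * stats::rnorm(n)
      bg_drivers <- c(bg_drivers, drv)
    } else {
      factor_m <- stats::rnorm(n)
      bg_drivers <- c(bg_drivers, NA_integer_)
    }
    for (k in seq_len(design$bg_module_size)) {
      g <- g + 1L
      chrom[g] <- chroms[1 + (g %% length(chroms))]
      start[g] <- stats::runif(1, 1, glen)
      expr[, g] <- design$bg_loading * factor_m +
        stats::rnorm(n, 0, design$bg_noise_sd)
      module[g] <- label
    }
    bg_map <- c(bg_map, label)
  }

  if (g < design$n_genes) {
    rest <- (g + 1L):design$n_genes
    chrom[rest] <- chroms[1 + (rest %% length(chroms))]
    start[rest] <- stats::runif(length(rest), 1, glen)
    expr[, rest] <- stats::rnorm(n * length(rest))
  }

  annotation <- data.frame(gene_id = gene_id, chrom = chrom,
                           start_Mb = start, stringsAsFactors = FALSE)
  truth <- structure(list(
    domain_locus = list(chrom = design$domain_chrom,
                        Mb = map$pos_Mb[center_idx]),
    domain_interval = c(lo = lo, hi = hi),
    domain_marker = map$marker_id[center_idx],
    cis_gene_ids = cis_ids,
    trans_gene_ids = trans_ids,
    cis_markers = map$marker_id[cis_markers],
    background_module_map = stats::setNames(module[!is.na(module)],
                                            gene_id[!is.na(module)]),
    genetic_bg_labels = bg_map[seq_len(design$n_genetic_bg)],
    bg_driver_markers = map$marker_id[bg_drivers],
    phenotype_effect = NA_real_, heritability = NA_real_
  ), class = "synthetic_truth")
  list(expr = expr, annotation = annotation, truth = truth)
}

#' Simulate a phenotype driven by the planted domain locus
#'
#' phenotype = b * x + e, with x the 0/1 coding at the domain-center marker
#' and the noise variance set from the realized genetic variance so that
#' Var(b x) / Var(total) equals the requested heritability.
#'
#' @param genotypes A `ris_genotypes` panel.
#' @param truth A `synthetic_truth` from [simulate_expression()].
#' @param heritability Fraction of phenotype variance explained by the
#'   domain genotype, in (0, 1).
#' @param effect Genotype effect b (default 1).
#' @param seed Integer seed.
#' @return Named numeric vector over strains; attributes record the
#'   realized parameters.
#' @export
simulate_phenotype <- function(genotypes, truth, heritability = 0.5,
                               effect = 1, seed = 1) {
  if (!(heritability > 0 && heritability < 1))
    .stopf("heritability must be in (0, 1)")
  set.seed(.seed_from(seed, 2L))
  x <- .geno_numeric(genotypes)[, truth$domain_marker]
  vg <- stats::var(effect * x)
  if (vg == 0) .stopf("domain marker is monomorphic in this panel")
  e_var <- vg * (1 - heritability) / heritability
  e <- stats::rnorm(length(x))
  e <- stats::resid(stats::lm(e ~ x))    # orthogonal to the genotype
  e <- e * sqrt(e_var / stats::var(e))   # realized variance ratio is exact
  y <- effect * x + e
  names(y) <- genotypes$strain_ids
  attr(y, "effect") <- effect
  attr(y, "heritability") <- heritability
  y
}

#' Simulate a structural-variant track with a density gradient
#'
#' Variant positions follow an inhomogeneous Poisson process with intensity
#' `background_rate + peak_height * exp(-(d / width)^2 / 2)` per Mb, where
#' d is the distance to the gradient center; off-center chromosomes carry
#' the homogeneous background only.
#'
#' @param map A `marker_map` providing chromosome extents.
#' @param center List/vector with `chrom` and `Mb` for the gradient peak.
#' @param peak_height Added intensity at the center (variants per Mb).
#' @param width Gaussian decay scale in Mb.
#' @param background_rate Homogeneous intensity (variants per Mb).
#' @param kind Track label, "indel" or "SINE".
#' @param seed Integer seed.
#' @return A `variant_track` data.frame (chrom, pos_Mb, kind), sorted.
#' @export
simulate_variant_track <- function(map, center, peak_height = 10, width = 6,
                                   background_rate = 5,
                                   kind = c("indel", "SINE"), seed = 1) {
  kind <- match.arg(kind)
  if (peak_height < 0 || background_rate < 0 || width <= 0)
    .stopf("rates must be >= 0 and width > 0")
  set.seed(.seed_from(seed, 3L))
  out <- list()
  for (ch in unique(map$chrom)) {
    len <- max(map$pos_Mb[map$chrom == ch])
    n_bg <- stats::rpois(1, background_rate * len)
    pos <- stats::runif(n_bg, 0, len)
    if (!is.null(center) && ch == center$chrom && peak_height > 0) {
      # thinning of a dominating homogeneous process for the bump
      n_cand <- stats::rpois(1, peak_height * len)
      cand <- stats::runif(n_cand, 0, len)
      keep <- stats::runif(n_cand) < exp(-((cand - center$Mb) / width)^2 / 2)
      pos <- c(pos, cand[keep])
    }
    if (length(pos))
      out[[length(out) + 1L]] <- data.frame(chrom = ch, pos_Mb = sort(pos))
  }
  track <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = integer(0), pos_Mb = numeric(0))
  track$kind <- rep(kind, nrow(track))
  rownames(track) <- NULL
  class(track) <- c("variant_track", "data.frame")
  track
}

#' Generate labeled gene/trait/genotype triads for causality validation
#'
#' Produces a causal chain (genotype -> expression -> phenotype) or a
#' reactive chain (genotype -> phenotype -> expression) at a given locus,
#' for testing reciprocal covariate scans against known direction. The
#' default downstream coupling differs by model: a causal gene tolerates a
#' moderately heritable downstream phenotype (link 0.4), whereas a
#' reactive gene must be strongly coupled to the phenotype for its eQTL to
#' be detectable at all at RIS panel sizes (link 0.75) -- both sit inside
#' the regime the reciprocal-scan procedure claims to resolve.
#'
#' @param genotypes A `ris_genotypes` panel.
#' @param marker_id Driving marker.
#' @param model "causal" or "reactive".
#' @param qtl_effect Genotype effect on the directly driven trait.
#' @param link Coupling of the downstream trait to its driver, in (0,1);
#'   squared correlation between the two traits. Default 0.4 for causal,
#'   0.75 for reactive chains.
#' @param seed Integer seed.
#' @return List with `gene`, `trait`, `model`.
#' @export
simulate_triad_chain <- function(genotypes, marker_id,
                                 model = c("causal", "reactive"),
                                 qtl_effect = 3.5, link = NULL, seed = 1) {
  model <- match.arg(model)
  if (is.null(link)) link <- if (model == "causal") 0.4 else 0.75
  stopifnot(link > 0, link < 1)
  set.seed(.seed_from(seed, 4L))
  x <- .geno_numeric(genotypes)[, marker_id]
  n <- length(x)
  driven <- qtl_effect * x + stats::rnorm(n, 0, 0.4)
  down_sd <- sqrt(stats::var(driven) * (1 - link) / link)
  downstream <- driven + stats::rnorm(n, 0, down_sd)
  if (model == "causal") {
    list(gene = stats::setNames(driven, genotypes$strain_ids),
         trait = stats::setNames(downstream, genotypes$strain_ids),
         model = model)
  } else {
    list(gene = stats::setNames(downstream, genotypes$strain_ids),
         trait = stats::setNames(driven, genotypes$strain_ids),
         model = model)
  }
}
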