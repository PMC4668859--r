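# Binned abundance profiles of structural variants (indels, polymorphic
# SINEs) around mQTL peaks, a random-site background, and group
# comparison of abundances near the center.

#' Binned variant abundance around a center position
#'
#' Counts track records per half-open offset bin [lo, hi) relative to the
#' center, tiling [-extent, +extent). Bins extending past the chromosome
#' ends are flagged as truncated.
#'
#' @param track A `variant_track` data.frame (chrom, pos_Mb, kind).
#' @param center List/row with `chrom` and `Mb`.
#' @param bin_width_Mb Bin width (default 2).
#' @param extent_Mb Half-extent of the profile (default 18; must be a
#'   multiple of the bin width).
#' @param kind Optional filter on the track's `kind` column.
#' @param chrom_length_Mb Optional chromosome length for truncation flags.
#' @return An `abundance_profile` data.frame: offset_lo, offset_hi, count,
#'   truncated; attributes `center`, `bin_width_Mb`, `extent_Mb`.
#' @export
binned_profile <- function(track, center, bin_width_Mb = 2, extent_Mb = 18,
                           kind = NULL, chrom_length_Mb = NULL) {
  if (extent_Mb %% bin_width_Mb != 0)
    .stopf("extent (%g) must be a multiple of the bin width (%g)",
           extent_Mb, bin_width_Mb)
  if (!is.null(kind)) track <- track[track$kind == kind, , drop = FALSE]
  sub <- track[as.character(track$chrom) == as.character(center$chrom), ,
               drop = FALSE]
  breaks <- seq(-extent_Mb, extent_Mb, by = bin_width_Mb)
  off <- sub$pos_Mb - center$Mb
  counts <- vapply(seq_len(length(breaks) - 1), function(i) {
    sum(off >= breaks[i] & off < breaks[i + 1])
  }, numeric(1))
  truncated <- rep(FALSE, length(counts))
  if (!is.null(chrom_length_Mb)) {
    lo_abs <- center$Mb + breaks[-length(breaks)]
    hi_abs <- center$Mb + breaks[-1]
    truncated <- lo_abs < 0 | hi_abs > chrom_length_Mb
  }
  out <- data.frame(offset_lo = breaks[-length(breaks)],
                    offset_hi = breaks[-1], count = counts,
                    truncated = truncated)
  attr(out, "center") <- center
  attr(out, "bin_width_Mb") <- bin_width_Mb
  attr(out, "extent_Mb") <- extent_Mb
  class(out) <- c("abundance_profile", "data.frame")
  out
}

#' Background profiles around randomly selected genomic sites
#'
#' Draws `n_sites` positions uniformly from a supplied polymorphic-site
#' table, or uniformly over the mapped genome (chromosomes weighted by
#' length) when none is given, and computes an abundance profile at each.
#'
#' @param track A `variant_track`.
#' @param map A `marker_map` providing chromosome extents.
#' @param n_sites Number of background sites (default 500).
#' @param sites Optional data.frame (chrom, pos_Mb) of polymorphic sites
#'   to sample from.
#' @param seed Integer seed.
#' @param ... Passed to [binned_profile()].
#' @return List of `abundance_profile`s, one per site.
#' @export
random_background <- function(track, map, n_sites = 500, sites = NULL,
                              seed = 1, ...) {
  stopifnot(n_sites >= 1)
  set.seed(.seed_from(seed, 7L))
  if (!is.null(sites)) {
    pick <- sites[sample(nrow(sites), n_sites, replace = nrow(sites) < n_sites), ,
                  drop = FALSE]
  } else {
    lens <- tapply(map$pos_Mb, map$chrom, max)
    chs <- sample(names(lens), n_sites, replace = TRUE,
                  prob = lens / sum(lens))
    pick <- data.frame(chrom = chs,
                       pos_Mb = stats::runif(n_sites, 0, lens[chs]))
  }
  lapply(seq_len(n_sites), function(i) {
    binned_profile(track, list(chrom = pick$chrom[i], Mb = pick$pos_Mb[i]), ...)
  })
}

#' Compare variant abundance between groups of profiles
#'
#' For each profile the total count within a window centered on offset 0
#' (default 20 Mb wide) is taken as its abundance; groups are compared by
#' one-way ANOVA followed by Tukey HSD. Groups with fewer than two
#' profiles are excluded with a warning.
#'
#' @param groups Named list of profile lists (each an `abundance_profile`
#'   collection).
#' @param window_Mb Total window width around the center (default 20).
#' @return List: anova_p, tukey (data.frame comparison, diff, p_adj),
#'   group_means, values (long data.frame).
#' @export
compare_abundance <- function(groups, window_Mb = 20) {
  stopifnot(length(groups) >= 2)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) {
    warning("group(s) with fewer than 2 profiles excluded: ",
            paste(names(groups)[sizes < 2], collapse = ", "))
    groups <- groups[sizes >= 2]
  }
  if (length(groups) < 2) .stopf("need at least 2 groups with >= 2 profiles")
  half <- window_Mb / 2
  vals <- do.call(rbind, lapply(names(groups), function(g) {
    v <- vapply(groups[[g]], function(p) {
      sum(p$count[p$offset_lo >= -half & p$offset_hi <= half])
    }, numeric(1))
    data.frame(group = g, abundance = v, stringsAsFactors = FALSE)
  }))
  vals$group <- factor(vals$group)
  fit <- stats::aov(abundance ~ group, data = vals)
  an_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group
  list(anova_p = an_p,
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL),
       group_means = tapply(vals$abundance, vals$group, mean),
       values = vals)
}
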