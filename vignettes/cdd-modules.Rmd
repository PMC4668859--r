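---
title: "Chromosome-domain-driven co-expression modules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome-domain-driven co-expression modules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cddnet)
```

`cddnet` analyzes the joint genetic architecture of gene expression and a
quantitative phenotype in recombinant inbred strain (RIS) panels, with the
goal of detecting *chromosome-domain-driven* (CDD) co-expression modules:
clusters of co-expressed genes whose module QTL (mQTL) sits on the same
chromosome that contributes the plurality of the module's genes, typically
as a physically tight, highly connected cis-regulated core. This vignette
documents the statistical models, the tunable parameters, the synthetic
data the package uses for validation, and the design decisions taken where
the methodology left genuine choices.

## 1. Genome scans on RIS panels

RIS are fully inbred, so every strain is homozygous at every marker and
genotypes are coded 0/1 (A/B). Scans regress the trait on this coding at
each marker (marker regression; no pseudomarker imputation — genotypes are
fully informative and positions between markers are not scanned):

$$\mathrm{LOD}(m) = \frac{n}{2}\log_{10}\frac{RSS_0}{RSS_1},$$

with $RSS_1$ from `trait ~ genotype (+ covariate)` and $RSS_0$ from the
same model without genotype. $n$ is the number of **strains** (24 by
default): the mapped traits are strain means, not individual animals.
Markers with an empty genotype class are skipped with a notice.

Significance uses either the fixed threshold **LOD 3.3** (the pipeline
default, a standard genome-wide 5% criterion for panels of this shape) or
a permutation threshold: the $(1-\alpha)$ quantile of the genome-wide
maximum LOD over trait permutations. On the default synthetic panel the
empirical 95th percentile of the null genome-wide maximum is ≈ 3.4,
consistent with the fixed default. Two calibration caveats are built into
the tests: the permutation threshold conditions on the trait's empirical
value distribution, so at $n = 24$ it varies by roughly ±0.2 LOD between
traits; calibration is therefore assessed per trait (each null trait
against its own threshold), which the suite verifies to be within
Monte Carlo error of the nominal 5%.

**Support intervals** are 1.5-LOD intervals: the smallest contiguous run
of scanned positions containing the chromosome peak outside of which every
position is more than 1.5 LOD below the peak, extended to the nearest
flanking markers. A flat curve yields the whole chromosome.

## 2. eQTLs, c3-eQTLs and multiplicity control

Every gene's expression is scanned; each chromosome whose maximum LOD
reaches the threshold contributes one eQTL record (so a gene may have
several). A record is **cis** when its peak is within 1 Mb of the
annotated gene start (symmetric window, strand ignored), **trans**
otherwise. One subtlety of small panels: tightly linked markers can carry
*identical* genotype columns, making the peak location an exact tie; ties
are resolved toward the marker nearest the gene start (lowest position
otherwise), since the likelihood surface genuinely cannot distinguish the
tied positions.

**c3-eQTLs** are cis-eQTLs that (i) correlate with the phenotype after
multiplicity control and (ii) colocalize with the phenotype QTL (their
1.5-LOD intervals intersect on the same chromosome). The per-gene
statistic is $|r|$ (Pearson, gene expression vs phenotype). Family-wise
control uses **Westfall–Young step-down maxT**: for each trait
permutation the successive maxima over the ordered statistics are
recorded, and

$$p_g^{adj} = \frac{1 + \#\{\text{perm step-max} \ge |r_g|\}}{B + 1},$$

with monotonicity enforced down the ordering (a single-step variant is
available by flag). Adjusted p-values are converted to **q-values** with
the Storey π₀ smoothing estimator (λ grid 0.05–0.95, cubic smoothing
spline evaluated at λ = 0.95; with fewer than ~20 p-values, where the
spline is unstable, the most conservative tail estimate over λ ≥ 0.5 is
used instead). Genes with q ≤ 0.1 pass the correlation screen.

## 3. Causality triads

For a gene, a phenotype and a locus that share linkage, four scans are
run: phenotype ± gene as covariate, gene ± phenotype as covariate, with
LODs read at the *fixed* peak markers of the unconditional scans so that
drops are comparable across genes. The reported quantities are the drop
`lod_pheno − lod_pheno|gene` and the conditional eQTL LOD
`lod_expr|pheno`. The convenience call is:

* **reactive-leaning** — the gene had a detectable eQTL and conditioning
  on the phenotype pushes it below threshold;
* **causal-leaning** — the drop removes at least 50% of the phenotype LOD
  (configurable; the methodology gives no cutoff, so the labels are
  explicitly a convenience layer over the reported LODs) *and* the eQTL
  stays detectable given the phenotype;
* **undetermined** otherwise.

One property worth stating because it is often assumed away: drops can be
mildly **negative**. A covariate correlated with residual trait variance
lowers both models' RSS and can *raise* the conditional LOD — the same
effect composite interval mapping exploits. The tests assert the true
bounds (drop ≤ full LOD, conditional LODs ≥ 0), not a nonnegativity that
does not hold.

## 4. The co-expression network core

The network machinery is implemented from scratch:

* **Adjacency** $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$, unsigned by
  default (the era-standard choice; a signed transform is a flag), zero
  diagonal, so connectivity $k_i = \sum_j a_{ij}$ is a row sum.
* **β = 6 by default.** `pick_soft_threshold()` implements the
  scale-free-topology criterion (bin log₁₀ k, regress log₁₀ p(k) on
  log₁₀ k, signed R², smallest β reaching 0.8). On real transcriptomes
  this criterion typically selects a β near 6; on the synthetic generator
  it rarely reaches 0.8, because the planted structure (a handful of
  similar-sized modules plus noise) does not produce a scale-free hub
  tail — a known, documented gap between the generator and real data. The
  pipeline therefore takes β from `network_params()` and exposes the
  criterion as a diagnostic.
* **Topological overlap**
  $TOM_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$,
  $TOM_{ii}=1$; clustering uses the dissimilarity $1 - TOM$.
* **Module detection** is average-linkage hierarchical clustering with an
  adaptive branch cut — the "tree" variant of dynamic tree cutting, not
  the hybrid PAM-stage algorithm. Distinct modules join the dendrogram
  close to dissimilarity 1, so the cut is placed at an offset below the
  top merge, `max_h − (0.05 + 0.05·deep_split)·(max_h − min_h)`
  (deep_split ∈ 0–4, default 2). A height-quantile cut was rejected
  empirically: merge heights pile up near the top of TOM dendrograms, so
  quantile cuts land above the module/noise joins and absorb noise genes
  into modules. Branches of ≥ `min_cluster_size` genes (default 40)
  become modules, named by deterministic colors in size order; the rest
  are grey/unassigned.
* **Eigengenes** are unit-norm first principal components of the
  standardized module expression, signed to correlate non-negatively with
  the module mean profile. Modules whose eigengene dissimilarity
  $1 - \mathrm{cor}$ falls below `cut_height` (default 0.15) are merged
  iteratively, recomputing eigengenes after each merge.
* **Robustness diagnostics**: prediction strength (per reference cluster,
  the fraction of within-cluster pairs co-clustered in an alternative
  labeling — deliberately one-directional, so a single-cluster alternative
  scores 1) and top-connected retention (the share of each module's top
  20/40% most connected genes that stay in the single best-matching module
  when parameters change).

## 5. Module genetics and CDD classification

Each eigengene is genome-scanned at the same 3.3 threshold used for
eQTLs (the methodology names no separate module threshold). A module is
**non-genetic** without an mQTL; otherwise **CDD** iff its main mQTL's
chromosome equals its predominant chromosome (most member genes; ties
break toward the mQTL chromosome, logged); else **genetic non-CDD**.
Domain statistics per module: mean *pairwise* distance among
predominant-chromosome genes (read as pairwise, not span — the quantity
describes distance "between genes"), percentage of cis-eQTL genes, and
relative connectivity (mean k of predominant-chromosome genes over mean k
of the rest; undefined for single-chromosome modules). The chance
expectation for the predominant-chromosome count is
`module_size × chrom_genes / genome_genes` with an exact binomial tail
p-value — for a 48-gene module against an 808/20,369 chromosome this is
1.9 genes. Classes are compared per statistic by one-way ANOVA with Tukey
HSD (`stats::aov`/`TukeyHSD`; the test suite re-derives both from
textbook sums of squares and `ptukey`).

## 6. Structural-variant profiles

Variant abundance (indels and polymorphic SINEs share one engine with a
`kind` filter) is counted in half-open 2 Mb offset bins `[lo, hi)` tiling
±18 Mb around a center; boundary variants count once, and bins truncated
by chromosome ends are flagged. Backgrounds are profiles around sites
drawn uniformly from a supplied polymorphic-site list, or uniformly over
the mapped genome (length-weighted chromosomes) when none is given —
default 500 sites. Group comparison sums each profile within a 20 Mb
window centered on offset zero and applies ANOVA + Tukey.

## 7. What the synthetic generator emulates — and what it does not

The generator reproduces the *statistical geometry* the analysis assumes,
at two scales: production defaults (24 strains, 19 autosomes × 32 markers
≈ 600, 2,000 genes) and a test scale used throughout the suite and the
acceptance script (16 markers/chromosome ≈ 300, 400 genes) chosen so a
full pipeline run takes well under a second.

* **Genotypes**: per chromosome, a two-state Markov chain with switch
  probability $R = 4r/(1+6r)$ between adjacent markers (sib-mating map
  expansion — the breeding scheme of reciprocal-cross mouse RIS panels;
  a selfing variant is a flag), $r$ from the Haldane map function on the
  cM spacing, first allele fair.
* **The planted domain module** mirrors the published geometry of a
  trait-linked CDD module: a *cis core* (8 genes inside a 6 Mb domain,
  each driven by the genotype at its nearest domain marker — tight
  linkage makes these near-copies of the domain-locus genotype while
  keeping each gene's eQTL peak within 1 Mb of the gene, as a
  cis-regulated physical cluster behaves), 5 *trans satellites* on other
  chromosomes driven by the domain-center genotype, and 20 *weak members*
  scattered genome-wide with sub-threshold genetic effects. The weak
  group matters: real domain modules are numerically dominated by weakly
  connected members, and without them the relative-connectivity ratio of
  the domain core would be computed against strong satellites only.
  All three groups share a latent co-regulation factor.
* **Effect sizes** were fixed by forward calculation, not fitting:
  strongly cis-regulated strain-mean expression is highly heritable, so
  cis effects give per-gene genetic R² ≈ 0.85 (LOD ≈ 10 at n = 24), which
  puts gene–phenotype correlations near
  $\sqrt{R^2_{gene} \cdot h^2} \approx 0.65$ at the default phenotype
  heritability of 0.5 — the regime in which published c3-eQTL screens
  operate.
* **Phenotype**: $y = b x + e$ with $e$ orthogonalized against $x$ and
  scaled so the realized variance ratio equals the requested heritability
  exactly.
* **Triad chains** for causality validation are generated with asymmetric
  couplings (causal link 0.4, reactive link 0.75): at $n = 24$ and
  threshold 3.3 a *reactive* gene's eQTL is only detectable when the gene
  is strongly coupled to the phenotype, whereas a *causal* gene tolerates
  a weakly heritable downstream phenotype. Both sit inside the regime the
  reciprocal-scan procedure claims to resolve; outside it the correct
  call is "undetermined", which the procedure indeed returns.
* **Variant tracks** are inhomogeneous Poisson processes: homogeneous
  background plus a Gaussian-decay bump (monotone decreasing from the
  center) on the domain chromosome, sampled by thinning.

Not emulated: microarray probe-level effects, batch structure, real
haplotype sharing, a scale-free connectivity tail (see §4), or linkage
disequilibrium beyond the marker Markov chain. Passing recovery tests
therefore demonstrates the pipeline's correctness and power under the
assumed generative structure, not performance on any particular real
dataset.

## 8. Numerical choices and degenerate inputs

* Genotype coding A = 0, B = 1; effect signs are free.
* Coordinates are 1-based Mb floats everywhere; TSV interfaces carry
  units in `#` comment headers.
* Constant traits, constant genes, all-flagged probe sets, heritability
  outside (0,1), maps with non-increasing positions, asymmetric
  adjacency, and extents that are not bin multiples all raise immediate,
  specific errors; constant genes inside a network get zeroed
  correlations with a notice.
* RSS ratios are guarded by machine epsilon, LODs floored at 0; eigengene
  sign is fixed by the module mean profile; module color names come from
  a fixed palette in size order; tied drops rank lexicographically by
  gene id; tied main mQTLs resolve to the lower chromosome.
* Westfall–Young uses the add-one permutation estimator, so the smallest
  attainable adjusted p is $1/(B+1)$.

## 9. Known limitations

* Marker-resolution peaks: peak positions are marker positions, so
  support intervals are conservative by up to one marker spacing.
* The exact branch-cut semantics of the original dynamic tree cut are
  not reproduced label-for-label; recovery of planted structure, not
  parity with any specific implementation, is the validated property.
* The q-value π₀ estimator is unstable for very small families and falls
  back to a conservative tail estimate.
* With 24 strains the phenotype's genome-wide peak lands off the true
  chromosome in a few percent of simulations at h² = 0.5; downstream
  colocalization inherits those misses — visible as recovery rates
  slightly below 100% in the acceptance report.
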