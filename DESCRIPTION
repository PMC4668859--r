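Package: cddnet
Title: Chromosome-Domain-Driven Co-Expression Modules and eQTL Mapping in
    Recombinant Inbred Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of quantitative
    traits in recombinant inbred strain (RIS) panels through the joint
    analysis of genotypes, gene expression and phenotypes. Provides marker
    regression genome scans with LOD scores, permutation thresholds and
    1.5-LOD support intervals; genome-wide eQTL mapping with cis/trans
    classification and screening of c3-eQTLs (cis-eQTLs that colocalize
    with a phenotypic QTL and correlate with the phenotype) under
    Westfall-Young maxT multiplicity control; reciprocal covariate-scan
    causality triads; a from-scratch weighted gene co-expression network
    core (soft thresholding, topological overlap, dynamic branch cutting,
    eigengenes, module merging, robustness diagnostics); module QTL
    mapping with chromosome-domain-driven (CDD) module classification and
    domain statistics; binned structural-variant abundance profiles around
    mQTL peaks; and a synthetic-data generator that plants domain-driven
    modules with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
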