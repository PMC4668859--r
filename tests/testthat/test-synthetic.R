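# Synthetic RIS panels: Markov-chain genotypes, planted expression
# structure, phenotype heritability and variant gradients.

test_that("coincident markers give identical genotype columns and seeds reproduce", {
  map <- data.frame(marker_id = c("a", "b"), chrom = 1,
                    pos_cM = c(5, 5), pos_Mb = c(5, 5))
  class(map) <- c("marker_map", "data.frame")
  g <- simulate_ris_genotypes(50, map, seed = 3)
  expect_identical(g$codes[, "a"], g$codes[, "b"])

  g2 <- simulate_ris_genotypes(50, map, seed = 3)
  expect_identical(g$codes, g2$codes)
  g3 <- simulate_ris_genotypes(24, fx_map(), seed = 11)
  g4 <- simulate_ris_genotypes(24, fx_map(), seed = 11)
  expect_identical(g3$codes, g4$codes)
})

test_that("non-increasing map positions are rejected", {
  map <- data.frame(marker_id = c("a", "b"), chrom = 1,
                    pos_cM = c(10, 5), pos_Mb = c(10, 5))
  expect_error(simulate_ris_genotypes(10, map), "non-increasing")
})

test_that("adjacent-marker switch frequency matches the sib-mating RIS expansion", {
  # closed-form oracle: R = 4r/(1+6r), r from Haldane
  map <- data.frame(marker_id = c("a", "b"), chrom = 1,
                    pos_cM = c(0, 10), pos_Mb = c(0, 20))
  class(map) <- c("marker_map", "data.frame")
  n <- 10000
  g <- simulate_ris_genotypes(n, map, seed = 5)
  emp <- mean(g$codes[, 1] != g$codes[, 2])
  r <- (1 - exp(-0.2)) / 2
  R <- 4 * r / (1 + 6 * r)
  expect_lt(abs(emp - R), 3 * sqrt(R * (1 - R) / n))
})

test_that("recombination matches 4r/(1+6r) across 1-50 cM spacings and alleles are balanced", {
  for (d in c(1, 5, 20, 50)) {
    map <- data.frame(marker_id = c("a", "b"), chrom = 1,
                      pos_cM = c(0, d), pos_Mb = c(0, d * 2))
    class(map) <- c("marker_map", "data.frame")
    n <- 4000
    g <- simulate_ris_genotypes(n, map, seed = 40 + d)
    r <- (1 - exp(-2 * d / 100)) / 2
    R <- 4 * r / (1 + 6 * r)
    emp <- mean(g$codes[, 1] != g$codes[, 2])
    expect_lt(abs(emp - R), 3.5 * sqrt(R * (1 - R) / n))
    freq <- mean(g$codes == "B")
    expect_lt(abs(freq - 0.5), 3.5 * sqrt(0.25 / n))
  }
})

test_that("noise-free, factor-free cis genes are exact affine functions of their genotype", {
  geno <- fx_panel()
  des <- default_design(fx_map(), n_genes = 20, n_cis = 4, n_trans = 2,
                        n_weak = 0, cis_loading = 0, trans_loading = 0,
                        noise_sd = 0, n_genetic_bg = 0, n_nongenetic_bg = 0,
                        bg_module_size = 0)
  sim <- simulate_expression(geno, des, seed = 2)
  x <- (geno$codes == "B") * 1
  for (i in seq_along(sim$truth$cis_gene_ids)) {
    gid <- sim$truth$cis_gene_ids[i]
    xg <- x[, sim$truth$cis_markers[i]]
    fit <- stats::lm(sim$expr[, gid] ~ xg)
    expect_lt(sum(stats::resid(fit)^2), 1e-20)
  }
})

test_that("planted cis genes are more correlated with each other than with background", {
  st <- fx_study()
  cc <- stats::cor(st$sim$expr)
  cis <- st$sim$truth$cis_gene_ids
  bg <- setdiff(colnames(cc), names(st$sim$truth$background_module_map))
  within <- mean(abs(cc[cis, cis][upper.tri(diag(length(cis)))]))
  between <- mean(abs(cc[cis, bg]))
  expect_gt(within, between)
})

test_that("cis genes are annotated inside the declared domain interval", {
  st <- fx_study()
  ann <- st$sim$annotation
  iv <- st$sim$truth$domain_interval
  cis_ann <- ann[ann$gene_id %in% st$sim$truth$cis_gene_ids, ]
  expect_true(all(cis_ann$chrom == st$sim$truth$domain_locus$chrom))
  expect_true(all(cis_ann$start_Mb >= iv["lo"] & cis_ann$start_Mb <= iv["hi"]))
})

test_that("a design whose domain interval contains no markers is rejected", {
  geno <- fx_panel()
  des <- default_design(fx_map(), domain_center_Mb = 62, domain_span_Mb = 0.01)
  expect_error(simulate_expression(geno, des), "no markers inside")
})

test_that("phenotype heritability is honored and the h2 -> 1 limit separates genotype groups", {
  geno <- fx_panel()
  st <- fx_study()
  ph <- simulate_phenotype(geno, st$sim$truth, heritability = 0.999, seed = 4)
  x <- (geno$codes == "B")[, st$sim$truth$domain_marker]
  expect_gt(min(ph[x]), max(ph[!x]))  # perfect separation in the limit

  ph5 <- simulate_phenotype(geno, st$sim$truth, heritability = 0.5, seed = 4)
  xb <- x * 1
  expect_equal(stats::var(xb * attr(ph5, "effect")) / stats::var(ph5), 0.5,
               tolerance = 1e-6)
  expect_identical(ph5, simulate_phenotype(geno, st$sim$truth, 0.5, seed = 4))
  expect_error(simulate_phenotype(geno, st$sim$truth, heritability = 1.2),
               "heritability")
})

test_that("flat variant tracks are homogeneous Poisson and gradients concentrate mass", {
  map <- fx_map()
  counts <- replicate(60, {
    tr <- simulate_variant_track(map, center = NULL, peak_height = 0,
                                 background_rate = 3,
                                 seed = sample.int(1e6, 1))
    pr <- binned_profile(tr, list(chrom = 5, Mb = 50), bin_width_Mb = 2,
                         extent_Mb = 18)
    mean(pr$count)
  })
  expect_lt(abs(mean(counts) - 6), 3 * sqrt(6 / (60 * 18)))

  # background 0, very narrow gradient: everything inside the peak support
  tr <- simulate_variant_track(map, center = list(chrom = 5, Mb = 50),
                               peak_height = 20, width = 0.5,
                               background_rate = 0, seed = 9)
  expect_true(all(tr$chrom == 5))
  expect_true(all(abs(tr$pos_Mb - 50) < 5 * 0.5))

  expect_identical(
    simulate_variant_track(map, list(chrom = 5, Mb = 50), seed = 12),
    simulate_variant_track(map, list(chrom = 5, Mb = 50), seed = 12))
})

test_that("a fully null pipeline yields zero c3-eQTLs in almost all seeds", {
  map <- fx_map()
  hits <- 0
  n_seeds <- 30
  for (s in seq_len(n_seeds)) {
    geno <- simulate_ris_genotypes(24, map, seed = 600 + s)
    des <- default_design(map, n_genes = 150, cis_effect = 0, trans_effect = 0,
                          cis_loading = 0, trans_loading = 0,
                          n_genetic_bg = 0, n_nongenetic_bg = 0,
                          bg_module_size = 0)
    sim <- suppressMessages(simulate_expression(geno, des, seed = 600 + s))
    set.seed(600 + s)
    ph <- stats::setNames(stats::rnorm(24), geno$strain_ids)  # null phenotype
    eq <- map_all_eqtls(sim$expr, geno, sim$annotation)
    cis_genes <- unique(eq$gene_id[eq$cis])
    if (length(cis_genes) == 0) next
    corr <- correlate_with_trait_wy(sim$expr[, cis_genes, drop = FALSE], ph,
                                    n_perm = 500, seed = s)
    c3 <- select_c3(eq, corr, lod_support_interval(genome_scan(ph, geno)))
    hits <- hits + (sum(c3$c3) > 0)
  }
  expect_lte(hits / n_seeds, 0.05 + 2 * sqrt(0.05 * 0.95 / n_seeds))
})
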