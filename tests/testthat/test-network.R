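# Co-expression network core: adjacency, TOM, module detection, merging,
# eigengenes, prediction strength and retention.

test_that("adjacency matches the brute-force correlation oracle", {
  set.seed(71)
  expr <- matrix(stats::rnorm(24 * 30), 24, 30,
                 dimnames = list(NULL, paste0("g", 1:30)))
  a <- adjacency_matrix(expr, beta = 6)
  # two-pass correlation oracle
  for (i in c(1, 7, 18)) for (j in c(2, 15, 30)) {
    xi <- expr[, i] - mean(expr[, i]); xj <- expr[, j] - mean(expr[, j])
    r <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    expect_equal(a[i, j], abs(r)^6, tolerance = 1e-12)
  }
  expect_equal(unname(diag(a)), rep(0, 30))
  expect_true(isSymmetric(unname(a)))

  # beta = 1, correlation -0.5 gives weight 0.5; perfect pair gives 1
  u <- scale(c(1, 2, 3, 4, 5, 6))[, 1]
  v <- scale(stats::resid(stats::lm(c(2, 6, 1, 5, 3, 4) ~ u)))[, 1]
  w <- -0.5 * u + sqrt(1 - 0.25) * v
  e2 <- cbind(a = u, b = w, c = 2 * u + 1)
  a2 <- adjacency_matrix(e2, beta = 1)
  expect_equal(a2["a", "b"], 0.5, tolerance = 1e-12)
  expect_equal(a2["a", "c"], 1, tolerance = 1e-12)
})

test_that("constant genes are zeroed out of the adjacency with a notice", {
  set.seed(72)
  expr <- matrix(stats::rnorm(24 * 5), 24, 5,
                 dimnames = list(NULL, paste0("g", 1:5)))
  expr[, 3] <- 2
  expect_message(a <- adjacency_matrix(expr, beta = 2), "constant")
  expect_equal(unname(a[3, ]), rep(0, 5))
})

test_that("TOM handles the boundary cases and matches the triple-loop oracle", {
  # no edge, no shared neighbors -> 0
  a0 <- matrix(0, 4, 4); a0[1, 2] <- a0[2, 1] <- 1; a0[3, 4] <- a0[4, 3] <- 1
  t0 <- topological_overlap(a0)
  expect_equal(t0[1, 3], 0)

  # identical neighbor profiles plus a direct edge -> 1
  a1 <- matrix(0, 5, 5)
  a1[1, 2] <- a1[2, 1] <- 1
  for (u in 3:5) { a1[1, u] <- a1[u, 1] <- 1; a1[2, u] <- a1[u, 2] <- 1 }
  expect_equal(topological_overlap(a1)[1, 2], 1)

  set.seed(73)
  for (n in c(10, 30, 50)) {
    m <- matrix(stats::runif(n * n), n, n)
    a <- (m + t(m)) / 2
    diag(a) <- 0
    expect_lt(max(abs(topological_overlap(a) - oracle_tom(a))), 1e-12)
  }
  expect_error(topological_overlap(matrix(stats::runif(9), 3, 3)), "symmetric")
})

test_that("connectivity equals adjacency row sums exactly", {
  st <- fx_study()
  a <- adjacency_matrix(st$sim$expr[, 1:100], beta = 6)
  k <- connectivity(a)
  expect_identical(unname(k), unname(rowSums(a)))
})

test_that("two well-separated correlation blocks yield exactly two matching modules", {
  set.seed(74)
  n <- 24
  f1 <- stats::rnorm(n); f2 <- stats::rnorm(n)
  expr <- cbind(
    sapply(1:45, function(i) 0.9 * f1 + stats::rnorm(n, 0, 0.45)),
    sapply(1:45, function(i) 0.9 * f2 + stats::rnorm(n, 0, 0.45)))
  colnames(expr) <- paste0("g", 1:90)
  tom <- topological_overlap(adjacency_matrix(expr, 6))
  labels <- detect_modules(tom, network_params(min_cluster_size = 40))
  expect_equal(length(setdiff(unique(labels), "grey")), 2)
  expect_equal(length(unique(labels[1:45])), 1)
  expect_equal(length(unique(labels[46:90])), 1)
  expect_false(labels[1] == labels[46])
  # assigned modules form a partition disjoint from the unassigned pool
  expect_equal(sum(table(labels)), 90)
})

test_that("module detection defaults to 40-gene minimum and warns on tiny inputs", {
  expect_equal(formals(network_params)$min_cluster_size, 40)
  expect_equal(formals(network_params)$beta, 6)
  set.seed(75)
  expr <- matrix(stats::rnorm(24 * 10), 24, 10,
                 dimnames = list(NULL, paste0("g", 1:10)))
  tom <- topological_overlap(adjacency_matrix(expr, 6))
  expect_warning(labels <- detect_modules(tom, network_params()), "unassigned")
  expect_true(all(labels == "grey"))
})

test_that("planted modules are recovered with high adjusted Rand index", {
  st <- fx_study()
  net <- suppressMessages(build_network(st$sim$expr,
                                        network_params(min_cluster_size = 10)))
  truth <- st$sim$truth$background_module_map
  ari <- adjusted_rand(truth, net$labels[names(truth)])
  expect_gte(ari, 0.9)
  # within-module TOM exceeds between-module TOM for the planted domain
  dom <- names(truth)[truth == "domain"]
  other <- setdiff(colnames(net$tom), dom)
  within <- mean(net$tom[dom, dom][upper.tri(diag(length(dom)))])
  between <- mean(net$tom[dom, other])
  expect_gt(within, between)
})

test_that("module merging respects the cut height", {
  set.seed(76)
  n <- 24
  f <- stats::rnorm(n)
  # two modules from the same factor: eigengene dissimilarity is small
  expr <- cbind(
    sapply(1:12, function(i) f + stats::rnorm(n, 0, 0.2)),
    sapply(1:12, function(i) f + stats::rnorm(n, 0, 0.2)),
    sapply(1:12, function(i) stats::rnorm(n)))
  colnames(expr) <- paste0("g", 1:36)
  labels <- stats::setNames(rep(c("blue", "red", "green"), each = 12),
                            colnames(expr))
  E <- module_eigengenes(expr, labels)
  d <- 1 - stats::cor(E[, "blue"], E[, "red"])

  expect_identical(merge_close_modules(expr, labels, cut_height = 0), labels)
  merged <- merge_close_modules(expr, labels, cut_height = d + 0.05)
  expect_equal(length(setdiff(unique(merged), "grey")), 2)
  expect_equal(length(unique(merged[1:24])), 1)
  kept <- merge_close_modules(expr, labels, cut_height = d * 0.5)
  expect_equal(length(setdiff(unique(kept), "grey")), 3)
})

test_that("eigengenes match an independent eigendecomposition oracle", {
  st <- fx_study()
  genes <- colnames(st$sim$expr)[101:140]
  eg <- module_eigengene(st$sim$expr, genes)
  z <- scale(st$sim$expr[, genes])
  ev <- eigen(crossprod(z), symmetric = TRUE)
  scores <- z %*% ev$vectors[, 1]
  scores <- scores[, 1] / sqrt(sum(scores^2))
  if (stats::cor(scores, rowMeans(z)) < 0) scores <- -scores
  expect_equal(unname(eg$scores), unname(scores), tolerance = 1e-8)
  expect_equal(eg$explained, ev$values[1] / sum(ev$values), tolerance = 1e-8)
  expect_equal(sum(eg$scores^2), 1, tolerance = 1e-12)
  expect_gte(stats::cor(eg$scores, rowMeans(z)), 0)
})

test_that("a module of identical profiles has a fully explanatory eigengene", {
  set.seed(77)
  base <- stats::rnorm(24)
  expr <- sapply(1:5, function(i) 2 * base + i)  # same standardized profile
  colnames(expr) <- paste0("g", 1:5)
  eg <- module_eigengene(expr, colnames(expr))
  expect_equal(eg$explained, 1, tolerance = 1e-12)
  expect_equal(abs(stats::cor(eg$scores, base)), 1, tolerance = 1e-12)
  expect_error(module_eigengene(matrix(1, 24, 2,
                                       dimnames = list(NULL, c("a", "b"))),
                                c("a", "b")), "degenerate")
})

test_that("module-trait correlations match theory and a permutation oracle", {
  st <- fx_study()
  E <- cbind(self = as.numeric(scale(st$ph)) / sqrt(23),
             other = module_eigengene(st$sim$expr,
                                      colnames(st$sim$expr)[101:140])$scores)
  res <- module_trait_correlation(E, st$ph)
  expect_equal(res$r[res$module == "self"], 1, tolerance = 1e-10)
  expect_equal(formals(module_trait_correlation)$sig_level, 0.01)

  # permutation oracle for the analytic p-value
  r_obs <- abs(res$r[res$module == "other"])
  set.seed(78)
  perm <- replicate(4000, abs(stats::cor(E[, "other"], sample(st$ph))))
  p_perm <- mean(perm >= r_obs)
  p_analytic <- res$p[res$module == "other"]
  expect_lt(abs(p_perm - p_analytic),
            3 * sqrt(p_analytic * (1 - p_analytic) / 4000) + 0.01)
})

test_that("prediction strength matches pair enumeration and its one-directional cases", {
  set.seed(79)
  genes <- paste0("g", 1:60)
  ref <- stats::setNames(sample(c("a", "b", "c"), 60, replace = TRUE), genes)
  alt <- stats::setNames(sample(c("x", "y"), 60, replace = TRUE), genes)
  ps <- prediction_strength(ref, alt)
  oracle <- oracle_prediction_strength(ref, alt)
  expect_equal(ps$per_cluster[names(oracle)], oracle)
  expect_equal(ps$median, stats::median(oracle))

  expect_equal(prediction_strength(ref, ref)$median, 1)
  one <- stats::setNames(rep("all", 60), genes)
  expect_equal(prediction_strength(ref, one)$median, 1)  # PS is one-directional
})

test_that("top-connected genes are retained across network parameter changes", {
  st <- fx_study(seed = 8)
  base <- network_params(beta = 6, min_cluster_size = 10)
  expect_equal(top_connected_retention(st$sim$expr, base, base, 0.2)$mean, 100)
  for (fr in c(0.2, 0.4)) {
    ret <- top_connected_retention(st$sim$expr, base,
                                   network_params(beta = 8, min_cluster_size = 10),
                                   fraction = fr)
    expect_gte(ret$mean, 90)
  }
})

test_that("soft-threshold selection degenerates gracefully", {
  st <- fx_study()
  single <- pick_soft_threshold(st$sim$expr, candidate_betas = 4)
  expect_equal(single$beta, 4)
  res <- suppressWarnings(pick_soft_threshold(st$sim$expr[, 1:120],
                                              candidate_betas = c(2, 4, 6, 8)))
  expect_true(res$beta %in% c(2, 4, 6, 8))
  expect_equal(nrow(res$fit_table), 4)
  expect_true(all(abs(res$fit_table$fit) <= 1))
})
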