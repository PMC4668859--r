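# Weighted gene co-expression network core, written from scratch:
# soft-threshold selection by the scale-free topology criterion, unsigned
# adjacency, topological overlap, average-linkage clustering with an
# adaptive branch cut, eigengenes, module merging, connectivity, trait
# correlation and robustness diagnostics.

#' Network construction parameters
#'
#' @param beta Soft-thresholding power (default 6).
#' @param deep_split Integer 0-4 controlling the branch-cut height
#'   quantile (higher = deeper splits, more/smaller modules).
#' @param min_cluster_size Minimum genes per module (default 40).
#' @param cut_height Maximum eigengene dissimilarity that qualifies two
#'   modules for merging (default 0.15).
#' @param signed Use signed adjacency ((1 + cor)/2)^beta instead of the
#'   default unsigned |cor|^beta.
#' @return A `network_params` list.
#' @export
network_params <- function(beta = 6, deep_split = 2, min_cluster_size = 40,
                           cut_height = 0.15, signed = FALSE) {
  stopifnot(beta >= 1, min_cluster_size >= 2,
            cut_height >= 0, cut_height <= 1,
            deep_split %in% 0:4)
  structure(list(beta = beta, deep_split = deep_split,
                 min_cluster_size = min_cluster_size,
                 cut_height = cut_height, signed = signed),
            class = "network_params")
}

#' Unsigned co-expression adjacency
#'
#' a_ij = |Pearson cor(x_i, x_j)|^beta for i != j; the diagonal is stored
#' as 0 so connectivity k_i = sum_j a_ij is a plain row sum. Constant
#' genes get zero correlations with a notice.
#'
#' @param expr Strains x genes matrix.
#' @param beta Soft-thresholding power.
#' @param signed Use the signed transform ((1 + cor)/2)^beta.
#' @return Genes x genes adjacency matrix.
#' @export
adjacency_matrix <- function(expr, beta = 6, signed = FALSE) {
  stopifnot(ncol(expr) >= 2, nrow(expr) >= 3)
  const <- apply(expr, 2, function(x) .is_constant(x))
  if (any(const)) {
    message(sum(const), " constant gene(s): correlations set to 0")
    expr[, const] <- expr[, const, drop = FALSE] +
      matrix(stats::rnorm(nrow(expr) * sum(const), 0, 1e-10),
             nrow(expr), sum(const))
  }
  cc <- suppressWarnings(stats::cor(expr))
  cc[!is.finite(cc)] <- 0
  if (any(const)) {
    cc[const, ] <- 0
    cc[, const] <- 0
  }
  a <- if (signed) ((1 + cc) / 2)^beta else abs(cc)^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) for
#' i != j and TOM_ii = 1: the similarity credits shared network neighbors.
#' The clustering dissimilarity is 1 - TOM.
#'
#' @param adjacency Symmetric matrix with entries in [0, 1], zero diagonal.
#' @return TOM matrix of the same dimension.
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    .stopf("adjacency must be symmetric")
  if (any(adjacency < 0 | adjacency > 1)) .stopf("adjacency entries must be in [0,1]")
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Connectivity (sum of connection strengths)
#'
#' @param adjacency Adjacency matrix (zero diagonal).
#' @return Named vector k_i = sum_j a_ij.
#' @export
connectivity <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  rowSums(a)
}

#' Choose the soft-thresholding power by the scale-free topology criterion
#'
#' For each candidate beta the connectivity distribution is binned on
#' log10(k) and log10(p(k)) is regressed on the bin mean log10(k); the fit
#' is the signed R^2 (negated when the slope is positive, since scale-free
#' topology requires a decreasing frequency of high-k hubs). The smallest
#' beta reaching `target_fit` is returned; if none does, the argmax with a
#' warning.
#'
#' @param expr Strains x genes matrix (>= 30 genes).
#' @param candidate_betas Candidate powers (>= 3 unless a single value is
#'   supplied, which is returned as-is).
#' @param target_fit Signed R^2 target (default 0.8).
#' @param n_bins Number of connectivity bins (default 10).
#' @return List: `beta`, `fit_table` (beta, fit, slope, mean_k).
#' @export
pick_soft_threshold <- function(expr, candidate_betas = c(1:10, 12, 14, 16),
                                target_fit = 0.8, n_bins = 10) {
  if (length(candidate_betas) == 1)
    return(list(beta = candidate_betas,
                fit_table = data.frame(beta = candidate_betas, fit = NA,
                                       slope = NA, mean_k = NA)))
  stopifnot(length(candidate_betas) >= 3, ncol(expr) >= 30)
  cc <- abs(stats::cor(expr))
  diag(cc) <- 0
  rows <- lapply(candidate_betas, function(b) {
    k <- rowSums(cc^b)
    if (.is_constant(k))
      .stopf("degenerate connectivity distribution (all k equal)")
    k <- k[k > 0]
    lk <- log10(k)
    br <- seq(min(lk), max(lk), length.out = n_bins + 1)
    bin <- cut(lk, br, include.lowest = TRUE)
    pk <- tapply(lk, bin, length) / length(lk)
    xk <- tapply(lk, bin, mean)
    ok <- !is.na(pk) & pk > 0
    fit <- stats::lm(log10(pk[ok]) ~ xk[ok])
    r2 <- summary(fit)$r.squared
    slope <- stats::coef(fit)[2]
    data.frame(beta = b, fit = if (slope > 0) -r2 else r2,
               slope = unname(slope), mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  hit <- which(tab$fit >= target_fit)
  if (length(hit)) {
    beta <- tab$beta[hit[1]]
  } else {
    warning("no candidate beta reached the scale-free fit target; returning argmax")
    beta <- tab$beta[which.max(tab$fit)]
  }
  list(beta = beta, fit_table = tab)
}

#' Detect modules by adaptive branch cutting of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering on 1 - TOM; the tree is cut at
#' a height offset below its top merge, scaled by `deep_split`
#' (cut = max_h - (0.05 + 0.05 * deep_split) * (max_h - min_h), so deeper
#' splits cut lower), and branches of at least `min_cluster_size` genes
#' become modules. Distinct modules join the dendrogram close to
#' dissimilarity 1, so a cut just below the top separates them while
#' leaving unclustered genes out. Modules are named by deterministic
#' colors ordered by descending size; remaining genes are "grey"
#' (unassigned).
#'
#' @param tom TOM matrix.
#' @param params A `network_params`.
#' @return Named character vector of module colors per gene.
#' @export
detect_modules <- function(tom, params = network_params()) {
  genes <- colnames(tom)
  n <- ncol(tom)
  if (n < params$min_cluster_size) {
    warning("fewer genes than min_cluster_size: all genes unassigned")
    return(stats::setNames(rep("grey", n), genes))
  }
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  h_range <- range(hc$height)
  cut_h <- h_range[2] - (0.05 + 0.05 * params$deep_split) * diff(h_range)
  raw <- stats::cutree(hc, h = cut_h)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= params$min_cluster_size]
  labels <- rep("grey", n)
  if (length(big)) {
    ord <- big[order(-sizes[big], as.integer(big))]
    for (i in seq_along(ord)) {
      col <- .module_palette[min(i, length(.module_palette))]
      labels[raw == as.integer(ord[i])] <- col
    }
  }
  stats::setNames(labels, genes)
}

#' Module eigengene (first principal component)
#'
#' Member genes are standardized across strains; the eigengene is the
#' unit-norm first principal component score vector, with its sign chosen
#' so that the correlation with the module's mean expression profile is
#' non-negative.
#'
#' @param expr Strains x genes matrix.
#' @param member_genes Character vector of module gene ids (>= 2).
#' @return List: `scores` (strain-length unit vector), `explained`
#'   (fraction of variance explained by the first component).
#' @export
module_eigengene <- function(expr, member_genes) {
  stopifnot(length(member_genes) >= 2)
  sub <- expr[, member_genes, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (all(sds < 1e-12)) .stopf("degenerate module: all member genes constant")
  sub <- sub[, sds > 1e-12, drop = FALSE]
  z <- scale(sub)
  sv <- svd(z)
  scores <- sv$u[, 1]
  scores <- scores / sqrt(sum(scores^2))
  mp <- rowMeans(z)
  if (stats::cor(scores, mp) < 0) scores <- -scores
  list(scores = stats::setNames(scores, rownames(expr)),
       explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Eigengenes for every module in a labeling
#'
#' @param expr Strains x genes matrix.
#' @param labels Module labels per gene ("grey" excluded).
#' @return Strains x modules matrix of eigengene scores.
#' @export
module_eigengenes <- function(expr, labels) {
  mods <- setdiff(unique(labels), "grey")
  if (length(mods) == 0) .stopf("no assigned modules")
  E <- vapply(mods, function(m) {
    module_eigengene(expr, names(labels)[labels == m])$scores
  }, numeric(nrow(expr)))
  colnames(E) <- mods
  E
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest module pair whose eigengene
#' dissimilarity 1 - cor(E_i, E_j) is below `cut_height`, recomputing
#' eigengenes after each merge, until no pair qualifies. The merged module
#' keeps the larger member's color.
#'
#' @param expr Strains x genes matrix.
#' @param labels Module labels from [detect_modules()].
#' @param cut_height Maximum qualifying dissimilarity.
#' @return Updated label vector.
#' @export
merge_close_modules <- function(expr, labels, cut_height = 0.15) {
  if (cut_height <= 0) return(labels)
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) return(labels)
    E <- module_eigengenes(expr, labels)
    dis <- 1 - stats::cor(E)
    diag(dis) <- Inf
    ij <- arrayInd(which.min(dis), dim(dis))
    if (dis[ij] >= cut_height) return(labels)
    m1 <- colnames(E)[ij[1]]; m2 <- colnames(E)[ij[2]]
    keep <- if (sum(labels == m1) >= sum(labels == m2)) m1 else m2
    drop_m <- setdiff(c(m1, m2), keep)
    labels[labels == drop_m] <- keep
  }
}

#' Correlate module eigengenes with a trait
#'
#' Pearson correlation per module with a two-sided p-value from the t
#' transform on n - 2 degrees of freedom; modules with p below
#' `sig_level` are flagged.
#'
#' @param eigengenes Strains x modules matrix.
#' @param trait Numeric trait vector.
#' @param sig_level Significance flag level (default 0.01).
#' @return data.frame: module, r, p, significant.
#' @export
module_trait_correlation <- function(eigengenes, trait, sig_level = 0.01) {
  .check_numeric_vector(trait, "trait", nrow(eigengenes))
  if (.is_constant(trait)) .stopf("degenerate trait: zero variance")
  n <- nrow(eigengenes)
  r <- as.vector(stats::cor(eigengenes, trait))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  data.frame(module = colnames(eigengenes), r = r, p = p,
             significant = p < sig_level, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Prediction strength between two module labelings
#'
#' For each reference cluster with >= 2 members, the proportion of its
#' within-cluster gene pairs that are also co-clustered in the alternative
#' labeling; the median over clusters summarizes stability. Unassigned
#' ("grey") genes form their own co-membership class.
#'
#' @param labels_ref,labels_alt Named label vectors over the same genes.
#' @return List: `per_cluster` (named vector), `median`.
#' @export
prediction_strength <- function(labels_ref, labels_alt) {
  genes <- names(labels_ref)
  stopifnot(setequal(genes, names(labels_alt)))
  labels_alt <- labels_alt[genes]
  mods <- names(which(table(labels_ref) >= 2))
  mods <- setdiff(mods, character(0))
  if (length(mods) == 0) .stopf("prediction strength undefined: all clusters singletons")
  ps <- vapply(mods, function(m) {
    idx <- which(labels_ref == m)
    alt <- labels_alt[idx]
    tab <- table(alt)
    same <- sum(tab * (tab - 1) / 2)
    total <- length(idx) * (length(idx) - 1) / 2
    same / total
  }, numeric(1))
  list(per_cluster = ps, median = stats::median(ps))
}

#' Retention of each module's most connected genes under parameter change
#'
#' Builds the network twice (base and variant parameters); for each base
#' module the top-`fraction` genes by whole-network connectivity are
#' looked up in the variant labeling, and retention is the percentage of
#' them assigned to the single variant module sharing the most members
#' with the base module. The mean over base modules is returned.
#'
#' @param expr Strains x genes matrix.
#' @param params_base,params_variant `network_params` for the two builds.
#' @param fraction Fraction of most connected genes (default 0.2).
#' @return List: `per_module` (named percentages), `mean`.
#' @export
top_connected_retention <- function(expr, params_base, params_variant,
                                    fraction = 0.2) {
  stopifnot(fraction > 0, fraction <= 1)
  base <- build_network(expr, params_base)
  variant <- build_network(expr, params_variant)
  mods <- setdiff(unique(base$labels), "grey")
  if (length(mods) == 0) .stopf("no modules in base network")
  per <- vapply(mods, function(m) {
    members <- names(base$labels)[base$labels == m]
    match_tab <- table(variant$labels[members])
    match_mod <- names(match_tab)[which.max(match_tab)]
    k <- base$connectivity[members]
    n_top <- max(1L, ceiling(fraction * length(members)))
    top <- members[order(-k)][seq_len(n_top)]
    100 * mean(variant$labels[top] == match_mod)
  }, numeric(1))
  list(per_module = per, mean = mean(per))
}

#' Build a full network model
#'
#' Adjacency, TOM, module detection, merging, eigengenes and
#' connectivity in one call.
#'
#' @param expr Strains x genes matrix.
#' @param params A `network_params`.
#' @return A `network_model` list: gene_ids, adjacency, tom, labels,
#'   eigengenes, connectivity, params.
#' @export
build_network <- function(expr, params = network_params()) {
  a <- adjacency_matrix(expr, params$beta, params$signed)
  tom <- topological_overlap(a)
  labels <- detect_modules(tom, params)
  labels <- merge_close_modules(expr, labels, params$cut_height)
  k <- connectivity(a)
  E <- if (length(setdiff(unique(labels), "grey")))
    module_eigengenes(expr, labels) else NULL
  structure(list(gene_ids = colnames(expr), adjacency = a, tom = tom,
                 labels = labels, eigengenes = E, connectivity = k,
                 params = params),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("co-expression network: %d genes, %d modules (beta = %g)\n",
              length(x$gene_ids), length(setdiff(names(tab), "grey")),
              x$params$beta))
  print(sort(tab, decreasing = TRUE))
  invisible(x)
}

#' Export edge and node tables for Cytoscape
#'
#' Writes an edge list (gene1, gene2, weight) filtered at a minimum TOM
#' weight and a node attribute table (gene, module, connectivity, chrom).
#'
#' @param model A `network_model`.
#' @param annotation Gene annotation data.frame (gene_id, chrom, start_Mb).
#' @param edge_file,node_file Output TSV paths.
#' @param min_weight Minimum TOM weight for edges (default 0.1).
#' @return Invisibly, list with the two data.frames.
#' @export
export_cytoscape <- function(model, annotation, edge_file, node_file,
                             min_weight = 0.1) {
  tom <- model$tom
  idx <- which(upper.tri(tom) & tom >= min_weight, arr.ind = TRUE)
  edges <- data.frame(gene1 = colnames(tom)[idx[, 1]],
                      gene2 = colnames(tom)[idx[, 2]],
                      weight = tom[idx], stringsAsFactors = FALSE)
  nodes <- data.frame(gene_id = model$gene_ids,
                      module = unname(model$labels[model$gene_ids]),
                      connectivity = unname(model$connectivity[model$gene_ids]),
                      stringsAsFactors = FALSE)
  nodes <- merge(nodes, annotation, by = "gene_id", all.x = TRUE)
  utils::write.table(edges, edge_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(nodes, node_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(edges = edges, nodes = nodes))
}
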