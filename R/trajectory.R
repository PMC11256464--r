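## Simplified lineage and pseudotime inference: variance-stabilizing log
## normalization, HVG selection, PCA, k-means clustering, a minimum
## spanning tree over cluster centroids, root-to-leaf lineages, projection
## pseudotime along piecewise-linear centroid paths, permutation tests for
## lineage-varying genes, and cosine-distance gene-module clustering.

#' Log-normalize counts to the median library size
#'
#' norm = log1p(count / size_factor), with median-ratio size factors, so a
#' cell's counts are rescaled to the median library before the log. Genes
#' with zero counts in more than \code{max_zero_frac} of cells are dropped
#' first (unreliable at these depths), as are mitochondrial confounders
#' when feature types are annotated.
#'
#' @param expr SingleCellExperiment or counts matrix (genes x cells).
#' @param max_zero_frac gene filter threshold (default 0.975).
#' @param drop_types feature types removed when \code{rowData(expr)$type}
#'   exists (default mito and mouse features).
#' @return dense matrix genes x cells of log-normalized expression.
#' @export
logNormalizeCounts <- function(expr, max_zero_frac = 0.975,
                               drop_types = c("mito", "mouse")) {
  m <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "counts") else expr
  if (is(expr, "SummarizedExperiment")) {
    rd <- SummarizedExperiment::rowData(expr)
    if (!is.null(rd$type)) m <- m[!(rd$type %in% drop_types), , drop = FALSE]
  }
  zero_frac <- 1 - Matrix::rowMeans(m > 0)
  m <- m[zero_frac <= max_zero_frac, , drop = FALSE]
  f <- computeSizeFactors(m)
  log1p(sweep(as.matrix(m), 2, f, "/"))
}

.project_on_path <- function(points, path_pts) {
  ## orthogonal projection of each row of points onto the piecewise-linear
  ## path; returns normalized arc length in [0,1] and distance to the path
  nseg <- nrow(path_pts) - 1
  seg_vec <- path_pts[-1, , drop = FALSE] - path_pts[-nrow(path_pts), , drop = FALSE]
  seg_len <- sqrt(rowSums(seg_vec^2))
  cum0 <- c(0, cumsum(seg_len))
  total <- max(cum0[nseg + 1], 1e-12)
  best_arc <- rep(0, nrow(points))
  best_d2 <- rep(Inf, nrow(points))
  for (sgm in seq_len(nseg)) {
    a <- path_pts[sgm, ]
    v <- seg_vec[sgm, ]
    l2 <- max(sum(v^2), 1e-24)
    t <- pmin(1, pmax(0, (sweep(points, 2, a) %*% v) / l2))
    proj <- outer(as.vector(t), v) + rep(a, each = nrow(points))
    d2 <- rowSums((points - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- cum0[sgm] + t[upd] * seg_len[sgm]
  }
  list(t = best_arc / total, dist = sqrt(best_d2))
}

#' Infer lineages over a cluster minimum spanning tree
#'
#' The normalized matrix is reduced to its \code{n_hvg} most variable genes
#' and \code{n_pcs} principal components; cells are k-means clustered
#' (small outlier clusters below \code{min_cluster_frac} are removed); a
#' minimum spanning tree connects cluster centroids in PC space; lineages
#' are the root-to-leaf paths from the start cluster - by default the
#' cluster holding the most untreated cells from the earliest passage.
#' Each cell's pseudotime per lineage is the normalized arc length of its
#' orthogonal projection onto the lineage's piecewise-linear centroid path;
#' cells in clusters shared between lineages split their weight by inverse
#' projection distance.
#'
#' @param expr SingleCellExperiment with counts, or an already normalized
#'   genes x cells matrix (then set \code{normalized = TRUE}).
#' @param n_hvg highly variable genes kept (default 3000).
#' @param n_pcs principal components (default 30).
#' @param k k-means cluster count (default 8).
#' @param start_cluster optional explicit root; otherwise the
#'   condition/passage rule is applied to \code{colData} (fields condition
#'   and passage).
#' @param min_cluster_frac outlier-cluster removal threshold (default 0.01).
#' @param normalized set TRUE when \code{expr} is already log-normalized.
#' @param seed RNG seed (k-means starts).
#' @return a \linkS4class{LineageSet}.
#' @export
inferLineages <- function(expr, n_hvg = 3000, n_pcs = 30, k = 8,
                          start_cluster = NULL, min_cluster_frac = 0.01,
                          normalized = FALSE, seed = 1L) {
  norm <- if (normalized) as.matrix(expr) else logNormalizeCounts(expr)
  if (is.null(colnames(norm)))
    colnames(norm) <- paste0("cell", seq_len(ncol(norm)))
  v <- apply(norm, 1, stats::var)
  if (all(v < 1e-12)) stop("degenerate input: all cells identical")
  hvg <- names(sort(v, decreasing = TRUE))[seq_len(min(n_hvg, sum(v > 0)))]
  x <- t(norm[hvg, , drop = FALSE])
  n_pcs <- min(n_pcs, ncol(x) - 1L, nrow(x) - 1L)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)$x

  set.seed(seed)
  k <- min(k, nrow(pc) - 1L)
  km <- stats::kmeans(pc, centers = k, nstart = 10, iter.max = 100)
  cl <- km$cluster

  ## drop small outlier clusters, re-index
  keep_cl <- as.integer(names(which(table(cl) >= min_cluster_frac *
                                      length(cl))))
  keep <- cl %in% keep_cl
  pc <- pc[keep, , drop = FALSE]
  cl <- match(cl[keep], keep_cl)
  names(cl) <- rownames(pc)
  ncl <- length(keep_cl)
  if (ncl < 2) stop("fewer than 2 clusters after outlier removal")
  centroids <- t(vapply(seq_len(ncl), function(j)
    colMeans(pc[cl == j, , drop = FALSE]), numeric(ncol(pc))))

  if (is.null(start_cluster)) {
    cd <- if (is(expr, "SummarizedExperiment"))
      SummarizedExperiment::colData(expr)[names(cl), ] else NULL
    if (!is.null(cd) && !is.null(cd$condition) && !is.null(cd$passage)) {
      unrx <- cd$condition == "UnRx" & cd$passage == min(cd$passage)
      if (!any(unrx)) unrx <- cd$condition == "UnRx"
      start_cluster <- if (any(unrx))
        as.integer(names(which.max(table(cl[unrx])))) else 1L
    } else start_cluster <- 1L
  }
  if (!any(cl == start_cluster)) stop("start rule selected an empty cluster")

  d <- as.matrix(stats::dist(centroids))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  deg <- igraph::degree(tree)
  leaves <- setdiff(which(deg == 1), start_cluster)
  if (!length(leaves)) leaves <- setdiff(seq_len(ncl), start_cluster)
  paths <- igraph::shortest_paths(tree, from = start_cluster,
                                  to = leaves)$vpath
  lineage_paths <- lapply(paths, as.integer)
  names(lineage_paths) <- paste0("L", seq_along(lineage_paths))
  mst_edges <- igraph::as_edgelist(tree)
  storage.mode(mst_edges) <- "integer"

  nlin <- length(lineage_paths)
  pt <- matrix(NA_real_, nrow(pc), nlin,
               dimnames = list(rownames(pc), names(lineage_paths)))
  dist_to <- matrix(Inf, nrow(pc), nlin)
  for (l in seq_len(nlin)) {
    path <- lineage_paths[[l]]
    on_lin <- cl %in% path
    if (length(path) < 2) { pt[on_lin, l] <- 0; dist_to[on_lin, l] <- 0; next }
    pr <- .project_on_path(pc[on_lin, , drop = FALSE],
                           centroids[path, , drop = FALSE])
    pt[on_lin, l] <- pr$t
    dist_to[on_lin, l] <- pr$dist
  }
  w <- matrix(0, nrow(pc), nlin, dimnames = dimnames(pt))
  n_memb <- rowSums(!is.na(pt))
  single <- n_memb == 1
  w[!is.na(pt) & single] <- 1
  multi <- which(n_memb > 1)
  for (i in multi) {
    inv <- ifelse(is.na(pt[i, ]), 0, 1 / (dist_to[i, ] + 1e-8))
    w[i, ] <- inv / sum(inv)
  }

  new("LineageSet", clusters = cl, centroids = centroids,
      mst_edges = mst_edges, lineages = lineage_paths, pseudotime = pt,
      weights = w, pca = pc, start_cluster = as.integer(start_cluster))
}

## per-cell hard lineage assignment (max weight) and pseudotime
.cell_lineage <- function(lin) {
  w <- lin@weights
  l <- max.col(w, ties.method = "first")
  t <- lin@pseudotime[cbind(seq_len(nrow(w)), l)]
  data.frame(cell = rownames(w), lineage = l, t = t,
             stringsAsFactors = FALSE)
}

## binned per-lineage mean curves: genes x (nbins * nlin), empty bins
## filled by linear interpolation over bin centers
.binned_curves <- function(norm, assign, nbins, nlin) {
  bin <- pmin(nbins, pmax(1L, ceiling(assign$t * nbins)))
  bin[assign$t == 0] <- 1L
  grp <- (assign$lineage - 1L) * nbins + bin
  ind <- matrix(0, length(grp), nbins * nlin)
  ind[cbind(seq_along(grp), grp)] <- 1
  cnt <- colSums(ind)
  sums <- norm[, assign$cell, drop = FALSE] %*% ind
  means <- sweep(sums, 2, pmax(cnt, 1), "/")
  centers <- (seq_len(nbins) - 0.5) / nbins
  for (l in seq_len(nlin)) {
    idx <- (l - 1L) * nbins + seq_len(nbins)
    filled <- cnt[idx] > 0
    if (any(!filled) && sum(filled) >= 2) {
      for (g in seq_len(nrow(means)))
        means[g, idx[!filled]] <- stats::approx(
          centers[filled], means[g, idx[filled]],
          xout = centers[!filled], rule = 2)$y
    }
  }
  attr(means, "bin_counts") <- cnt
  means
}

#' Permutation tests for lineage-varying genes
#'
#' Per gene, three statistics on binned per-lineage mean curves over a
#' common pseudotime grid: \code{pattern_stat}, the mean squared difference
#' between lineage curves averaged over lineage pairs (the
#' whole-trajectory pattern analogue); \code{end_stat} and
#' \code{early_stat}, the absolute smoothed-mean differences in the last /
#' first pseudotime decile. The null distribution shuffles each cell's
#' lineage label within its pseudotime decile, preserving the pseudotime
#' profile while breaking lineage structure; p-values are empirical and
#' BH-adjusted per statistic.
#'
#' @param expr normalized genes x cells matrix (see
#'   \code{\link{logNormalizeCounts}}) or SingleCellExperiment.
#' @param lin a \linkS4class{LineageSet} with >= 2 lineages.
#' @param genes optional subset of genes to test.
#' @param n_perm permutations (default 500).
#' @param nbins pseudotime bins (default 10, i.e., deciles).
#' @param min_cells lineages with fewer cells are excluded with a warning.
#' @param seed RNG seed.
#' @return data.frame per gene: pattern_stat, end_stat, early_stat and
#'   their empirical p-values and BH adjustments.
#' @export
lineageGeneTests <- function(expr, lin, genes = NULL, n_perm = 500,
                             nbins = 10, min_cells = 20, seed = 1L) {
  norm <- if (is(expr, "SummarizedExperiment")) logNormalizeCounts(expr)
          else as.matrix(expr)
  if (!is.null(genes)) norm <- norm[intersect(genes, rownames(norm)), ,
                                    drop = FALSE]
  asg <- .cell_lineage(lin)
  asg <- asg[!is.na(asg$t) & asg$cell %in% colnames(norm), ]
  sizes <- table(factor(asg$lineage, seq_along(lin@lineages)))
  ok_lin <- as.integer(names(which(sizes >= min_cells)))
  if (length(ok_lin) < length(sizes))
    warning("excluding lineages with < ", min_cells, " cells: ",
            paste(setdiff(names(sizes), as.character(ok_lin)),
                  collapse = ", "))
  if (length(ok_lin) < 2) stop("need >= 2 lineages with enough cells")
  asg <- asg[asg$lineage %in% ok_lin, ]
  asg$lineage <- match(asg$lineage, ok_lin)
  nlin <- length(ok_lin)

  stat_fun <- function(a) {
    cur <- .binned_curves(norm, a, nbins, nlin)
    pats <- ends <- earls <- 0
    npair <- 0
    for (l1 in seq_len(nlin - 1)) for (l2 in seq(l1 + 1, nlin)) {
      i1 <- (l1 - 1L) * nbins; i2 <- (l2 - 1L) * nbins
      dif <- cur[, i1 + seq_len(nbins), drop = FALSE] -
             cur[, i2 + seq_len(nbins), drop = FALSE]
      pats <- pats + rowMeans(dif^2)
      ends <- pmax(ends, abs(dif[, nbins]))
      earls <- pmax(earls, abs(dif[, 1]))
      npair <- npair + 1
    }
    cbind(pattern = pats / npair, end = ends, early = earls)
  }
  obs <- stat_fun(asg)

  set.seed(seed)
  dec <- pmin(nbins, pmax(1L, ceiling(asg$t * nbins)))
  dec[asg$t == 0] <- 1L
  ge <- matrix(0L, nrow(norm), 3,
               dimnames = list(rownames(norm), colnames(obs)))
  for (i in seq_len(n_perm)) {
    perm <- asg
    for (b in unique(dec)) {
      idx <- which(dec == b)
      perm$lineage[idx] <- asg$lineage[idx][sample.int(length(idx))]
    }
    ps <- stat_fun(perm)
    ge <- ge + (ps >= obs)
  }
  p <- (1 + ge) / (1 + n_perm)
  out <- data.frame(gene = rownames(norm),
                    pattern_stat = obs[, "pattern"],
                    end_stat = obs[, "end"], early_stat = obs[, "early"],
                    p_pattern = p[, "pattern"], p_end = p[, "end"],
                    p_early = p[, "early"], stringsAsFactors = FALSE)
  out$p_adj_pattern <- stats::p.adjust(out$p_pattern, "BH")
  out$p_adj_end <- stats::p.adjust(out$p_end, "BH")
  out$p_adj_early <- stats::p.adjust(out$p_early, "BH")
  rownames(out) <- out$gene
  out
}

#' Select trajectory-significant genes
#'
#' A gene is significant when its pattern test and at least one of the
#' endpoint / early tests pass \code{alpha} on adjusted p-values; an
#' optional rank cap keeps the \code{top_n} by pattern statistic (the
#' rank-based analogue of a fixed Wald-statistic cutoff).
#'
#' @param tests \code{\link{lineageGeneTests}} output.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param top_n optional cap on the number of genes, ranked by
#'   \code{pattern_stat}.
#' @return character vector of gene ids.
#' @export
significantLineageGenes <- function(tests, alpha = 0.05, top_n = NULL) {
  sig <- tests$p_adj_pattern < alpha &
    (tests$p_adj_end < alpha | tests$p_adj_early < alpha)
  g <- tests[sig, , drop = FALSE]
  g <- g[order(-g$pattern_stat), ]
  if (!is.null(top_n)) g <- utils::head(g, top_n)
  g$gene
}

#' Smoothed per-gene per-lineage expression curves
#'
#' Binned per-lineage means linearly interpolated onto a common pseudotime
#' grid, concatenated across lineages per gene.
#'
#' @param expr normalized genes x cells matrix or SingleCellExperiment.
#' @param lin a \linkS4class{LineageSet}.
#' @param genes optional gene subset.
#' @param nbins bins for the raw means; \code{grid_n} grid points.
#' @param grid_n grid resolution (default 100).
#' @return matrix genes x (grid_n * n_lineages) with attributes
#'   \code{grid} and \code{n_lineages}.
#' @export
smoothedCurves <- function(expr, lin, genes = NULL, nbins = 10,
                           grid_n = 100) {
  norm <- if (is(expr, "SummarizedExperiment")) logNormalizeCounts(expr)
          else as.matrix(expr)
  if (!is.null(genes)) norm <- norm[intersect(genes, rownames(norm)), ,
                                    drop = FALSE]
  asg <- .cell_lineage(lin)
  asg <- asg[!is.na(asg$t) & asg$cell %in% colnames(norm), ]
  nlin <- length(lin@lineages)
  cur <- .binned_curves(norm, asg, nbins, nlin)
  centers <- (seq_len(nbins) - 0.5) / nbins
  grid <- seq(0, 1, length.out = grid_n)
  out <- matrix(0, nrow(cur), grid_n * nlin,
                dimnames = list(rownames(cur), NULL))
  for (l in seq_len(nlin)) {
    src <- (l - 1L) * nbins + seq_len(nbins)
    dst <- (l - 1L) * grid_n + seq_len(grid_n)
    for (g in seq_len(nrow(cur)))
      out[g, dst] <- stats::approx(centers, cur[g, src], xout = grid,
                                   rule = 2)$y
  }
  attr(out, "grid") <- grid
  attr(out, "n_lineages") <- nlin
  out
}

#' Cluster genes into modules by curve shape
#'
#' Cosine distance between concatenated per-lineage smoothed curves,
#' embedded by PCA to \code{n_components} and clustered by Leiden community
#' detection on a shared-rank kNN graph. All-zero-curve genes are dropped
#' with a warning (cosine undefined). Per-module per-lineage mean curves
#' are min-max scaled to [-2, 2].
#'
#' @param curves matrix from \code{\link{smoothedCurves}}.
#' @param n_components PCA dimensions of the embedding (default 25).
#' @param k_nn kNN graph degree (default 10).
#' @param resolution Leiden resolution (default 1).
#' @param seed RNG seed.
#' @return a \linkS4class{GeneModuleSet}.
#' @export
clusterGeneModules <- function(curves, n_components = 25, k_nn = 10,
                               resolution = 1, seed = 1L) {
  if (nrow(curves) < 10) stop("need >= 10 genes to cluster")
  grid <- attr(curves, "grid")
  nlin <- attr(curves, "n_lineages")
  nrm <- sqrt(rowSums(curves^2))
  if (any(nrm == 0)) {
    warning("dropping ", sum(nrm == 0), " all-zero-curve gene(s)")
    curves <- curves[nrm > 0, , drop = FALSE]
    nrm <- nrm[nrm > 0]
  }
  unit <- curves / nrm                    # Euclidean on unit rows ~ cosine
  n_components <- min(n_components, ncol(unit) - 1L, nrow(unit) - 1L)
  emb <- stats::prcomp(unit, center = TRUE, rank. = n_components)$x

  set.seed(seed)
  k_nn <- min(k_nn, nrow(emb) - 1L)
  d <- as.matrix(stats::dist(emb))
  adj <- matrix(0, nrow(d), ncol(d))
  for (i in seq_len(nrow(d))) {
    nb <- order(d[i, ])[2:(k_nn + 1)]
    adj[i, nb] <- 1
  }
  adj <- pmax(adj, t(adj))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cm <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  modules <- as.integer(igraph::membership(cm))
  names(modules) <- rownames(curves)

  grid_n <- length(grid)
  curve_list <- lapply(sort(unique(modules)), function(m) {
    mg <- curves[modules == m, , drop = FALSE]
    avg <- colMeans(mg)
    out <- matrix(avg, nrow = grid_n, ncol = nlin)
    rng <- range(out)
    if (diff(rng) > 0)
      out <- (out - rng[1]) / diff(rng) * 4 - 2   # min-max to [-2, 2]
    else out[] <- 0
    colnames(out) <- paste0("L", seq_len(nlin))
    out
  })
  names(curve_list) <- paste0("M", sort(unique(modules)))
  status <- rep(NA_character_, length(curve_list))
  names(status) <- names(curve_list)
  new("GeneModuleSet", modules = modules, curves = curve_list,
      grid = grid, status = status)
}

#' In-cis / in-trans annotation of genes per lineage
#'
#' Within each lineage, the clones present (holding at least
#' \code{min_clone_frac} of the lineage's cells, from the scRNA-seq clone
#' assignment) define the copy-number contrast: a gene is in-cis for that
#' lineage iff its bin's clone-median copy number differs between any pair
#' of those clones. A single-clone lineage has no contrast, so every gene
#' is in-trans there.
#'
#' @param genes character vector of gene ids.
#' @param lin a \linkS4class{LineageSet}.
#' @param assign a \linkS4class{CloneAssignment} covering the cells.
#' @param profiles a \linkS4class{CloneProfileSet}.
#' @param map gene-bin map from \code{\link{mapGenesToBins}}.
#' @param min_clone_frac clone presence threshold (default 0.05).
#' @return logical matrix genes x lineages (TRUE = in-cis; NA = unmapped).
#' @export
annotateLineageCisTrans <- function(genes, lin, assign, profiles, map,
                                    min_clone_frac = 0.05) {
  med <- medianCN(profiles)
  bin <- map$bin[match(genes, map$gene)]
  asg <- .cell_lineage(lin)
  clone <- cloneLabels(assign)
  nlin <- length(lin@lineages)
  out <- matrix(NA, length(genes), nlin,
                dimnames = list(genes, paste0("L", seq_len(nlin))))
  for (l in seq_len(nlin)) {
    cells <- asg$cell[asg$lineage == l]
    cl <- clone[intersect(cells, names(clone))]
    cl <- cl[!is.na(cl)]
    if (!length(cl)) next
    tab <- table(cl) / length(cl)
    present <- names(tab)[tab >= min_clone_frac]
    if (length(present) < 2) {
      message("lineage L", l, " carries a single clone; all in-trans")
      out[, l] <- FALSE
      out[is.na(bin), l] <- NA
      next
    }
    sub <- med[present, , drop = FALSE]
    differs <- apply(sub, 2, function(x) length(unique(x)) > 1)
    out[, l] <- differs[bin]
  }
  out
}
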