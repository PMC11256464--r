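## simulation: cells along a latent time with log-linear up/down programs
linear_traj <- function(n = 800, seed = 1, size = 5) {
  set.seed(seed)
  tt <- runif(n)
  slopes <- c(runif(25, 1, 2.5), runif(25, -2.5, -1))
  mu <- exp(outer(slopes, tt) + 1)
  mu <- rbind(mu, matrix(2, 30, n))
  x <- matrix(rnbinom(nrow(mu) * n, mu = mu, size = size), nrow(mu), n)
  rownames(x) <- paste0("g", seq_len(nrow(mu)))
  colnames(x) <- paste0("c", seq_len(n))
  list(x = x, t = tt)
}

## Y-branch: shared trunk then two diverging programs after t > 0.5
branch_traj <- function(n = 900, seed = 4) {
  set.seed(seed)
  tt <- runif(n); br <- sample(1:2, n, TRUE)
  f1 <- ifelse(tt > 0.5 & br == 1, tt - 0.5, 0)
  f2 <- ifelse(tt > 0.5 & br == 2, tt - 0.5, 0)
  mu <- rbind(exp(outer(c(runif(15, 1, 2), runif(15, -2, -1)), tt) + 1),
              exp(2 + 4 * outer(rep(1, 15), f1)),
              exp(2 + 4 * outer(rep(1, 15), f2)),
              matrix(3, 20, n))
  x <- matrix(rnbinom(nrow(mu) * n, mu = mu, size = 5), nrow(mu), n)
  rownames(x) <- paste0("g", seq_len(nrow(mu)))
  colnames(x) <- paste0("c", seq_len(n))
  list(x = x, t = tt, branch = br)
}

start_from_truth <- function(x, tt, ...) {
  lin0 <- inferLineages(x, ...)
  unname(lin0@clusters[colnames(x)[which.min(tt)]])
}

test_that("latent time is recovered on a linear trajectory", {
  sim <- linear_traj(seed = 1)
  sc <- start_from_truth(sim$x, sim$t, n_hvg = 80, n_pcs = 5, k = 6,
                         seed = 2)
  lin <- inferLineages(sim$x, n_hvg = 80, n_pcs = 5, k = 6, seed = 2,
                       start_cluster = sc)
  sz <- colSums(!is.na(pseudotimes(lin)))
  pt <- pseudotimes(lin)[, which.max(sz)]
  expect_gte(abs(cor(pt, sim$t, method = "kendall",
                     use = "complete.obs")), 0.8)
  ## pseudotime bounded in [0, 1]
  expect_true(all(pt >= 0 & pt <= 1, na.rm = TRUE))
  ## weights in [0, 1]
  expect_true(all(lin@weights >= 0 & lin@weights <= 1))
})

test_that("a Y-branching topology yields lineages sharing the trunk", {
  sim <- branch_traj()
  sc <- start_from_truth(sim$x, sim$t, n_hvg = 80, n_pcs = 8, k = 7,
                         seed = 2)
  lin <- inferLineages(sim$x, n_hvg = 80, n_pcs = 8, k = 7, seed = 2,
                       start_cluster = sc)
  expect_gte(length(lineages(lin)), 2)
  trunk <- Reduce(intersect, lineages(lin)[1:2])
  expect_gte(length(trunk), 1)
  expect_true(all(vapply(lineages(lin), function(l)
    l[1] == lin@start_cluster, logical(1))))
})

test_that("degenerate identical cells are caught", {
  x <- matrix(3, 20, 50, dimnames = list(paste0("g", 1:20),
                                         paste0("c", 1:50)))
  expect_error(inferLineages(x, n_hvg = 20, n_pcs = 5, k = 4, seed = 1),
               "degenerate|cluster")
})

test_that("affine transforms of PC space preserve cluster orderings", {
  sim <- linear_traj(n = 400, seed = 7)
  lin <- inferLineages(sim$x, n_hvg = 80, n_pcs = 5, k = 5, seed = 3,
                       start_cluster = 1L)
  ## scaling all centroids and cells leaves projections' order unchanged
  pr1 <- pseudotimes(lin)[, 1]
  lin2 <- lin
  lin2@pca <- lin@pca * 3 + 1
  lin2@centroids <- lin@centroids * 3 + 1
  pr2 <- cloneTx:::.project_on_path(
    lin2@pca[!is.na(pr1), , drop = FALSE],
    lin2@centroids[lineages(lin)[[1]], , drop = FALSE])$t
  expect_equal(unname(rank(pr2)), unname(rank(pr1[!is.na(pr1)])))
})

test_that("lineage tests flag branch genes and respect the null", {
  sim <- branch_traj()
  sc <- start_from_truth(sim$x, sim$t, n_hvg = 80, n_pcs = 8, k = 7,
                         seed = 2)
  lin <- inferLineages(sim$x, n_hvg = 80, n_pcs = 8, k = 7, seed = 2,
                       start_cluster = sc)
  tests <- lineageGeneTests(sim$x, lin, n_perm = 100, seed = 5)
  sig <- significantLineageGenes(tests)
  branch_genes <- paste0("g", 31:60)
  trunk_genes <- paste0("g", 1:30)
  expect_gte(mean(branch_genes %in% sig), 0.9)
  ## trunk genes follow both lineages identically: mostly not significant
  expect_lte(mean(trunk_genes %in% sig), 0.2)
  ## pattern stat is zero when lineages contain identical curves
  expect_true(all(tests$pattern_stat >= 0))
  ## top-N capping keeps the ranking by pattern_stat
  top5 <- significantLineageGenes(tests, top_n = 5)
  expect_length(top5, min(5, length(sig)))
})

test_that("gene modules recover planted curve archetypes", {
  skip_if_not_installed("mclust")
  sim <- branch_traj()
  sc <- start_from_truth(sim$x, sim$t, n_hvg = 80, n_pcs = 8, k = 7,
                         seed = 2)
  lin <- inferLineages(sim$x, n_hvg = 80, n_pcs = 8, k = 7, seed = 2,
                       start_cluster = sc)
  ## two archetypes: trunk-induced vs trunk-repressed genes
  genes <- paste0("g", 1:30)
  curves <- smoothedCurves(sim$x, lin, genes = genes)
  mods <- clusterGeneModules(curves, n_components = 10, seed = 6)
  truth_lab <- rep(1:2, each = 15)
  ari <- mclust::adjustedRandIndex(moduleLabels(mods), truth_lab)
  expect_gte(ari, 0.9)
  ## module curves scaled within [-2, 2]
  for (cu in mods@curves) expect_lte(max(abs(cu)), 2)
  ## duplicate genes land in the same module
  curves2 <- rbind(curves, dup = curves[1, ])
  attr(curves2, "grid") <- attr(curves, "grid")
  attr(curves2, "n_lineages") <- attr(curves, "n_lineages")
  mods2 <- clusterGeneModules(curves2, n_components = 10, seed = 6)
  expect_equal(unname(moduleLabels(mods2)["dup"]),
               unname(moduleLabels(mods2)[rownames(curves)[1]]))
  ## determinism
  mods3 <- clusterGeneModules(curves, n_components = 10, seed = 6)
  expect_identical(moduleLabels(mods), moduleLabels(mods3))
})

test_that("lineage cis/trans annotation uses per-lineage clone contrasts", {
  ## two lineages; lineage 1 mixes clones A+B, lineage 2 only clone A
  bins <- tiny_bins(4)
  med <- rbind(A = c(2, 2, 3, 4), B = c(2, 3, 3, 4))
  prof <- new("CloneProfileSet", median_cn = med, bins = bins,
              n_cells = c(A = 10L, B = 10L))
  genes <- GRanges("chr1", IRanges((0:3) * 500 + 10, width = 50),
                   strand = "+")
  genes$gene_id <- paste0("g", 1:4)
  map <- mapGenesToBins(genes, bins)
  cells <- paste0("c", 1:40)
  w <- cbind(L1 = rep(c(1, 0), each = 20), L2 = rep(c(0, 1), each = 20))
  pt <- w; pt[pt == 0] <- NA; pt[, 1] <- ifelse(is.na(pt[, 1]), NA, 0.5)
  pt[, 2] <- ifelse(is.na(pt[, 2]), NA, 0.5)
  rownames(w) <- rownames(pt) <- cells
  lin <- new("LineageSet", clusters = stats::setNames(rep(1:2, each = 20),
                                                      cells),
             centroids = matrix(0, 2, 2), mst_edges = cbind(1L, 2L),
             lineages = list(L1 = 1L, L2 = 2L), pseudotime = pt,
             weights = w, pca = matrix(0, 40, 2,
                                       dimnames = list(cells, NULL)),
             start_cluster = 1L)
  clone <- stats::setNames(c(rep(c("A", "B"), 10), rep("A", 20)), cells)
  asg <- new("CloneAssignment", clone = clone,
             posterior = matrix(1, 40, 1, dimnames = list(cells, "A")),
             genes_used = character(), log_lik = 0,
             dropped_cells = character(), params = list())
  out <- suppressMessages(
    annotateLineageCisTrans(paste0("g", 1:4), lin, asg, prof, map))
  ## lineage 1: A vs B differ only at bin 2 -> g2 in-cis
  expect_equal(unname(out[, "L1"]), c(FALSE, TRUE, FALSE, FALSE))
  ## lineage 2: single clone -> all in-trans
  expect_true(all(!out[, "L2"]))
})
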