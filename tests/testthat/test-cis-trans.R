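## helpers building a DE table + profiles around explicit medians
ct_fixture <- function(medA, medB, logFC) {
  n <- length(logFC)
  bins <- tiny_bins(n)
  genes <- GRanges("chr1", IRanges((seq_len(n) - 1) * 500 + 10,
                                   width = 100), strand = "+")
  genes$gene_id <- paste0("g", seq_len(n))
  map <- mapGenesToBins(genes, bins)
  med <- rbind(A = medA, B = medB)
  prof <- new("CloneProfileSet", median_cn = med, bins = bins,
              n_cells = c(A = 5L, B = 5L))
  de <- data.frame(gene = genes$gene_id, logFC = logFC,
                   p_value = 1e-5, fdr = 1e-4)
  list(de = de, map = map, prof = prof)
}

test_that("the six-trend sign table is honoured", {
  f <- ct_fixture(medA = c(4, 2, 3, 2, 2, 3),
                  medB = c(2, 2, 2, 3, 2, 4),
                  logFC = c(1, -0.8, -0.6, 0.9, 0.7, -1))
  calls <- classifyCisTrans(f$de, f$map, f$prof, "A", "B")
  expect_equal(unname(calls$category),
               c("GainUp", "InTransDown", "GainDown", "LossUp",
                 "InTransUp", "LossDown"))
  expect_equal(calls$is_cis, c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(calls$cn_correlated, c(TRUE, NA, FALSE, FALSE, NA, TRUE))
  expect_equal(calls$delta_cn, c(2, 0, 1, -1, 0, -1))
})

test_that("negating logFC mirrors the categories", {
  set.seed(41)
  n <- 40
  f <- ct_fixture(medA = sample(c(2, 3, 4), n, TRUE),
                  medB = sample(c(2, 3), n, TRUE),
                  logFC = round(runif(n, -2, 2), 3))
  f$de <- f$de[f$de$logFC != 0, ]
  c1 <- classifyCisTrans(f$de, f$map, f$prof, "A", "B")
  f2 <- f; f2$de$logFC <- -f2$de$logFC
  c2 <- classifyCisTrans(f2$de, f2$map, f2$prof, "A", "B")
  swap <- c(GainUp = "GainDown", GainDown = "GainUp",
            LossUp = "LossDown", LossDown = "LossUp",
            InTransUp = "InTransDown", InTransDown = "InTransUp")
  expect_identical(unname(swap[c1$category]), c2$category)
})

test_that("classification matches a brute-force re-derivation on synthetic data", {
  p <- simulationParams(n_clones = 2, cells_per_sample = 150,
                        n_passages = 1, conditions = "UnRx",
                        frac_mouse_cells = 0, frac_lowqc_cells = 0,
                        seed = 43)
  truth <- simulateTruth(p)
  sim <- simulateCells(truth)
  prof <- cloneMedianProfiles(sim$cn)
  map <- mapGenesToBins(truth@genes, truth@bins)
  ## pseudo DE table over all genes with random logFC
  set.seed(44)
  de <- data.frame(gene = truth@genes$gene_id,
                   logFC = round(stats::rnorm(length(truth@genes)), 3),
                   p_value = 1e-5, fdr = 1e-4)
  de <- de[de$logFC != 0, ]
  calls <- classifyCisTrans(de, map, prof, "A", "B")
  ## independent oracle: walk raw cell CN values per gene
  copy <- copyMatrix(sim$cn)
  clone <- cloneLabels(sim$cn)
  for (i in seq_len(nrow(calls))) {
    g <- calls$gene[i]
    b <- map[g, "bin"]
    mA <- stats::median(copy[clone == "A", b])
    mB <- stats::median(copy[clone == "B", b])
    lfc <- de$logFC[de$gene == g]
    expected <- if (mA == mB) {
      if (lfc > 0) "InTransUp" else "InTransDown"
    } else if (mA > mB) {
      if (lfc > 0) "GainUp" else "GainDown"
    } else {
      if (lfc > 0) "LossUp" else "LossDown"
    }
    if (calls$category[i] != expected) {
      fail(sprintf("gene %s: got %s expected %s", g, calls$category[i],
                   expected))
      break
    }
  }
  succeed()
})

test_that("proportions sum to 1 per stratum and recover planted fractions", {
  f <- ct_fixture(medA = c(4, 4, 2, 2), medB = c(2, 2, 2, 2),
                  logFC = c(1, 1, 0.8, -0.9))
  props <- summarizeProportions(classifyCisTrans(f$de, f$map, f$prof,
                                                 "A", "B"))
  for (s in unique(props$stratum))
    expect_equal(sum(props$fraction[props$stratum == s]), 1)
  all_row <- props[props$stratum == "all", ]
  expect_equal(all_row$fraction[all_row$category == "GainUp"], 0.5)
  ## balanced 50/50 cis/trans
  expect_equal(sum(all_row$fraction[all_row$category %in%
    c("GainUp", "LossDown", "GainDown", "LossUp")]), 0.5)
})

test_that("boundary overlap fraction counts anti-correlated spanning genes", {
  f <- ct_fixture(medA = c(3, 3, 3, 2), medB = c(2, 2, 2, 2),
                  logFC = c(-1, -1, 1, 1))
  calls <- classifyCisTrans(f$de, f$map, f$prof, "A", "B")
  ## no spanning genes in this fixture
  expect_equal(boundaryOverlapFraction(calls), 0)
  calls$spans_boundary[1] <- TRUE   # one of the two anti-correlated genes
  expect_equal(boundaryOverlapFraction(calls), 0.5)
  calls$spans_boundary[1:2] <- TRUE
  expect_equal(boundaryOverlapFraction(calls), 1)
  expect_warning(val <- boundaryOverlapFraction(calls[3, , drop = FALSE]),
                 "anti-correlated")
  expect_true(is.nan(val))
})

test_that("generator boundary placement is recovered at the planted rate", {
  p <- simulationParams(frac_boundary = 0.15, seed = 47)
  truth <- simulateTruth(p)
  map <- mapGenesToBins(truth@genes, truth@bins)
  expect_equal(mean(map$spans_boundary), 0.15, tolerance = 0.02)
  ## map agrees with the generator's own flags
  expect_identical(map$spans_boundary,
                   unname(truth@genes$spans_boundary))
})
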