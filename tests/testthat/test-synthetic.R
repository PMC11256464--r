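test_that("prevalence dynamics follow the selection update", {
  ## equal fitness, 1 passage: symmetric prevalence
  p <- clean_params(seed = 2, n_clones = 2, n_passages = 1,
                    conditions = "UnRx", cells_per_sample = 2000,
                    rx_fitness = 1)
  truth <- simulateTruth(p)
  expect_equal(unname(truth@prevalence[1, ]), c(0.5, 0.5))
  counts <- table(truth@cell_truth$clone)
  expect_gt(stats::prop.test(counts[1], sum(counts), p = 0.5)$p.value,
            1e-4)

  ## clone B with 10x Rx fitness expands monotonically across Rx passages;
  ## closed-form check: p_B(t) = p0 s^t / (p0 s^t + (1-p0))
  p2 <- clean_params(seed = 3, n_clones = 2, n_passages = 4,
                     conditions = c("UnRx", "Rx"),
                     fitness = 1, rx_fitness = c(1, 10))
  t2 <- simulateTruth(p2)
  rx <- t2@prevalence[t2@sample_info$condition == "Rx", "B"]
  expect_true(all(diff(rx) >= 0))
  expected <- vapply(1:4, function(t) 0.5 * 10^t / (0.5 * 10^t + 0.5),
                     numeric(1))
  expect_equal(unname(rx), expected, tolerance = 1e-12)
})

test_that("prevalence rows are simplex and clone profiles distinct", {
  truth <- simulateTruth(simulationParams(n_clones = 4, seed = 9))
  expect_true(all(abs(rowSums(truth@prevalence) - 1) < 1e-9))
  cc <- truth@clone_cn
  for (i in 1:3) for (j in (i + 1):4)
    expect_gt(sum(cc[i, ] != cc[j, ]), 0)
  expect_true(all(cc >= 0 & cc <= 8))
})

test_that("same seed gives identical truth, cells and chip counts", {
  p <- simulationParams(cells_per_sample = 100, n_passages = 1, seed = 5)
  t1 <- simulateTruth(p); t2 <- simulateTruth(p)
  expect_identical(t1@clone_cn, t2@clone_cn)
  expect_identical(t1@cell_truth, t2@cell_truth)
  s1 <- simulateCells(t1); s2 <- simulateCells(t2)
  expect_identical(as.matrix(assay(s1$expr)), as.matrix(assay(s2$expr)))
  expect_identical(copyMatrix(s1$cn), copyMatrix(s2$cn))
  expect_identical(simulateChipCounts(t1), simulateChipCounts(t2))
})

test_that("generator validates degenerate parameters", {
  expect_error(simulationParams(n_clones = 1), "clones")
  expect_error(simulationParams(fitness = 0, rx_fitness = 0),
               "degenerate fitness")
  expect_error(simulationParams(frac_anticorrelated = 1.5), "fractions")
})

test_that("dosage law and treatment programs shape empirical means", {
  ## one clone so CN is the only dosage source; compare planted programs
  p <- simulationParams(n_clones = 2, n_passages = 1, cells_per_sample = 700,
                        frac_mouse_cells = 0, frac_lowqc_cells = 0,
                        frac_doublets = 0, frac_anticorrelated = 0,
                        seed = 13)
  truth <- simulateTruth(p)
  sim <- simulateCells(truth)
  ct <- truth@cell_truth
  m <- as.matrix(assay(sim$expr))
  prog <- truth@gene_program

  ## induced_reversible: mean(Rx)/mean(UnRx) ~ tau, mean(RxH)/mean(UnRx) ~ 1
  ## (cells of one clone to fix dosage)
  cl <- names(which.max(table(ct$clone)))
  pick <- function(cond) ct$cell_id[ct$clone == cl & ct$condition == cond]
  g <- names(prog)[prog == "induced_reversible"]
  g <- g[truth@base_mean[g] > 1]
  r_rx <- rowMeans(m[g, pick("Rx")]) / rowMeans(m[g, pick("UnRx")])
  r_rxh <- rowMeans(m[g, pick("RxH")]) / rowMeans(m[g, pick("UnRx")])
  expect_equal(mean(r_rx), p@tau_induced, tolerance = 0.1)
  expect_equal(mean(r_rxh), 1, tolerance = 0.1)

  ## per-gene empirical mean matches the generative mean within 5%
  ## over all >= 5000 UnRx+RxH... use UnRx cells of the modal clone
  cells <- ct$cell_id[ct$clone == cl & ct$condition == "UnRx"]
  dose <- (pmax(truth@clone_cn[cl, truth@genes$bin], 0.1) / 2) ^
    truth@dosage
  neutral <- names(prog)[prog == "neutral"]
  neutral <- neutral[truth@base_mean[neutral] >= 1]
  gen_mean <- truth@base_mean[neutral] *
    dose[match(neutral, truth@genes$gene_id)]
  ## library factors average ~ E[lognormal(0, .3)]
  lib <- exp(0.3^2 / 2)
  emp <- rowMeans(m[neutral, cells])
  ratio <- emp / (gen_mean * lib)
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("chip counts encode the class enrichment structure", {
  truth <- simulateTruth(simulationParams(seed = 4))
  chip <- simulateChipCounts(truth, enrichment = 5, base_rate = 50)
  lib <- attr(chip, "library_sizes")
  rpm <- function(col) chip[[col]] / lib[[col]] * 1e6
  act <- chip$class == "active"
  ctrl <- chip$class == "repressed_control"
  ## E[K4 RPM]/E[input RPM] = enrichment for active promoters
  expect_equal(mean(rpm("H3K4me3_1")[act]) / mean(rpm("input_1")[act]),
               5, tolerance = 0.1)
  ## control block matches the repressed class generative parameters
  repd <- chip$class == "repressed"
  expect_equal(mean(rpm("H3K27me3_1")[ctrl]),
               mean(rpm("H3K27me3_1")[repd]), tolerance = 0.15)
  expect_equal(mean(rpm("H3K4me3_1")[ctrl]),
               mean(rpm("H3K4me3_1")[repd]), tolerance = 0.15)
})

test_that("clone prevalence recovered from cell labels matches the update", {
  p <- clean_params(seed = 8, n_clones = 3, cells_per_sample = 1000,
                    n_passages = 2)
  truth <- simulateTruth(p)
  for (i in seq_len(nrow(truth@prevalence))) {
    smp <- rownames(truth@prevalence)[i]
    sub <- truth@cell_truth[truth@cell_truth$sample == smp, ]
    obs <- table(factor(sub$clone, colnames(truth@prevalence)))
    exp_p <- truth@prevalence[i, ]
    ## multinomial 99% CI per clone
    se <- sqrt(exp_p * (1 - exp_p) / nrow(sub))
    expect_true(all(abs(obs / nrow(sub) - exp_p) < 2.58 * se + 1e-9))
  }
})
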