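## shared fixture builders; everything generated in code

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SingleCellExperiment)
})

## tiny bin set on one chromosome
tiny_bins <- function(n = 3, width = 500) {
  GRanges("chr1", IRanges(start = (seq_len(n) - 1) * width + 1,
                          end = seq_len(n) * width))
}

## CNMatrix from an explicit cell x bin matrix
tiny_cn <- function(copy, clone, bins = tiny_bins(ncol(copy))) {
  rownames(copy) <- paste0("cell", seq_len(nrow(copy)))
  CNMatrix(copy, bins, clone)
}

## small clean simulation for parameter-recovery style tests
clean_params <- function(seed, ...) {
  simulationParams(
    program_sizes = c(induced_fixed = 0, induced_reversible = 0,
                      repressed_fixed = 0, repressed_reversible = 0),
    frac_anticorrelated = 0, frac_mouse_cells = 0, frac_lowqc_cells = 0,
    frac_doublets = 0, seed = seed, ...)
}

## counts matrix of NB genes x cells with given per-gene means
nb_counts <- function(mu, n_cells, size = 2, prefix = "c") {
  x <- matrix(stats::rnbinom(length(mu) * n_cells, mu = mu, size = size),
              nrow = length(mu))
  rownames(x) <- if (is.null(names(mu))) paste0("g", seq_along(mu))
                 else names(mu)
  colnames(x) <- paste0(prefix, seq_len(n_cells))
  x
}

## brute-force BH adjustment (independent oracle)
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## hand-built SCE with one planted violation of each QC rule
qc_fixture <- function() {
  set.seed(31)
  n_genes <- 1500
  genes <- c(sprintf("G%04d", seq_len(n_genes)), "MT-1", "MT-2",
             "RPS1", "RPL1", "mm_G1")
  good <- function() {
    x <- numeric(length(genes)); names(x) <- genes
    x[seq_len(1200)] <- rpois(1200, 3) + 1      # 1200 detected genes
    x["MT-1"] <- round(sum(x) * 0.05)           # ~5% mito
    x["RPS1"] <- round(sum(x) * 0.10)
    x
  }
  cells <- replicate(30, good(), simplify = TRUE)
  colnames(cells) <- paste0("ok", 1:30)
  ## planted violations
  v_genes <- good(); v_genes[seq_len(1500)] <- 0
  v_genes[seq_len(997)] <- 5   # 997 + 2 mito/ribo = 999 detected genes
  v_mito <- good(); v_mito["MT-1"] <- sum(v_mito) * 0.5
  v_ribo <- good(); v_ribo["RPL1"] <- sum(v_ribo) * 2      # >60% ribo
  v_count <- good() * 0.05                      # tiny library
  v_count[v_count > 0] <- pmax(round(v_count[v_count > 0]), 1)
  v_mouse <- good(); v_mouse["mm_G1"] <- sum(v_mouse) + 10
  bad <- cbind(v_genes, v_mito, v_ribo, v_count, v_mouse)
  m <- cbind(cells, bad)
  SingleCellExperiment(assays = list(
    counts = Matrix::Matrix(m, sparse = TRUE)))
}

## brute-force weighted KS enrichment score (independent oracle)
es_brute <- function(scores, set, p = 1) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  hit <- names(s) %in% set
  w <- abs(s)^p
  run <- 0; best <- 0
  for (i in seq_along(s)) {
    if (hit[i]) run <- run + w[i] / sum(w[hit])
    else run <- run - 1 / sum(!hit)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}
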