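## Synthetic PDX time-series generator.
##
## Ground truth is fully specified: multi-clone segmental copy-number
## profiles on fixed-width bins, clone prevalences evolving by deterministic
## selection followed by multinomial resampling, dosage-coupled
## negative-binomial UMI counts with treatment-responsive gene programs,
## mouse-cell and low-quality-cell contamination, and promoter ChIP counts
## with Active/Bivalent/Repressed enrichment structure.

BIN_WIDTH <- 5e5L
MITO_GENES <- paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6",
                              "CO3", "ND3", "ND4L", "ND4", "ND5", "ND6",
                              "CYB"))
RIBO_GENES <- c(paste0("RPS", 1:10), paste0("RPL", 1:10))
MOUSE_GENES <- sprintf("mm_Gene%02d", 1:50)

#' Construct simulation parameters
#'
#' Defaults describe the study conditions the generator emulates: 200
#' 500-kb-style bins, 3 clones with a minor clone carrying strong fitness
#' under drug (so a clonal sweep occurs under treatment), 4 passages under
#' each of UnRx/Rx/RxH, negative-binomial counts with shared dispersion 2,
#' a 2-fold induced and 0.5-fold repressed treatment program split into
#' holiday-reversible and holiday-fixed halves, and small mouse / low-quality
#' contamination fractions.
#'
#' @param n_bins,n_clones,genes_per_bin,n_passages,cells_per_sample counts.
#' @param conditions condition labels, subset of \code{c("UnRx","Rx","RxH")}.
#' @param fitness per-clone growth multipliers without drug (recycled).
#' @param rx_fitness per-clone growth multipliers under drug; default gives
#'   the last clone a 6-fold advantage (a clonal-sweep scenario).
#' @param initial_prevalence optional starting clone prevalences;
#'   default uniform.
#' @param dosage_exponent dosage-law exponent for dosage-following genes.
#' @param frac_anticorrelated fraction of genes with exponent -1.
#' @param frac_boundary fraction of genes placed across a bin boundary.
#' @param nb_dispersion NB size parameter (Var = mu + mu^2/size).
#' @param program_sizes named counts of induced_fixed, induced_reversible,
#'   repressed_fixed, repressed_reversible genes.
#' @param tau_induced,tau_repressed treatment fold-effects.
#' @param frac_mouse_cells,frac_lowqc_cells,frac_doublets contamination.
#' @param flip_rate per-bin copy-state flip noise of per-cell CN calls.
#' @param seed RNG seed.
#' @return a \linkS4class{SimulationParams} object.
#' @examples
#' simulationParams(n_clones = 2, seed = 1)
#' @export
simulationParams <- function(n_bins = 200, n_clones = 3, genes_per_bin = 12,
                             n_passages = 4,
                             conditions = c("UnRx", "Rx", "RxH"),
                             cells_per_sample = 500,
                             fitness = 1,
                             rx_fitness = NULL,
                             initial_prevalence = NULL,
                             dosage_exponent = 1,
                             frac_anticorrelated = 0.03,
                             frac_boundary = 0.1,
                             nb_dispersion = 2,
                             program_sizes = c(induced_fixed = 50,
                                               induced_reversible = 50,
                                               repressed_fixed = 50,
                                               repressed_reversible = 50),
                             tau_induced = 2, tau_repressed = 0.5,
                             frac_mouse_cells = 0.05,
                             frac_lowqc_cells = 0.05,
                             frac_doublets = 0.02,
                             flip_rate = 0.01,
                             seed = 1L) {
  fitness <- rep_len(fitness, n_clones)
  if (is.null(rx_fitness))
    rx_fitness <- c(rep(1, n_clones - 1), 6)
  rx_fitness <- rep_len(rx_fitness, n_clones)
  ps <- c(induced_fixed = 0L, induced_reversible = 0L,
          repressed_fixed = 0L, repressed_reversible = 0L)
  ps[names(program_sizes)] <- as.integer(program_sizes)
  new("SimulationParams",
      n_bins = as.integer(n_bins), n_clones = as.integer(n_clones),
      genes_per_bin = as.integer(genes_per_bin),
      n_passages = as.integer(n_passages), conditions = conditions,
      cells_per_sample = as.integer(cells_per_sample),
      fitness = fitness, rx_fitness = rx_fitness,
      initial_prevalence = if (is.null(initial_prevalence)) numeric(0)
                           else rep_len(initial_prevalence, n_clones),
      dosage_exponent = dosage_exponent,
      frac_anticorrelated = frac_anticorrelated,
      frac_boundary = frac_boundary, nb_dispersion = nb_dispersion,
      program_sizes = ps, tau_induced = tau_induced,
      tau_repressed = tau_repressed,
      frac_mouse_cells = frac_mouse_cells,
      frac_lowqc_cells = frac_lowqc_cells,
      frac_doublets = frac_doublets, flip_rate = flip_rate,
      seed = as.integer(seed))
}

## segmental copy-state draw around ploidy 2, states 0..8
.segmental_profile <- function(n_bins, mean_seg = 15) {
  state_probs <- c(0.01, 0.08, 0.52, 0.20, 0.10, 0.05, 0.02, 0.01, 0.01)
  cn <- integer(0)
  while (length(cn) < n_bins) {
    len <- 1L + stats::rgeom(1, 1 / mean_seg)
    cn <- c(cn, rep(sample(0:8, 1, prob = state_probs), len))
  }
  cn[seq_len(n_bins)]
}

.mutate_profile <- function(cn, n_events, mean_seg = 10) {
  n_bins <- length(cn)
  for (i in seq_len(n_events)) {
    len <- min(n_bins, 1L + stats::rgeom(1, 1 / mean_seg))
    s <- sample(seq_len(n_bins - len + 1L), 1)
    delta <- sample(c(-2L, -1L, 1L, 2L), 1, prob = c(0.15, 0.35, 0.35, 0.15))
    idx <- s:(s + len - 1L)
    cn[idx] <- pmin(8L, pmax(0L, cn[idx] + delta))
  }
  cn
}

.make_bins <- function(n_bins) {
  n_chrom <- max(1L, min(4L, n_bins %/% 25L))
  per <- rep(n_bins %/% n_chrom, n_chrom)
  per[seq_len(n_bins %% n_chrom)] <- per[seq_len(n_bins %% n_chrom)] + 1L
  chrom <- rep(paste0("chr", seq_len(n_chrom)), per)
  idx <- unlist(lapply(per, seq_len))
  GRanges(chrom, IRanges(start = (idx - 1L) * BIN_WIDTH + 1L,
                         end = idx * BIN_WIDTH))
}

## place genes_per_bin genes inside each bin; a frac_boundary subset
## straddles the boundary to the next bin on the same chromosome, with the
## majority of its length in its home bin
.make_genes <- function(bins, genes_per_bin, frac_boundary) {
  n_bins <- length(bins)
  n_genes <- n_bins * genes_per_bin
  chrom <- rep(as.character(seqnames(bins)), each = genes_per_bin)
  bin_start <- rep(start(bins), each = genes_per_bin)
  bin_end <- rep(end(bins), each = genes_per_bin)
  bin_idx <- rep(seq_len(n_bins), each = genes_per_bin)
  slot_in_bin <- rep(seq_len(genes_per_bin), n_bins)
  width <- 10000L
  gap <- (BIN_WIDTH - 20000L) %/% genes_per_bin
  gstart <- bin_start + 5000L + (slot_in_bin - 1L) * gap
  gend <- gstart + width - 1L
  ## boundary genes: last two slots of eligible bins straddle the boundary
  ## to the next bin, with the majority of their length in the home bin
  last_bin_of_chrom <- bin_idx == stats::ave(bin_idx, chrom, FUN = max)
  eligible <- slot_in_bin >= genes_per_bin - 1L & !last_bin_of_chrom
  n_boundary <- round(frac_boundary * n_genes)
  pick <- which(eligible)
  pick <- pick[seq_len(min(n_boundary, length(pick)))]
  inside <- ifelse(slot_in_bin[pick] == genes_per_bin, 5999L, 6999L)
  gstart[pick] <- bin_end[pick] - inside
  gend[pick] <- gstart[pick] + width - 1L
  spans <- logical(n_genes); spans[pick] <- TRUE
  gr <- GRanges(chrom, IRanges(gstart, gend),
                strand = rep(c("+", "-"), length.out = n_genes))
  gr$gene_id <- sprintf("G%04d", seq_len(n_genes))
  gr$bin <- bin_idx
  gr$spans_boundary <- spans
  names(gr) <- gr$gene_id
  gr
}

#' Simulate the ground truth of one PDX time series
#'
#' Clone copy-number profiles are drawn as segmental Markov chains around
#' ploidy 2 (states capped at 0..8). Clone prevalences start with the
#' designated drug-resistant clone minor and evolve per passage by the
#' deterministic selection update p'_k = p_k s_k / sum_j p_j s_j, with the
#' drug fitness map applied under Rx (and for all but the final passage of an
#' RxH line); the realized sample composition is a multinomial resample of
#' \code{cells_per_sample} cells from the deterministic prevalence.
#'
#' @param params a \linkS4class{SimulationParams} object.
#' @return a \linkS4class{SyntheticTruth} object.
#' @examples
#' truth <- simulateTruth(simulationParams(n_clones = 2, seed = 7))
#' truth
#' @export
simulateTruth <- function(params) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  set.seed(params@seed)
  K <- params@n_clones
  clones <- LETTERS[seq_len(K)]

  ## clone CN profiles: shared ancestor plus clone-private events
  repeat {
    anc <- .segmental_profile(params@n_bins)
    clone_cn <- t(vapply(seq_len(K), function(k)
      .mutate_profile(anc, n_events = 4L + (k %% 3L)),
      integer(params@n_bins)))
    dup <- FALSE
    for (i in seq_len(K - 1)) for (j in seq(i + 1, K))
      if (all(clone_cn[i, ] == clone_cn[j, ])) dup <- TRUE
    if (!dup) break
  }
  dimnames(clone_cn) <- list(clones, NULL)

  bins <- .make_bins(params@n_bins)
  genes <- .make_genes(bins, params@genes_per_bin, params@frac_boundary)
  n_genes <- length(genes)

  ## prevalence trajectories: resistant clone (max rx fitness) starts minor
  p0 <- params@initial_prevalence
  if (!length(p0)) p0 <- rep(1 / K, K)
  p0 <- p0 / sum(p0)

  sample_info <- expand.grid(condition = params@conditions,
                             passage = seq_len(params@n_passages),
                             stringsAsFactors = FALSE)
  sample_info <- sample_info[, c("passage", "condition")]
  sample_info$sample <- paste0("X", sample_info$passage, "_",
                               sample_info$condition)
  prevalence <- t(vapply(seq_len(nrow(sample_info)), function(i) {
    t <- sample_info$passage[i]
    cond <- sample_info$condition[i]
    w <- switch(cond,
      UnRx = p0 * params@fitness ^ t,
      Rx   = p0 * params@rx_fitness ^ t,
      RxH  = p0 * params@rx_fitness ^ (t - 1) * params@fitness)
    w / sum(w)
  }, numeric(K)))
  dimnames(prevalence) <- list(sample_info$sample, clones)

  ## gene programs
  program <- rep("neutral", n_genes)
  names(program) <- genes$gene_id
  ps <- params@program_sizes
  n_anti <- round(params@frac_anticorrelated * n_genes)
  picks <- sample(n_genes, sum(ps) + n_anti)
  program[picks[seq_len(sum(ps))]] <- rep(names(ps), ps)
  anti <- picks[seq_len(n_anti) + sum(ps)]
  program[anti] <- "anticorrelated"
  dosage <- rep(params@dosage_exponent, n_genes)
  names(dosage) <- genes$gene_id
  dosage[anti] <- -1

  chrom_class <- sample(c("active", "bivalent", "repressed"),
                        sum(ps), replace = TRUE)
  names(chrom_class) <- names(program)[program %in% names(ps)]

  base_mean <- stats::rlnorm(n_genes, meanlog = log(1.5), sdlog = 1)
  names(base_mean) <- genes$gene_id

  ## cells: multinomial resample per sample, then contamination flags
  cell_truth <- do.call(rbind, lapply(seq_len(nrow(sample_info)), function(i) {
    counts <- as.vector(stats::rmultinom(1, params@cells_per_sample,
                                         prevalence[i, ]))
    clone <- rep(clones, counts)
    n <- length(clone)
    data.frame(cell_id = sprintf("%s_c%04d", sample_info$sample[i],
                                 seq_len(n)),
               sample = sample_info$sample[i],
               passage = sample_info$passage[i],
               condition = sample_info$condition[i],
               clone = clone,
               is_mouse = seq_len(n) %in%
                 sample(n, round(params@frac_mouse_cells * n)),
               stringsAsFactors = FALSE)
  }))
  n_cells <- nrow(cell_truth)
  cell_truth$is_lowqc <- FALSE
  human <- which(!cell_truth$is_mouse)
  cell_truth$is_lowqc[sample(human,
    round(params@frac_lowqc_cells * length(human)))] <- TRUE
  cell_truth$is_doublet <- FALSE
  ok <- which(!cell_truth$is_mouse & !cell_truth$is_lowqc)
  cell_truth$is_doublet[sample(ok,
    round(params@frac_doublets * length(ok)))] <- TRUE
  rownames(cell_truth) <- cell_truth$cell_id

  new("SyntheticTruth", clone_cn = clone_cn, bins = bins, genes = genes,
      prevalence = prevalence, sample_info = sample_info,
      gene_program = program, chromatin_class = chrom_class,
      base_mean = base_mean, dosage = dosage, cell_truth = cell_truth,
      params = params)
}

## treatment fold-effect tau_g(condition) per gene
.tau_matrix <- function(truth) {
  p <- truth@params
  prog <- truth@gene_program
  tau <- matrix(1, nrow = length(prog), ncol = 3,
                dimnames = list(names(prog), c("UnRx", "Rx", "RxH")))
  ind <- grepl("^induced", prog); rep_ <- grepl("^repressed", prog)
  fixed <- grepl("fixed$", prog)
  tau[ind, "Rx"] <- p@tau_induced
  tau[rep_, "Rx"] <- p@tau_repressed
  tau[ind & fixed, "RxH"] <- p@tau_induced
  tau[rep_ & fixed, "RxH"] <- p@tau_repressed
  tau
}

#' Simulate per-cell copy-number calls and UMI counts
#'
#' UMI counts follow NegativeBinomial(mean = L_c mu_g (c_gk/2)^delta_g
#' tau_g(condition), size = nb_dispersion), where c_gk is the copy state of
#' the cell's clone at the gene's bin (floored at 0.1 so anti-correlated
#' exponents stay finite), L_c is a lognormal library factor, and tau encodes
#' the treatment program (induced genes up under Rx, and under RxH iff fixed;
#' repressed genes mirrored). Mouse cells emit counts predominantly on a
#' disjoint \code{mm_}-prefixed feature set; low-quality cells have inflated
#' mitochondrial fraction and depressed gene detection. Per-cell CN calls are
#' the clone profile with per-bin flip noise.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param params the \linkS4class{SimulationParams} used to build it.
#' @return list with \code{cn} (a \linkS4class{CNMatrix} over the clean human
#'   cells) and \code{expr} (a \link[SingleCellExperiment]{SingleCellExperiment}
#'   over all cells, with truth flags in \code{colData}).
#' @export
simulateCells <- function(truth, params = truth@params) {
  stopifnot(is(truth, "SyntheticTruth"))
  if (any(truth@base_mean <= 0)) stop("zero base_mean for a gene")
  set.seed(params@seed + 1L)
  ct <- truth@cell_truth
  n_cells <- nrow(ct)
  genes <- truth@genes
  n_genes <- length(genes)
  disp <- params@nb_dispersion

  ## per-clone per-gene dosage factor
  cn_gene <- truth@clone_cn[, genes$bin, drop = FALSE]  # clone x gene
  dos <- (pmax(cn_gene, 0.1) / 2) ^
    matrix(truth@dosage, nrow = nrow(cn_gene), ncol = n_genes, byrow = TRUE)
  tau <- .tau_matrix(truth)

  L <- stats::rlnorm(n_cells, 0, 0.3)
  L[ct$is_lowqc] <- L[ct$is_lowqc] * 0.3

  features <- c(genes$gene_id, MITO_GENES, RIBO_GENES, MOUSE_GENES)
  counts <- matrix(0, nrow = n_cells, ncol = length(features),
                   dimnames = list(ct$cell_id, features))

  grp <- interaction(ct$clone, ct$condition, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    k <- ct$clone[idx[1]]; cond <- ct$condition[idx[1]]
    gene_mean <- truth@base_mean * dos[k, ] * tau[, cond]
    mu <- outer(L[idx], gene_mean)
    human_total <- sum(gene_mean)
    ## mito ~5% and ribo ~20% of the human transcriptome; low-QC cells get
    ## a mito load comparable to their depressed human signal
    mito_mean <- outer(L[idx], rep(human_total * 0.0667 / 13, 13))
    mito_mean[ct$is_lowqc[idx], ] <- mito_mean[ct$is_lowqc[idx], ] * 15
    ribo_mean <- outer(L[idx], rep(human_total * 0.25 / 20, 20))
    mouse_mean <- outer(L[idx], rep(human_total * 0.005 / 50, 50))
    ## mouse cells: human signal collapses, mouse features dominate
    m <- ct$is_mouse[idx]
    if (any(m)) {
      mu[m, ] <- mu[m, ] * 0.02
      mito_mean[m, ] <- mito_mean[m, ] * 0.02
      ribo_mean[m, ] <- ribo_mean[m, ] * 0.02
      mouse_mean[m, ] <- outer(L[idx][m], rep(human_total * 1.0 / 50, 50))
    }
    mm <- cbind(mu, mito_mean, ribo_mean, mouse_mean)
    counts[idx, ] <- matrix(
      stats::rnbinom(length(mm), mu = as.vector(mm), size = disp),
      nrow = length(idx))
  }

  rd <- DataFrame(
    gene_id = features,
    type = rep(c("gene", "mito", "ribo", "mouse"),
               c(n_genes, length(MITO_GENES), length(RIBO_GENES),
                 length(MOUSE_GENES))),
    row.names = features)
  cd <- DataFrame(ct[, c("cell_id", "sample", "passage", "condition",
                         "clone", "is_mouse", "is_lowqc", "is_doublet")],
                  row.names = ct$cell_id)
  expr <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(t(counts), sparse = TRUE)),
    rowData = rd, colData = cd)

  ## DLP-style CN matrix over clean human cells
  keep <- !ct$is_mouse & !ct$is_lowqc
  prof <- truth@clone_cn[ct$clone[keep], , drop = FALSE]
  flip <- matrix(stats::runif(length(prof)) < params@flip_rate,
                 nrow = nrow(prof))
  delta <- matrix(sample(c(-1L, 1L), length(prof), replace = TRUE),
                  nrow = nrow(prof))
  copy <- prof + flip * delta
  copy[copy < 0] <- 0L
  copy[copy > 8] <- 8L
  storage.mode(copy) <- "integer"
  rownames(copy) <- ct$cell_id[keep]
  clone <- ct$clone[keep]
  names(clone) <- ct$cell_id[keep]
  cn <- new("CNMatrix", copy = copy, bins = truth@bins, clone = clone)

  list(cn = cn, expr = expr)
}

#' Simulate promoter ChIP-seq counts
#'
#' Per-promoter Poisson counts for H3K4me3, H3K27me3 and input (2 replicates
#' each) over the program genes' chromatin classes, plus a repressed control
#' block. Expected ChIP/input RPM ratio equals the class enrichment factor:
#' active promoters are K4-high/K27-low, bivalent K4-high/K27-high,
#' repressed K4-low/K27-high.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param params the matching \linkS4class{SimulationParams}.
#' @param classes optional named character overriding the truth's chromatin
#'   classes (values in active/bivalent/repressed).
#' @param enrichment fold-enrichment of marked promoters over input.
#' @param base_rate expected input reads per promoter at library size 1e6.
#' @param n_control size of the repressed control block.
#' @return data.frame with promoter coordinates, truth class, six count
#'   columns and a \code{library_sizes} attribute; the control block genes
#'   are prefixed \code{ctrl_}.
#' @export
simulateChipCounts <- function(truth, params = truth@params, classes = NULL,
                               enrichment = 5, base_rate = 20,
                               n_control = 500) {
  stopifnot(is(truth, "SyntheticTruth"))
  set.seed(params@seed + 2L)
  if (is.null(classes)) classes <- truth@chromatin_class
  if (!all(classes %in% c("active", "bivalent", "repressed")))
    stop("chromatin classes must be active/bivalent/repressed")

  genes <- truth@genes[names(classes)]
  prom <- promoterWindows(genes)
  tab <- data.frame(gene = names(classes),
                    chrom = as.character(seqnames(prom)),
                    start = start(prom) - 1L, end = end(prom),
                    class = unname(classes), stringsAsFactors = FALSE)
  ctrl <- data.frame(gene = sprintf("ctrl_%04d", seq_len(n_control)),
                     chrom = "chrC",
                     start = (seq_len(n_control) - 1L) * 4000L,
                     end = (seq_len(n_control) - 1L) * 4000L + 2000L,
                     class = "repressed_control", stringsAsFactors = FALSE)
  tab <- rbind(tab, ctrl)

  k4 <- ifelse(tab$class %in% c("active", "bivalent"), enrichment, 1)
  k27 <- ifelse(tab$class == "active", 1, enrichment)
  lib <- c(H3K4me3_1 = 1.0e6, H3K4me3_2 = 1.2e6,
           H3K27me3_1 = 0.9e6, H3K27me3_2 = 1.1e6,
           input_1 = 1.5e6, input_2 = 1.4e6)
  fac <- list(H3K4me3_1 = k4, H3K4me3_2 = k4,
              H3K27me3_1 = k27, H3K27me3_2 = k27,
              input_1 = rep(1, nrow(tab)), input_2 = rep(1, nrow(tab)))
  for (tr in names(lib))
    tab[[tr]] <- stats::rpois(nrow(tab),
                              base_rate * fac[[tr]] * lib[[tr]] / 1e6)
  attr(tab, "library_sizes") <- lib
  tab
}
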