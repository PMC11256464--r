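#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand findOverlaps pintersect promoters
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits DataFrame metadata metadata<-
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Simulation parameters for the synthetic PDX time-series generator
#'
#' Holds every tunable of the ground-truth generator: genome layout
#' (\code{n_bins} fixed-width bins emulating 500-kb copy-number regions,
#' \code{genes_per_bin} genes placed inside each bin), clonal structure
#' (\code{n_clones} copy-number clones with per-clone relative growth
#' multipliers \code{fitness} under no treatment and \code{rx_fitness} under
#' drug), the sampling design (\code{n_passages} serial passages under each
#' condition in \code{conditions}, \code{cells_per_sample} cells each), and
#' the expression model (per-gene dosage exponent, negative-binomial
#' dispersion, treatment-responsive gene program sizes, contamination
#' fractions).
#'
#' @slot n_bins integer, number of genomic bins.
#' @slot n_clones integer, number of copy-number clones (>= 2).
#' @slot genes_per_bin integer, genes placed per bin.
#' @slot n_passages integer, passages per condition line.
#' @slot conditions character, condition labels (subset of UnRx/Rx/RxH).
#' @slot cells_per_sample integer, cells drawn per sample.
#' @slot fitness numeric, per-clone growth multiplier without drug.
#' @slot rx_fitness numeric, per-clone growth multiplier under drug.
#' @slot initial_prevalence numeric, starting clone prevalences
#'   (empty = uniform).
#' @slot dosage_exponent numeric scalar, exponent delta of the dosage law
#'   mean ~ (cn/2)^delta for dosage-following genes.
#' @slot frac_anticorrelated numeric, fraction of genes with delta = -1.
#' @slot frac_boundary numeric, fraction of genes straddling a bin boundary.
#' @slot nb_dispersion numeric, shared NB size parameter
#'   (Var = mu + mu^2/size).
#' @slot program_sizes integer, named counts for induced_fixed,
#'   induced_reversible, repressed_fixed, repressed_reversible genes.
#' @slot tau_induced,tau_repressed numeric, treatment fold-effects of the
#'   induced / repressed programs.
#' @slot frac_mouse_cells,frac_lowqc_cells,frac_doublets numeric fractions.
#' @slot flip_rate numeric, per-bin copy-state flip noise in per-cell CN.
#' @slot seed integer, RNG seed.
#' @export
setClass("SimulationParams",
  slots = c(
    n_bins = "integer", n_clones = "integer", genes_per_bin = "integer",
    n_passages = "integer", conditions = "character",
    cells_per_sample = "integer",
    fitness = "numeric", rx_fitness = "numeric",
    initial_prevalence = "numeric",
    dosage_exponent = "numeric", frac_anticorrelated = "numeric",
    frac_boundary = "numeric", nb_dispersion = "numeric",
    program_sizes = "integer",
    tau_induced = "numeric", tau_repressed = "numeric",
    frac_mouse_cells = "numeric", frac_lowqc_cells = "numeric",
    frac_doublets = "numeric", flip_rate = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character()
  fr <- c(object@frac_anticorrelated, object@frac_boundary,
          object@frac_mouse_cells, object@frac_lowqc_cells,
          object@frac_doublets, object@flip_rate)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "all fractions must be in [0, 1]")
  if (object@n_clones < 2L) msg <- c(msg, "need >=2 clones")
  if (any(!is.finite(object@fitness)) || any(object@fitness < 0) ||
      any(!is.finite(object@rx_fitness)) || any(object@rx_fitness < 0))
    msg <- c(msg, "fitness values must be finite and >= 0")
  if (all(object@fitness == 0) || all(object@rx_fitness == 0))
    msg <- c(msg, "degenerate fitness: all zero")
  if (length(object@fitness) != object@n_clones ||
      length(object@rx_fitness) != object@n_clones)
    msg <- c(msg, "fitness maps must have one entry per clone")
  if (object@nb_dispersion <= 0) msg <- c(msg, "nb_dispersion must be > 0")
  if (!all(object@conditions %in% c("UnRx", "Rx", "RxH")))
    msg <- c(msg, "conditions must be in {UnRx, Rx, RxH}")
  if (length(msg)) msg else TRUE
})

#' Ground truth of one simulated PDX time series
#'
#' @slot clone_cn integer matrix clone x bin, copy states in 0..8.
#' @slot bins GRanges of the genomic bins.
#' @slot genes GRanges of simulated genes (with gene_id, bin, spans_boundary).
#' @slot prevalence numeric matrix sample x clone; rows sum to 1. These are
#'   the deterministic selection-update prevalences before multinomial
#'   resampling.
#' @slot sample_info data.frame with sample, passage, condition.
#' @slot gene_program named character: neutral, induced_fixed,
#'   induced_reversible, repressed_fixed, repressed_reversible,
#'   anticorrelated.
#' @slot chromatin_class named character for program genes: active, bivalent,
#'   repressed.
#' @slot base_mean named numeric, per-gene baseline mean mu_g > 0.
#' @slot dosage named numeric, per-gene dosage exponent.
#' @slot cell_truth data.frame: cell_id, sample, passage, condition, clone,
#'   is_mouse, is_lowqc, is_doublet.
#' @slot params the SimulationParams used.
#' @export
setClass("SyntheticTruth",
  slots = c(
    clone_cn = "matrix", bins = "GRanges", genes = "GRanges",
    prevalence = "matrix", sample_info = "data.frame",
    gene_program = "character", chromatin_class = "character",
    base_mean = "numeric", dosage = "numeric",
    cell_truth = "data.frame", params = "SimulationParams"
  )
)

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (any(abs(rowSums(object@prevalence) - 1) > 1e-9))
    msg <- c(msg, "prevalence rows must sum to 1")
  cc <- object@clone_cn
  if (nrow(cc) >= 2) {
    for (i in seq_len(nrow(cc) - 1)) for (j in seq(i + 1, nrow(cc)))
      if (all(cc[i, ] == cc[j, ]))
        msg <- c(msg, "clone_cn rows must differ pairwise in >=1 bin")
  }
  if (any(cc < 0 | cc > 8)) msg <- c(msg, "copy states must lie in 0..8")
  if (length(msg)) msg else TRUE
})

#' Per-cell integer copy-number matrix on fixed genomic bins
#'
#' DLP-style measurement: one integer copy state per cell per fixed-width
#' genomic bin, plus a clone label per cell (from an upstream phylogeny).
#'
#' @slot copy integer matrix cells x bins.
#' @slot bins GRanges, sorted, non-overlapping within chromosome.
#' @slot clone named character, clone label per cell.
#' @export
setClass("CNMatrix",
  slots = c(copy = "matrix", bins = "GRanges", clone = "character"))

setValidity("CNMatrix", function(object) {
  msg <- character()
  if (ncol(object@copy) != length(object@bins))
    msg <- c(msg, "ncol(copy) must equal length(bins)")
  if (any(object@copy < 0)) msg <- c(msg, "copy values must be >= 0")
  if (any(object@copy != round(object@copy)))
    msg <- c(msg, "copy values must be integers")
  if (length(object@clone) &&
      (is.null(names(object@clone)) ||
       !identical(names(object@clone), rownames(object@copy))))
    msg <- c(msg, "clone labels must be named by the cells of copy")
  sp <- split(object@bins, as.character(seqnames(object@bins)))
  for (gr in sp) {
    if (length(gr) < 2) next
    s <- start(gr); e <- end(gr)
    o <- order(s)
    if (any(e[o][-length(o)] >= s[o][-1]))
      msg <- c(msg, "bins overlap within a chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Per-clone median copy-number profiles
#'
#' @slot median_cn numeric matrix clone x bin; medians of integer copy states
#'   are kept exact (possibly half-integer).
#' @slot bins GRanges of the bins.
#' @slot n_cells named integer, member-cell count per clone.
#' @export
setClass("CloneProfileSet",
  slots = c(median_cn = "matrix", bins = "GRanges", n_cells = "integer"))

#' Probabilistic clone assignment of scRNA-seq cells
#'
#' @slot clone named character, MAP clone per assigned cell (NA when below
#'   the posterior floor).
#' @slot posterior numeric matrix cells x clones, rows sum to 1.
#' @slot genes_used character, dosage-informative genes used by the model.
#' @slot log_lik numeric, EM log-likelihood trace of the best restart.
#' @slot dropped_cells character, cells below min_counts_per_cell.
#' @slot params list of assignment parameters used.
#' @export
setClass("CloneAssignment",
  slots = c(clone = "character", posterior = "matrix",
            genes_used = "character", log_lik = "numeric",
            dropped_cells = "character", params = "list"))

setValidity("CloneAssignment", function(object) {
  if (nrow(object@posterior) &&
      any(abs(rowSums(object@posterior) - 1) > 1e-8))
    "posterior rows must sum to 1" else TRUE
})

#' Lineages inferred over a cluster minimum spanning tree
#'
#' @slot clusters named integer, cluster id per cell.
#' @slot centroids numeric matrix cluster x PC.
#' @slot mst_edges integer matrix of MST edges (cluster pairs).
#' @slot lineages list of integer vectors, root-to-leaf cluster paths.
#' @slot pseudotime numeric matrix cells x lineages in [0,1]; NA off-lineage.
#' @slot weights numeric matrix cells x lineages in [0,1].
#' @slot pca numeric matrix cells x PC.
#' @slot start_cluster integer, root cluster id.
#' @export
setClass("LineageSet",
  slots = c(clusters = "integer", centroids = "matrix", mst_edges = "matrix",
            lineages = "list", pseudotime = "matrix", weights = "matrix",
            pca = "matrix", start_cluster = "integer"))

#' Gene modules over smoothed pseudotime curves
#'
#' @slot modules named integer, module id per gene.
#' @slot curves list: per module, a matrix grid x lineage of scaled mean
#'   curves in [-2, 2].
#' @slot grid numeric, common pseudotime grid.
#' @slot status named character, promoter chromatin status per module
#'   (filled by the chromatin stage; NA until then).
#' @export
setClass("GeneModuleSet",
  slots = c(modules = "integer", curves = "list", grid = "numeric",
            status = "character"))

## ---- show methods -------------------------------------------------------

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams:", object@n_clones, "clones,", object@n_bins,
      "bins x", object@genes_per_bin, "genes/bin,",
      object@n_passages, "passages x {",
      paste(object@conditions, collapse = ", "), "},",
      object@cells_per_sample, "cells/sample, seed", object@seed, "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@clone_cn), "clones,",
      length(object@bins), "bins,", length(object@genes), "genes,",
      nrow(object@sample_info), "samples,", nrow(object@cell_truth),
      "cells\n")
  cat("  gene program:",
      paste(names(table(object@gene_program)), table(object@gene_program),
            sep = "=", collapse = ", "), "\n")
})

setMethod("show", "CNMatrix", function(object) {
  cat("CNMatrix:", nrow(object@copy), "cells x", ncol(object@copy),
      "bins;", length(unique(object@clone)), "clones\n")
})

setMethod("show", "CloneProfileSet", function(object) {
  cat("CloneProfileSet:", nrow(object@median_cn), "clones x",
      ncol(object@median_cn), "bins; cells/clone:",
      paste(names(object@n_cells), object@n_cells, sep = "=",
            collapse = ", "), "\n")
})

setMethod("show", "CloneAssignment", function(object) {
  tab <- table(object@clone, useNA = "ifany")
  cat("CloneAssignment:", nrow(object@posterior), "cells,",
      ncol(object@posterior), "clones,", length(object@genes_used),
      "genes;", length(object@dropped_cells), "cells dropped\n")
  cat("  MAP counts:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "LineageSet", function(object) {
  cat("LineageSet:", length(object@clusters), "cells,",
      nrow(object@centroids), "clusters,", length(object@lineages),
      "lineages from cluster", object@start_cluster, "\n")
})

setMethod("show", "GeneModuleSet", function(object) {
  tab <- table(object@modules)
  cat("GeneModuleSet:", length(object@modules), "genes in", length(tab),
      "modules (", paste(names(tab), tab, sep = ":", collapse = ", "),
      ")\n")
})

## ---- accessors ----------------------------------------------------------

#' @rdname CNMatrix-class
#' @param object a \code{CNMatrix} or \code{CloneProfileSet}.
#' @export
setGeneric("copyMatrix", function(object) standardGeneric("copyMatrix"))
#' @rdname CNMatrix-class
#' @export
setMethod("copyMatrix", "CNMatrix", function(object) object@copy)

#' @rdname CNMatrix-class
#' @export
setGeneric("cloneLabels", function(object) standardGeneric("cloneLabels"))
#' @rdname CNMatrix-class
#' @export
setMethod("cloneLabels", "CNMatrix", function(object) object@clone)
#' @rdname CNMatrix-class
#' @export
setMethod("cloneLabels", "CloneAssignment", function(object) object@clone)

#' @rdname CNMatrix-class
#' @export
setGeneric("cnBins", function(object) standardGeneric("cnBins"))
#' @rdname CNMatrix-class
#' @export
setMethod("cnBins", "CNMatrix", function(object) object@bins)
#' @rdname CNMatrix-class
#' @export
setMethod("cnBins", "CloneProfileSet", function(object) object@bins)

#' @rdname CloneProfileSet-class
#' @param object a \code{CloneProfileSet}.
#' @export
setGeneric("medianCN", function(object) standardGeneric("medianCN"))
#' @rdname CloneProfileSet-class
#' @export
setMethod("medianCN", "CloneProfileSet", function(object) object@median_cn)

#' @rdname CloneAssignment-class
#' @param object a \code{CloneAssignment}.
#' @export
setGeneric("posteriors", function(object) standardGeneric("posteriors"))
#' @rdname CloneAssignment-class
#' @export
setMethod("posteriors", "CloneAssignment", function(object) object@posterior)

#' @rdname LineageSet-class
#' @param object a \code{LineageSet}.
#' @export
setGeneric("pseudotimes", function(object) standardGeneric("pseudotimes"))
#' @rdname LineageSet-class
#' @export
setMethod("pseudotimes", "LineageSet", function(object) object@pseudotime)

#' @rdname LineageSet-class
#' @export
setGeneric("lineages", function(object) standardGeneric("lineages"))
#' @rdname LineageSet-class
#' @export
setMethod("lineages", "LineageSet", function(object) object@lineages)

#' @rdname GeneModuleSet-class
#' @param object a \code{GeneModuleSet}.
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))
#' @rdname GeneModuleSet-class
#' @export
setMethod("moduleLabels", "GeneModuleSet", function(object) object@modules)
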