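## Clone-level copy-number summaries: per-clone median profiles, pairwise
## Manhattan distances between profiles, and gene-to-bin mapping by maximal
## genomic overlap.

#' Construct a CNMatrix
#'
#' @param copy integer matrix cells x bins (rownames = cell ids).
#' @param bins GRanges of fixed, non-overlapping, sorted genomic bins.
#' @param clone clone label per cell (named or in row order of \code{copy}).
#' @return a \linkS4class{CNMatrix}.
#' @export
CNMatrix <- function(copy, bins, clone) {
  if (is.null(rownames(copy)))
    rownames(copy) <- paste0("cell", seq_len(nrow(copy)))
  clone <- as.character(clone)
  if (is.null(names(clone))) names(clone) <- rownames(copy)
  new("CNMatrix", copy = copy, bins = bins,
      clone = clone[rownames(copy)])
}

#' Per-clone median copy-number profiles
#'
#' Groups cells by clone label and summarizes each bin by the median copy
#' state of the clone's cells. Medians over an even number of cells are kept
#' as exact half-integers, not rounded: two clone medians are "different"
#' only when not exactly equal.
#'
#' @param cn a \linkS4class{CNMatrix} with a clone label for every cell.
#' @return a \linkS4class{CloneProfileSet}.
#' @examples
#' bins <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1, 501), c(500, 1000)))
#' cn <- CNMatrix(rbind(c(2L, 2L), c(2L, 4L)), bins, c("A", "A"))
#' medianCN(cloneMedianProfiles(cn))   # bin2 median 3.0
#' @export
cloneMedianProfiles <- function(cn) {
  stopifnot(is(cn, "CNMatrix"))
  clone <- cloneLabels(cn)
  if (any(is.na(clone) | clone == ""))
    stop("every cell must carry a clone label")
  clones <- sort(unique(clone))
  n_cells <- vapply(clones, function(k) sum(clone == k), integer(1))
  if (any(n_cells == 0))
    stop("clone with 0 cells: ", paste(clones[n_cells == 0], collapse = ", "))
  med <- t(vapply(clones, function(k)
    apply(copyMatrix(cn)[clone == k, , drop = FALSE], 2, stats::median),
    numeric(ncol(copyMatrix(cn)))))
  dimnames(med) <- list(clones, NULL)
  new("CloneProfileSet", median_cn = med, bins = cnBins(cn),
      n_cells = n_cells)
}

#' Manhattan distance between two clone CN profiles
#'
#' Per-bin average of absolute copy-number differences,
#' mean_i |a_i - b_i| (so the value is comparable across genomes of
#' different bin counts); set \code{normalize = FALSE} for the raw sum.
#'
#' @param a,b numeric profiles over the same bin set, or a
#'   \linkS4class{CloneProfileSet} plus two clone labels.
#' @param normalize divide by the number of bins (default).
#' @return nonnegative numeric; 0 iff the profiles are identical.
#' @examples
#' manhattanDistance(c(2, 2, 4), c(2, 3, 2))   # (0+1+2)/3 = 1
#' @export
manhattanDistance <- function(a, b, normalize = TRUE) {
  if (is(a, "CloneProfileSet")) {
    prof <- medianCN(a)
    stopifnot(is.character(b), length(b) == 2)
    a <- prof[b[1], ]; b <- prof[b[2], ]
  }
  if (length(a) != length(b)) stop("bin mismatch between profiles")
  d <- sum(abs(a - b))
  if (normalize) d / length(a) else d
}

#' All pairwise clone distances
#'
#' @param profiles a \linkS4class{CloneProfileSet}.
#' @param normalize see \code{\link{manhattanDistance}}.
#' @return symmetric matrix of pairwise distances.
#' @export
cloneDistances <- function(profiles, normalize = TRUE) {
  med <- medianCN(profiles)
  k <- nrow(med)
  d <- matrix(0, k, k, dimnames = list(rownames(med), rownames(med)))
  for (i in seq_len(k)) for (j in seq_len(k))
    d[i, j] <- manhattanDistance(med[i, ], med[j, ], normalize)
  d
}

#' Map genes to genomic bins by maximal overlap
#'
#' Each gene is assigned the bin with which it shares the most overlapping
#' bases; equal-overlap ties go to the lower-coordinate bin.
#' \code{spans_boundary} is TRUE when the gene overlaps two or more bins.
#' Genes overlapping no bin are returned unmapped (bin = NA).
#'
#' @param genes GRanges with a \code{gene_id} metadata column.
#' @param bins GRanges of the copy-number bins (any order; canonically
#'   sorted internally, so the result is invariant to bin input order).
#' @return data.frame: gene, bin (index into the sorted bins), overlap_bp,
#'   spans_boundary; plus the sorted bins as attribute \code{"bins"}.
#' @export
mapGenesToBins <- function(genes, bins) {
  if (any(width(genes) < 1) || any(width(bins) < 1))
    stop("malformed interval: end <= start")
  ord <- order(as.factor(seqnames(bins)), start(bins))
  bins <- bins[ord]
  ov <- findOverlaps(genes, bins)
  w <- width(pintersect(genes[queryHits(ov)], bins[subjectHits(ov)]))
  gene_id <- if (!is.null(genes$gene_id)) genes$gene_id
             else as.character(seq_along(genes))
  res <- data.frame(gene = gene_id, bin = NA_integer_,
                    overlap_bp = 0L, spans_boundary = FALSE,
                    chrom = as.character(seqnames(genes)),
                    stringsAsFactors = FALSE)
  if (length(ov)) {
    df <- data.frame(q = queryHits(ov), s = subjectHits(ov), w = w)
    ## maximal overlap; ties -> lower-coordinate (lower sorted index) bin
    df <- df[order(df$q, -df$w, df$s), ]
    nhit <- table(factor(df$q, levels = seq_along(genes)))
    best <- df[!duplicated(df$q), ]
    res$bin[best$q] <- best$s
    res$overlap_bp[best$q] <- best$w
    res$spans_boundary <- as.integer(nhit) >= 2L
  }
  rownames(res) <- res$gene
  attr(res, "bins") <- bins
  res
}
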