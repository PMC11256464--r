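## scRNA-seq cell quality control: mouse-cell removal by cross-species
## count comparison, then the four-rule QC filter (detected genes,
## mitochondrial fraction, ribosomal fraction, MAD-based low-count rule).

#' QC thresholds
#'
#' @param min_genes minimum detected (nonzero) human genes per cell.
#' @param max_mito_frac maximum fraction of UMIs on mitochondrial genes.
#' @param max_ribo_frac maximum fraction of UMIs on ribosomal genes.
#' @param mad_k a cell is removed when its total UMI count falls more than
#'   \code{mad_k} median absolute deviations below the overall median.
#' @param scale_mad scale the MAD by the 1.4826 consistency constant
#'   (the scater \code{isOutlier} convention).
#' @param drop_doublets drop cells flagged \code{is_doublet} in metadata.
#' @param mito_pattern,ribo_pattern regexes identifying mitochondrial and
#'   ribosomal features by name when the matrix carries no \code{type}
#'   annotation.
#' @return list of class \code{QCThresholds}.
#' @export
qcThresholds <- function(min_genes = 1000, max_mito_frac = 0.20,
                         max_ribo_frac = 0.60, mad_k = 3,
                         scale_mad = TRUE, drop_doublets = TRUE,
                         mito_pattern = "^MT-",
                         ribo_pattern = "^RP[LS]") {
  stopifnot(max_mito_frac >= 0, max_mito_frac <= 1,
            max_ribo_frac >= 0, max_ribo_frac <= 1, mad_k > 0)
  structure(list(min_genes = min_genes, max_mito_frac = max_mito_frac,
                 max_ribo_frac = max_ribo_frac, mad_k = mad_k,
                 scale_mad = scale_mad, drop_doublets = drop_doublets,
                 mito_pattern = mito_pattern, ribo_pattern = ribo_pattern),
            class = "QCThresholds")
}

#' Flag mouse cells by cross-species total counts
#'
#' A cell is classified as a mouse cell iff its total count aligned to the
#' mouse reference is strictly greater than its total aligned to the human
#' reference. Ties are kept as human.
#'
#' @param human_counts,mouse_counts per-cell nonnegative totals.
#' @return logical vector, TRUE for mouse cells.
#' @examples
#' flagMouseCells(c(500, 600, 0), c(600, 600, 1))  # TRUE FALSE TRUE
#' @export
flagMouseCells <- function(human_counts, mouse_counts) {
  if (length(human_counts) != length(mouse_counts))
    stop("human_counts and mouse_counts must have the same length")
  if (any(human_counts < 0) || any(mouse_counts < 0))
    stop("counts must be nonnegative")
  mouse_counts > human_counts
}

.feature_types <- function(expr, th) {
  rd <- SummarizedExperiment::rowData(expr)
  if (!is.null(rd$type)) {
    list(mito = rd$type == "mito", ribo = rd$type == "ribo",
         mouse = rd$type == "mouse")
  } else {
    nm <- rownames(expr)
    list(mito = grepl(th$mito_pattern, nm),
         ribo = grepl(th$ribo_pattern, nm),
         mouse = grepl("^mm_", nm))
  }
}

#' Four-rule scRNA-seq QC filter
#'
#' Removes mouse cells (strict cross-species rule), then retains cells
#' meeting all of: (i) at least \code{min_genes} detected human genes,
#' (ii) mitochondrial UMI fraction below \code{max_mito_frac},
#' (iii) ribosomal UMI fraction below \code{max_ribo_frac}, and (iv) total
#' UMI count at least median(total) - mad_k * MAD(total). Detected genes,
#' fractions and totals are computed over human (non-mouse) features only,
#' after mouse-cell removal. Doublet flags in \code{colData} are consumed
#' when \code{drop_doublets} is set; no doublet detection is performed.
#'
#' Filtering is idempotent in the default "frozen" mode: the count-median
#' rule of a second pass can be frozen to the thresholds of the first by
#' passing \code{freeze} (the report carries \code{count_floor}).
#'
#' @param expr a SingleCellExperiment with a counts assay; mitochondrial /
#'   ribosomal / mouse features identified by \code{rowData(expr)$type} or
#'   by name pattern.
#' @param th a \code{\link{qcThresholds}} object.
#' @param freeze optional count floor from a previous pass, overriding the
#'   re-evaluated median - k MAD rule.
#' @return list with \code{expr} (the filtered object, mouse features
#'   retained but mouse cells removed) and \code{report}: per-criterion
#'   removal counts (a cell may fail several) plus the net count and the
#'   count floor used.
#' @export
qcFilter <- function(expr, th = qcThresholds(), freeze = NULL) {
  if (ncol(expr) == 0) stop("empty matrix")
  ft <- .feature_types(expr, th)
  if (!any(ft$mito)) stop("missing mitochondrial gene annotation")
  m <- SummarizedExperiment::assay(expr, "counts")

  mouse_tot <- Matrix::colSums(m[ft$mouse, , drop = FALSE])
  human_all <- !ft$mouse
  human_tot <- Matrix::colSums(m[human_all, , drop = FALSE])
  is_mouse <- flagMouseCells(human_tot, mouse_tot)

  kept <- expr[, !is_mouse, drop = FALSE]
  mk <- SummarizedExperiment::assay(kept, "counts")
  hk <- mk[human_all, , drop = FALSE]
  total <- Matrix::colSums(hk)
  detected <- Matrix::colSums(hk > 0)
  mito_frac <- Matrix::colSums(mk[ft$mito, , drop = FALSE]) / pmax(total, 1)
  ribo_frac <- Matrix::colSums(mk[ft$ribo, , drop = FALSE]) / pmax(total, 1)

  if (is.null(freeze)) {
    mad_tot <- stats::mad(total, constant = if (th$scale_mad) 1.4826 else 1)
    floor_tot <- stats::median(total) - th$mad_k * mad_tot
  } else floor_tot <- freeze

  fail_genes <- detected < th$min_genes
  fail_mito <- mito_frac >= th$max_mito_frac
  fail_ribo <- ribo_frac >= th$max_ribo_frac
  fail_count <- total < floor_tot
  fail_doublet <- if (th$drop_doublets &&
                      !is.null(kept$is_doublet)) kept$is_doublet
                  else rep(FALSE, ncol(kept))
  pass <- !(fail_genes | fail_mito | fail_ribo | fail_count | fail_doublet)

  report <- list(
    n_input = ncol(expr),
    removed_mouse = sum(is_mouse),
    removed_min_genes = sum(fail_genes),
    removed_mito = sum(fail_mito),
    removed_ribo = sum(fail_ribo),
    removed_low_count = sum(fail_count),
    removed_doublet = sum(fail_doublet),
    removed_net = sum(is_mouse) + sum(!pass),
    n_retained = sum(pass),
    count_floor = floor_tot,
    failed = list(min_genes = colnames(kept)[fail_genes],
                  mito = colnames(kept)[fail_mito],
                  ribo = colnames(kept)[fail_ribo],
                  low_count = colnames(kept)[fail_count],
                  doublet = colnames(kept)[fail_doublet],
                  mouse = colnames(expr)[is_mouse]))
  list(expr = kept[, pass, drop = FALSE], report = report)
}
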