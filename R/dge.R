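## Two-group negative-binomial differential expression with size-factor
## offsets, moment dispersion estimation shrunk toward a mean-dispersion
## trend, a Wald test on the log-mean difference, and BH FDR.

#' Median-ratio library size factors
#'
#' factor_c = total_c / median(total): a simple, strictly positive
#' library-size normalizer (scale-invariant relative to the median cell).
#'
#' @param expr SingleCellExperiment or counts matrix (genes x cells).
#' @return named numeric vector of per-cell factors.
#' @examples
#' computeSizeFactors(matrix(c(100, 200, 300), 1))  # 0.5 1.0 1.5
#' @export
computeSizeFactors <- function(expr) {
  m <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "counts") else expr
  tot <- Matrix::colSums(m)
  if (any(tot == 0))
    stop("all-zero cell(s): ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  f <- tot / stats::median(tot)
  names(f) <- colnames(m)
  f
}

## moment estimator of NB dispersion alpha (Var = mu + alpha mu^2) for one
## gene given per-cell means mu_c; returns >= 0
.alpha_moment <- function(x, mu) {
  num <- sum((x - mu)^2 - mu)
  den <- sum(mu^2)
  if (den <= 0) return(0)
  max(num / den, 0)
}

#' Negative-binomial Wald differential expression
#'
#' Per gene, group means are estimated with log size-factor offsets
#' (lambda_hat = sum x / sum f), dispersions by a moment estimator shrunk
#' toward a trended dispersion (running mean over expression deciles) with
#' a prior weight of 20 pseudo-genes, and a two-sided Wald test is applied
#' to the difference of log means. logFC is log2(groupA over groupB), so a
#' positive value means higher expression in group A; swapping the groups
#' negates every logFC and leaves p-values unchanged. FDR is
#' Benjamini-Hochberg over the tested genes. Genes expressed in fewer than
#' \code{min_frac} of the cells of both groups are not tested.
#'
#' @param expr SingleCellExperiment or counts matrix (genes x cells).
#' @param groupA,groupB disjoint cell-id (or column index) sets.
#' @param min_cells minimum group size (the study rule is >= 100 cells per
#'   clone; relax deliberately for small designs).
#' @param min_frac expression floor: fraction of cells with nonzero counts
#'   required in at least one group (default 0.01).
#' @param size_factors optional per-cell factors; computed over the union of
#'   the two groups when missing.
#' @param prior_weight pseudo-genes of weight given to the dispersion trend.
#' @return \code{DETable} data.frame: gene, logFC, p_value, fdr, meanA,
#'   meanB (size-factor-normalized group means), dispersion.
#' @export
deTest <- function(expr, groupA, groupB, min_cells = 100, min_frac = 0.01,
                   size_factors = NULL, prior_weight = 20) {
  m <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "counts") else expr
  if (length(intersect(groupA, groupB)))
    stop("overlapping groups")
  if (length(groupA) < min_cells || length(groupB) < min_cells)
    stop("both groups need at least ", min_cells, " cells")
  cells <- c(groupA, groupB)
  m <- as.matrix(m[, cells, drop = FALSE])
  if (is.null(size_factors)) size_factors <- computeSizeFactors(m)
  f <- size_factors[cells]
  ia <- seq_along(groupA)
  ib <- seq_along(groupB) + length(groupA)

  expressed <- pmax(rowMeans(m[, ia, drop = FALSE] > 0),
                    rowMeans(m[, ib, drop = FALSE] > 0)) >= min_frac
  if (!any(expressed)) stop("gene universe empty after expression floor")
  x <- m[expressed, , drop = FALSE]

  fa <- sum(f[ia]); fb <- sum(f[ib])
  la <- rowSums(x[, ia, drop = FALSE]) / fa
  lb <- rowSums(x[, ib, drop = FALSE]) / fb

  ## moment dispersion per gene over both groups (offsets folded into mu)
  alpha <- vapply(seq_len(nrow(x)), function(g) {
    mu <- c(la[g] * f[ia], lb[g] * f[ib])
    .alpha_moment(x[g, ], mu)
  }, numeric(1))

  ## trend over mean-expression deciles; shrink with prior_weight
  amean <- (la + lb) / 2
  dec <- cut(rank(amean, ties.method = "first"),
             breaks = 10, labels = FALSE)
  trend <- stats::ave(alpha, dec, FUN = mean)
  n_obs <- length(cells)
  alpha_sh <- (n_obs * alpha + prior_weight * trend) / (n_obs + prior_weight)

  ## Wald on log lambda difference:
  ## Var(lambda_hat) = (lambda sum f + alpha lambda^2 sum f^2) / (sum f)^2
  va <- (pmax(la, 1e-8) * fa + alpha_sh * la^2 * sum(f[ia]^2)) / fa^2
  vb <- (pmax(lb, 1e-8) * fb + alpha_sh * lb^2 * sum(f[ib]^2)) / fb^2
  vla <- va / pmax(la, 1e-8)^2
  vlb <- vb / pmax(lb, 1e-8)^2
  z <- (log(pmax(la, 1e-8)) - log(pmax(lb, 1e-8))) / sqrt(vla + vlb)
  p <- 2 * stats::pnorm(-abs(z))

  ## pseudo-count of 0.5 only when a group mean is exactly zero
  logfc <- log2(ifelse(la == 0, 0.5, la) / ifelse(lb == 0, 0.5, lb))

  out <- data.frame(gene = rownames(x), logFC = logfc, p_value = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    meanA = la, meanB = lb, dispersion = alpha_sh,
                    stringsAsFactors = FALSE)
  rownames(out) <- out$gene
  out
}

#' Filter a DE table at significance thresholds
#'
#' The study's two working presets are fdr < 0.01 with |logFC| > 0.5
#' (gene-level analyses) and fdr < 0.01 with |logFC| >= 0.25 (pathway
#' ranking input).
#'
#' @param de a \code{DETable} from \code{\link{deTest}}.
#' @param fdr,lfc thresholds.
#' @param lfc_strict require |logFC| strictly greater than \code{lfc}
#'   (default) or >=.
#' @return the filtered table.
#' @export
deSignificant <- function(de, fdr = 0.01, lfc = 0.5, lfc_strict = TRUE) {
  keep <- de$fdr < fdr &
    (if (lfc_strict) abs(de$logFC) > lfc else abs(de$logFC) >= lfc)
  de[keep, , drop = FALSE]
}
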