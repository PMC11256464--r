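## Promoter chromatin-status classification from ChIP/input promoter signal:
## 2-kb upstream promoter windows, replicate-averaged ChIP/input RPM ratios,
## and a per-mark two-group ANOVA against a repressed control set feeding
## the Active / Bivalent / Repressed decision table.

#' Promoter windows upstream of the TSS
#'
#' 2-kb window immediately upstream of the transcription start site:
#' for a + strand gene [start-2000, start), for a - strand gene
#' [end, end+2000) in 0-based half-open terms, clipped at the chromosome
#' origin.
#'
#' @param genes stranded GRanges.
#' @param window window width in bp (default 2000).
#' @return GRanges of promoter windows (names preserved).
#' @export
promoterWindows <- function(genes, window = 2000) {
  if (any(strand(genes) == "*")) stop("missing strand in gene annotation")
  plus <- as.logical(strand(genes) == "+")
  ps <- ifelse(plus, pmax(start(genes) - window, 1L), end(genes) + 1L)
  pe <- ifelse(plus, pmax(start(genes) - 1L, 1L), end(genes) + window)
  out <- GRanges(seqnames(genes), IRanges(ps, pe), strand = strand(genes))
  names(out) <- names(genes)
  if (!is.null(genes$gene_id)) out$gene_id <- genes$gene_id
  out
}

#' Replicate-averaged ChIP/input RPM ratios per promoter
#'
#' RPM = count / library_size * 1e6 per replicate track; per mark the
#' replicate RPMs are averaged and divided by the averaged input RPM.
#' Zero input RPM is floored by a 0.5-read pseudo-count before the ratio.
#'
#' @param counts promoter count table (as from
#'   \code{\link{simulateChipCounts}} or \code{\link{readPromoterCounts}}):
#'   one row per promoter with columns \code{<mark>_<rep>} and a
#'   \code{library_sizes} attribute.
#' @param marks ChIP mark prefixes (default H3K4me3 and H3K27me3).
#' @param input_prefix input track prefix.
#' @return data.frame: gene plus one ratio column per mark.
#' @export
chipInputRPM <- function(counts, marks = c("H3K4me3", "H3K27me3"),
                         input_prefix = "input") {
  lib <- attr(counts, "library_sizes")
  if (is.null(lib)) stop("counts must carry a library_sizes attribute")
  if (any(lib <= 0)) stop("zero library size")
  rpm <- function(prefix) {
    cols <- grep(paste0("^", prefix, "_"), names(counts), value = TRUE)
    if (!length(cols)) stop("no columns for track ", prefix)
    rowMeans(sapply(cols, function(cc) counts[[cc]] / lib[[cc]] * 1e6))
  }
  input <- rpm(input_prefix)
  input <- pmax(input, 0.5 / max(lib) * 1e6)   # pseudo-count floor
  out <- data.frame(gene = counts$gene, stringsAsFactors = FALSE)
  for (mk in marks) out[[mk]] <- rpm(mk) / input
  rownames(out) <- out$gene
  out
}

## two-group one-way ANOVA (F-test); with two groups F = t^2
.anova_p <- function(x, y) {
  vals <- c(x, y)
  grp <- factor(rep(c("a", "b"), c(length(x), length(y))))
  stats::anova(stats::lm(vals ~ grp))[1, "Pr(>F)"]
}

#' Classify module promoter chromatin status
#'
#' Per mark, a one-way ANOVA compares the module's promoter ChIP/input
#' ratios against the repressed control set. Decision table: K4 enriched
#' (p < alpha and module mean above control) with K27 depleted (p < alpha,
#' mean below control) is Active; K4 enriched with K27 not different
#' (p >= alpha) is Bivalent; neither mark different is Repressed; any other
#' combination is Unclassified.
#'
#' @param module_ratios data.frame from \code{\link{chipInputRPM}} for the
#'   module promoters (>= 5 rows).
#' @param control_ratios same for the repressed control promoters - the
#'   500 lowest-expressed nonzero genes' promoters (>= 50 rows).
#' @param alpha significance level (default 0.05).
#' @return list: status, per-mark p-values and group means.
#' @export
classifyModuleStatus <- function(module_ratios, control_ratios,
                                 alpha = 0.05) {
  if (nrow(control_ratios) < 50) stop("control set smaller than 50")
  if (nrow(module_ratios) < 5) stop("need >= 5 promoters per module")
  res <- list()
  for (mk in c("H3K4me3", "H3K27me3")) {
    p <- .anova_p(module_ratios[[mk]], control_ratios[[mk]])
    res[[mk]] <- list(p = p, module_mean = mean(module_ratios[[mk]]),
                      control_mean = mean(control_ratios[[mk]]))
  }
  k4 <- res$H3K4me3; k27 <- res$H3K27me3
  k4_enriched <- k4$p < alpha && k4$module_mean > k4$control_mean
  k4_same <- k4$p >= alpha
  k27_depleted <- k27$p < alpha && k27$module_mean < k27$control_mean
  k27_same <- k27$p >= alpha
  status <- if (k4_enriched && k27_depleted) "Active"
    else if (k4_enriched && k27_same) "Bivalent"
    else if (k4_same && k27_same) "Repressed"
    else "Unclassified"
  list(status = status,
       p_H3K4me3 = k4$p, p_H3K27me3 = k27$p,
       mean_H3K4me3 = k4$module_mean, mean_H3K27me3 = k27$module_mean,
       control_mean_H3K4me3 = k4$control_mean,
       control_mean_H3K27me3 = k27$control_mean)
}

#' Classify every module of a GeneModuleSet
#'
#' @param mods a \linkS4class{GeneModuleSet}.
#' @param ratios \code{\link{chipInputRPM}} table covering module and
#'   control promoters.
#' @param control_genes gene ids of the repressed control block.
#' @param alpha significance level.
#' @return the GeneModuleSet with its \code{status} slot filled; the
#'   per-module detail table is attached as attribute \code{"detail"}.
#' @export
classifyModules <- function(mods, ratios, control_genes, alpha = 0.05) {
  ctrl <- ratios[ratios$gene %in% control_genes, , drop = FALSE]
  detail <- list()
  status <- mods@status
  for (m in names(mods@curves)) {
    mid <- as.integer(sub("^M", "", m))
    genes <- names(mods@modules)[mods@modules == mid]
    mr <- ratios[ratios$gene %in% genes, , drop = FALSE]
    if (nrow(mr) < 5) { status[m] <- NA_character_; next }
    cl <- classifyModuleStatus(mr, ctrl, alpha)
    status[m] <- cl$status
    detail[[m]] <- as.data.frame(cl)
  }
  mods@status <- status
  attr(mods, "detail") <- do.call(rbind, detail)
  mods
}
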