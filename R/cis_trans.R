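## Six-trend classification of DE genes by clone copy-number difference:
## in-cis (GainUp, LossDown, GainDown, LossUp) when the clone-median copy
## numbers at the gene's bin differ, in-trans (InTransUp, InTransDown)
## otherwise. GainUp/LossDown are copy-number correlated; GainDown/LossUp
## are anti-correlated.

#' Classify significant DE genes into the six variation trends
#'
#' For each gene of a significance-filtered DE table, delta_cn is the
#' difference of the (possibly half-integer) clone-median copy numbers at
#' the gene's mapped bin, cloneA minus cloneB, compared exactly (no
#' tolerance; \code{min_delta} raises the cutoff when copy-number noise
#' warrants it). The category follows the sign table: delta_cn>0 &
#' logFC>0 GainUp; delta_cn<0 & logFC<0 LossDown; delta_cn>0 & logFC<0
#' GainDown; delta_cn<0 & logFC>0 LossUp; delta_cn=0 InTransUp/InTransDown
#' by logFC sign. Unmapped genes are excluded and reported via attribute
#' \code{"unmapped"}.
#'
#' @param de DE table already filtered at the contrast's thresholds
#'   (see \code{\link{deSignificant}}).
#' @param map gene-bin map from \code{\link{mapGenesToBins}}.
#' @param profiles a \linkS4class{CloneProfileSet}.
#' @param cloneA,cloneB the contrasted clones (logFC is A over B).
#' @param min_delta medians are "different" iff |delta| > min_delta
#'   (default 0: any exact difference).
#' @return data.frame: gene, chrom, category, is_cis, cn_correlated
#'   (NA for in-trans), delta_cn, logFC, spans_boundary.
#' @export
classifyCisTrans <- function(de, map, profiles, cloneA, cloneB,
                             min_delta = 0) {
  med <- medianCN(profiles)
  if (!all(c(cloneA, cloneB) %in% rownames(med)))
    stop("clones not present in profiles")
  idx <- match(de$gene, map$gene)
  if (anyNA(idx)) stop("gene absent from map: ",
                       paste(utils::head(de$gene[is.na(idx)]), collapse = ", "))
  bin <- map$bin[idx]
  unmapped <- de$gene[is.na(bin)]
  keep <- !is.na(bin)
  de <- de[keep, , drop = FALSE]; idx <- idx[keep]; bin <- bin[keep]

  zero_lfc <- de$logFC == 0
  if (any(zero_lfc)) {
    warning(sum(zero_lfc), " gene(s) with logFC exactly 0 excluded")
    de <- de[!zero_lfc, , drop = FALSE]
    idx <- idx[!zero_lfc]; bin <- bin[!zero_lfc]
  }

  delta <- med[cloneA, bin] - med[cloneB, bin]
  cis <- abs(delta) > min_delta
  up <- de$logFC > 0
  category <- ifelse(!cis, ifelse(up, "InTransUp", "InTransDown"),
               ifelse(delta > 0,
                      ifelse(up, "GainUp", "GainDown"),
                      ifelse(up, "LossUp", "LossDown")))
  out <- data.frame(gene = de$gene, chrom = map$chrom[idx],
                    category = category, is_cis = cis,
                    cn_correlated = ifelse(cis,
                      category %in% c("GainUp", "LossDown"), NA),
                    delta_cn = unname(delta), logFC = de$logFC,
                    spans_boundary = map$spans_boundary[idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- out$gene
  attr(out, "unmapped") <- unmapped
  out
}

#' Category proportions, global and per chromosome
#'
#' @param calls output of \code{\link{classifyCisTrans}}.
#' @return data.frame with stratum ("all" or a chromosome), category,
#'   n and fraction; fractions sum to 1 within each stratum.
#' @export
summarizeProportions <- function(calls) {
  if (!nrow(calls)) stop("empty call table")
  lev <- c("GainUp", "LossDown", "GainDown", "LossUp",
           "InTransUp", "InTransDown")
  one <- function(sub, stratum) {
    tab <- table(factor(sub$category, lev))
    data.frame(stratum = stratum, category = lev, n = as.integer(tab),
               fraction = as.numeric(tab) / nrow(sub),
               stringsAsFactors = FALSE)
  }
  res <- one(calls, "all")
  for (ch in sort(unique(calls$chrom)))
    res <- rbind(res, one(calls[calls$chrom == ch, , drop = FALSE], ch))
  res
}

#' Bin-boundary overlap among anti-correlated genes
#'
#' Fraction of copy-number anti-correlated in-cis genes (GainDown/LossUp)
#' whose gene body overlaps two or more copy-number bins - the diagnostic
#' for segment-boundary miscalls as a source of apparent anti-correlation.
#'
#' @param calls output of \code{\link{classifyCisTrans}}.
#' @return fraction in [0,1]; NaN with a warning when there are no
#'   anti-correlated genes.
#' @export
boundaryOverlapFraction <- function(calls) {
  anti <- calls[calls$is_cis & !is.na(calls$cn_correlated) &
                  !calls$cn_correlated, , drop = FALSE]
  if (!nrow(anti)) {
    warning("no anti-correlated genes; fraction undefined")
    return(NaN)
  }
  mean(anti$spans_boundary)
}
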