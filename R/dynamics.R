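## Gene-dynamics rules for treated / holiday time series: stable
## treatment-response genes (DE at Rx vs UnRx, non-DE at Rx vs RxH) and
## holiday-diverged genes (DE at Rx vs RxH) split by whether the change
## points back toward the untreated state.

#' Treatment-induced and repressed stable genes
#'
#' A gene is called induced (repressed) when it is differentially expressed
#' between Rx and UnRx (fdr < \code{de_fdr}, |logFC| > \code{de_lfc}, with
#' logFC above / below the threshold) and non-differentially expressed
#' between Rx and RxH (fdr > \code{stable_fdr}): significant change on
#' treatment that is stable across drug withdrawal. Genes present in only
#' one table are excluded and reported via attribute \code{"excluded"}.
#'
#' @param de_rx_unrx,de_rx_rxh full DE tables for the Rx vs UnRx and
#'   Rx vs RxH contrasts (same gene universe).
#' @param de_fdr,de_lfc,stable_fdr thresholds (defaults 0.01, 0.5, 0.1).
#' @return data.frame: gene, class (induced/repressed), logFC_rx_unrx,
#'   logFC_rx_rxh, fdr_rx_unrx, fdr_rx_rxh.
#' @export
stableResponseGenes <- function(de_rx_unrx, de_rx_rxh, de_fdr = 0.01,
                                de_lfc = 0.5, stable_fdr = 0.1) {
  if (stable_fdr <= de_fdr)
    stop("threshold inversion: stable_fdr must exceed de_fdr")
  shared <- intersect(de_rx_unrx$gene, de_rx_rxh$gene)
  excluded <- setdiff(union(de_rx_unrx$gene, de_rx_rxh$gene), shared)
  a <- de_rx_unrx[match(shared, de_rx_unrx$gene), ]
  b <- de_rx_rxh[match(shared, de_rx_rxh$gene), ]
  de_ok <- a$fdr < de_fdr & abs(a$logFC) > de_lfc
  stable_ok <- b$fdr > stable_fdr
  keep <- de_ok & stable_ok
  out <- data.frame(gene = shared[keep],
                    class = ifelse(a$logFC[keep] > 0, "induced",
                                   "repressed"),
                    logFC_rx_unrx = a$logFC[keep],
                    logFC_rx_rxh = b$logFC[keep],
                    fdr_rx_unrx = a$fdr[keep], fdr_rx_rxh = b$fdr[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- out$gene
  attr(out, "excluded") <- excluded
  out
}

#' Holiday-diverged genes: toward or away from the untreated state
#'
#' Genes differentially expressed between Rx and RxH (fdr < \code{de_fdr},
#' |logFC| > \code{de_lfc}) are intersected with the tested gene universe of
#' the Rx vs UnRx contrast and labelled "diverged_toward" (the untreated
#' state) when logFC(Rx vs RxH) has the same sign as logFC(Rx vs UnRx), and
#' "diverged_away" otherwise. A Rx-vs-UnRx logFC of exactly 0 shares no
#' sign, hence classifies away. When clone CN context is supplied (gene-bin
#' map plus profiles and the Rx/RxH clone pair), each gene is additionally
#' annotated in-cis/in-trans using the copy numbers at Rx and RxH.
#'
#' @param de_rx_rxh,de_rx_unrx full DE tables.
#' @param de_fdr,de_lfc significance thresholds for the Rx vs RxH contrast.
#' @param map,profiles,cloneRx,cloneRxH optional CN context for the
#'   in-cis/in-trans annotation.
#' @return data.frame: gene, class, both logFCs and fdrs, and is_cis
#'   (NA without CN context).
#' @export
holidayDivergence <- function(de_rx_rxh, de_rx_unrx, de_fdr = 0.01,
                              de_lfc = 0.5, map = NULL, profiles = NULL,
                              cloneRx = NULL, cloneRxH = NULL) {
  sig <- de_rx_rxh[de_rx_rxh$fdr < de_fdr &
                     abs(de_rx_rxh$logFC) > de_lfc, , drop = FALSE]
  shared <- intersect(sig$gene, de_rx_unrx$gene)
  if (!length(shared)) {
    warning("empty intersection between the two contrasts")
    return(data.frame(gene = character(), class = character(),
                      logFC_rx_rxh = numeric(), logFC_rx_unrx = numeric(),
                      fdr_rx_rxh = numeric(), fdr_rx_unrx = numeric(),
                      is_cis = logical()))
  }
  a <- sig[match(shared, sig$gene), ]
  b <- de_rx_unrx[match(shared, de_rx_unrx$gene), ]
  toward <- sign(a$logFC) == sign(b$logFC) & b$logFC != 0
  is_cis <- rep(NA, length(shared))
  if (!is.null(map) && !is.null(profiles)) {
    med <- medianCN(profiles)
    bin <- map$bin[match(shared, map$gene)]
    is_cis <- ifelse(is.na(bin), NA,
                     med[cloneRx, bin] != med[cloneRxH, bin])
  }
  out <- data.frame(gene = shared,
                    class = ifelse(toward, "diverged_toward",
                                   "diverged_away"),
                    logFC_rx_rxh = a$logFC, logFC_rx_unrx = b$logFC,
                    fdr_rx_rxh = a$fdr, fdr_rx_unrx = b$fdr,
                    is_cis = is_cis, stringsAsFactors = FALSE)
  rownames(out) <- out$gene
  out
}
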