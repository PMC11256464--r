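## Preranked gene set enrichment: classic weighted Kolmogorov-Smirnov
## running-sum enrichment score, gene-label permutation null, NES
## normalized by the same-sign permutation mean, and the four-way
## treated/holiday pathway-change categorization.

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then gene ids.
#'
#' @param path GMT file path.
#' @param min_size,max_size set-size bounds applied on read (default 5/500).
#' @return named list of unique gene-id vectors.
#' @export
readGMT <- function(path, min_size = 5, max_size = 500) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) unique(strsplit(l, "\t")[[1]][-(1:2)]))
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], "")
  sets[lengths(sets) >= min_size & lengths(sets) <= max_size]
}

#' Write a GMT gene-set file
#'
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @export
writeGMT <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), ""), path)
}

## weighted KS running-sum ES for hit indicator over a ranking;
## scores already sorted decreasing
.es <- function(sorted_scores, hit, p = 1) {
  w <- abs(sorted_scores)^p
  wh <- sum(w[hit])
  n_miss <- sum(!hit)
  inc <- ifelse(hit, if (wh > 0) w / wh else 0, -1 / n_miss)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Preranked GSEA with permutation-normalized scores
#'
#' Genes are ranked by score (descending; ties broken by gene id). For each
#' set, the classic weighted Kolmogorov-Smirnov running sum gives the
#' enrichment score ES (weight exponent \code{p}, default 1). A gene-label
#' permutation null (resampling sets of the same size from the ranking)
#' yields the empirical p-value within the sign class of ES and the
#' normalized score NES = ES / mean(|permuted ES| of the same sign).
#' Adjusted p-values are BH across sets. Deterministic given \code{seed}.
#'
#' @param ranked named numeric vector: gene score (typically logFC).
#' @param sets named list of gene-id vectors.
#' @param n_perm permutations (default 1000).
#' @param p weight exponent (1 = classic weighted; 0 = unweighted KS).
#' @param seed RNG seed.
#' @param min_size sets smaller than this after intersection with the
#'   ranking are skipped with a warning.
#' @return data.frame: set, size, ES, NES, p_value, p_adj, direction,
#'   leading_edge (comma-separated genes).
#' @export
prerankedGSEA <- function(ranked, sets, n_perm = 1000, p = 1, seed = 1L,
                          min_size = 3) {
  if (any(!is.finite(ranked))) stop("ranked scores must be finite")
  ord <- order(-ranked, names(ranked))
  scores <- ranked[ord]
  genes <- names(scores)
  n <- length(genes)

  present <- lapply(sets, intersect, genes)
  skip <- lengths(present) < min_size
  if (any(skip))
    warning("skipping sets absent from the ranking: ",
            paste(names(sets)[skip], collapse = ", "))
  present <- present[!skip]
  if (!length(present))
    return(data.frame(set = character(), size = integer(), ES = numeric(),
                      NES = numeric(), p_value = numeric(),
                      p_adj = numeric(), direction = character(),
                      leading_edge = character()))

  set.seed(seed)
  sizes <- sort(unique(lengths(present)))
  perm_es <- lapply(sizes, function(sz) {
    vapply(seq_len(n_perm), function(i) {
      hit <- logical(n)
      hit[sample.int(n, sz)] <- TRUE
      .es(scores, hit, p)
    }, numeric(1))
  })
  names(perm_es) <- as.character(sizes)

  res <- lapply(names(present), function(nm) {
    hit <- genes %in% present[[nm]]
    es <- .es(scores, hit, p)
    null <- perm_es[[as.character(sum(hit))]]
    same <- null[sign(null) == sign(es)]
    pval <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    ## leading edge: hits at or before the running-sum extremum
    w <- abs(scores)^p
    wh <- sum(w[hit])
    inc <- ifelse(hit, if (wh > 0) w / wh else 0, -1 / sum(!hit))
    run <- cumsum(inc)
    peak <- which.max(abs(run))
    le <- if (es > 0) genes[seq_len(peak)][hit[seq_len(peak)]]
          else genes[seq(peak, n)][hit[seq(peak, n)]]
    data.frame(set = nm, size = sum(hit), ES = es, NES = nes,
               p_value = pval, p_adj = NA_real_,
               direction = if (es > 0) "up" else "down",
               leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- out$set
  out
}

#' Four-way pathway-change categories between treated and holiday
#'
#' Per pathway, using significance at \code{alpha} on the unadjusted
#' permutation p: "Rx_only" (enriched in treated only), "RxH_only"
#' (holiday only), "both_same_direction", "both_reverse_direction", or
#' "neither".
#'
#' @param rx_results,rxh_results \code{\link{prerankedGSEA}} tables over the
#'   same set collection.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame: set, category, both directions and p-values.
#' @export
pathwayChangeCategories <- function(rx_results, rxh_results, alpha = 0.05) {
  if (!setequal(rx_results$set, rxh_results$set))
    stop("mismatched set collections")
  rxh_results <- rxh_results[match(rx_results$set, rxh_results$set), ]
  sig_rx <- rx_results$p_value < alpha
  sig_rxh <- rxh_results$p_value < alpha
  same <- rx_results$direction == rxh_results$direction
  category <- ifelse(sig_rx & !sig_rxh, "Rx_only",
              ifelse(!sig_rx & sig_rxh, "RxH_only",
              ifelse(sig_rx & sig_rxh & same, "both_same_direction",
              ifelse(sig_rx & sig_rxh, "both_reverse_direction",
                     "neither"))))
  data.frame(set = rx_results$set, category = category,
             direction_rx = rx_results$direction,
             direction_rxh = rxh_results$direction,
             p_rx = rx_results$p_value, p_rxh = rxh_results$p_value,
             stringsAsFactors = FALSE)
}

#' Reference gene-set overlap of cis/trans calls
#'
#' For each cis/trans category and each reference set, the fraction of the
#' category's genes belonging to the set; enrichment significance comes
#' from \code{\link{prerankedGSEA}} on the contrast's logFC ranking.
#'
#' @param calls \code{\link{classifyCisTrans}} output.
#' @param refs named list of reference gene sets (e.g., a curated
#'   resistance list).
#' @param ranked optional named logFC vector for the enrichment test;
#'   defaults to the calls' own logFC.
#' @param n_perm,seed permutation settings.
#' @return list with \code{fractions} (category x set) and
#'   \code{enrichment} (the preranked GSEA table on the reference sets).
#' @export
referenceSetOverlap <- function(calls, refs, ranked = NULL, n_perm = 1000,
                                seed = 1L) {
  if (any(lengths(refs) == 0)) stop("empty reference set")
  cats <- list(in_cis = calls$gene[calls$is_cis],
               in_trans = calls$gene[!calls$is_cis],
               all = calls$gene)
  fractions <- sapply(refs, function(set)
    vapply(cats, function(g)
      if (length(g)) mean(g %in% set) else NA_real_, numeric(1)))
  if (is.null(ranked))
    ranked <- stats::setNames(calls$logFC, calls$gene)
  enr <- prerankedGSEA(ranked, refs, n_perm = n_perm, seed = seed)
  list(fractions = fractions, enrichment = enr)
}
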