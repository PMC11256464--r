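## Assignment of scRNA-seq cells to copy-number clones under a gene-dosage
## model. Genes are filtered by per-clone copy-number purity; cells are
## assigned by EM over a mixture in which a cell from clone k distributes
## its counts with per-gene rates proportional to mu_g * min(cn_gk, max_cn).

#' Clone-assignment parameters
#'
#' @param cn_purity minimum fraction of a clone's cells carrying the modal
#'   copy state at a gene's bin for the gene to be used (0.6 by default).
#' @param min_counts_per_cell cells with fewer total counts over the
#'   selected genes are dropped (default 25; typical working range 25-100).
#' @param max_cn copy-number saturation threshold (default 6).
#' @param n_restarts EM restarts (default 3).
#' @param max_iter maximum EM iterations (default 500).
#' @param tol relative log-likelihood convergence tolerance.
#' @param min_posterior cells whose maximum posterior falls below this are
#'   left unassigned (default 0 = always assign).
#' @param seed RNG seed for restarts.
#' @return list of class \code{AssignmentParams}.
#' @export
assignmentParams <- function(cn_purity = 0.6, min_counts_per_cell = 25,
                             max_cn = 6, n_restarts = 3, max_iter = 500,
                             tol = 1e-6, min_posterior = 0, seed = 1L) {
  stopifnot(cn_purity > 0, cn_purity <= 1, max_cn >= 2)
  structure(list(cn_purity = cn_purity,
                 min_counts_per_cell = min_counts_per_cell,
                 max_cn = max_cn, n_restarts = n_restarts,
                 max_iter = max_iter, tol = tol,
                 min_posterior = min_posterior, seed = as.integer(seed)),
            class = "AssignmentParams")
}

#' Select dosage-informative genes for clone assignment
#'
#' A gene is kept iff (a) for every clone, at least \code{cn_purity} of that
#' clone's cells carry the clone's modal copy state at the gene's bin, and
#' (b) the clone modal copy states are not all equal after clipping at
#' \code{max_cn} (otherwise the gene carries no dosage signal).
#'
#' @param cn a \linkS4class{CNMatrix}.
#' @param map gene-bin map from \code{\link{mapGenesToBins}}.
#' @param p an \code{\link{assignmentParams}} object.
#' @return character vector of gene ids, with the clipped clone x gene modal
#'   copy states as attribute \code{"cn"}.
#' @export
selectAssignmentGenes <- function(cn, map, p = assignmentParams()) {
  clone <- cloneLabels(cn)
  clones <- sort(unique(clone))
  copy <- copyMatrix(cn)
  mapped <- map[!is.na(map$bin), , drop = FALSE]

  ## per clone x bin: modal copy state and its purity
  modal <- purity <- matrix(NA_real_, length(clones), ncol(copy),
                            dimnames = list(clones, NULL))
  for (k in clones) {
    sub <- copy[clone == k, , drop = FALSE]
    for (b in seq_len(ncol(copy))) {
      tab <- tabulate(sub[, b] + 1L)
      modal[k, b] <- which.max(tab) - 1L
      purity[k, b] <- max(tab) / nrow(sub)
    }
  }
  b <- mapped$bin
  pure_ok <- apply(purity[, b, drop = FALSE] >= p$cn_purity, 2, all)
  cn_gene <- pmin(modal[, b, drop = FALSE], p$max_cn)
  informative <- apply(cn_gene, 2, function(x) length(unique(x)) > 1)
  keep <- pure_ok & informative
  if (!any(keep))
    stop("no genes pass the purity/informativeness filter; ",
         "consider lowering cn_purity")
  genes <- mapped$gene[keep]
  out_cn <- cn_gene[, keep, drop = FALSE]
  colnames(out_cn) <- genes
  attr(genes, "cn") <- out_cn
  genes
}

## per-restart EM; x cells x genes, dose clones x genes.
## Model: x_c | clone k ~ Multinomial(N_c, pi_k), pi_kg = mu_g d_gk / Z_k.
## mu is updated by the multiplicative fixed-point of the tied M-step (the
## expected complete-data objective is concave in log mu); an update that
## would decrease the observed likelihood is rejected, so the trace is
## non-decreasing by construction (generalized EM).
.em_fit <- function(x, dose, mu0, max_iter, tol) {
  K <- nrow(dose)
  s <- rowSums(x)
  prior <- rep(1 / K, K)
  mu <- mu0
  ll_trace <- numeric(0)
  ll_old <- -Inf
  const <- sum(lgamma(s + 1)) - sum(lgamma(x + 1))
  estep <- function(mu, prior) {
    lograte <- log(mu) + t(log(dose))        # genes x clones
    logZ <- apply(lograte, 2, function(v) {
      mx <- max(v); mx + log(sum(exp(v - mx)))
    })
    ll_ck <- x %*% lograte - outer(s, logZ)
    lp <- sweep(ll_ck, 2, log(prior), "+")
    m <- apply(lp, 1, max)
    r <- exp(lp - m)
    rs <- rowSums(r)
    list(ll = sum(m + log(rs)) + const, r = r / rs, logZ = logZ)
  }
  e <- estep(mu, prior)
  for (it in seq_len(max_iter)) {
    ll_trace <- c(ll_trace, e$ll)
    if (is.finite(ll_old) && abs(e$ll - ll_old) < tol * (abs(ll_old) + 1))
      break
    ll_old <- e$ll
    prior_new <- pmax(colMeans(e$r), 1e-12)
    prior_new <- prior_new / sum(prior_new)
    ## mu_g <- sum_c x_cg / sum_k (d_gk / Z_k) sum_c r_ck N_c
    nk <- colSums(e$r * s)
    denom <- as.vector(t(dose / exp(e$logZ)) %*% nk)
    mu_new <- pmax(colSums(x), 1e-10) / pmax(denom, 1e-300)
    e_new <- estep(mu_new, prior_new)
    if (e_new$ll >= e$ll - 1e-9) {
      mu <- mu_new; prior <- prior_new; e <- e_new
    } else {
      e2 <- estep(mu, prior_new)             # prior-only update is exact
      if (e2$ll >= e$ll - 1e-9) { prior <- prior_new; e <- e2 }
      break
    }
  }
  list(mu = mu, prior = prior, resp = e$r, ll = ll_trace)
}

#' Assign cells to clones by dosage EM
#'
#' Mixture model: a cell c from clone k spreads its N_c counts over the
#' selected genes with rates proportional to mu_g * dose_gk, where dose is
#' the clone's modal copy state clipped at \code{max_cn} (copy 0 is mapped
#' to a pseudo-dosage 0.1 for numerical robustness). Responsibilities and
#' the shared expression scale mu are alternated in closed form; the
#' log-likelihood is non-decreasing across iterations and the best of
#' \code{n_restarts} jittered starts is kept. mu is initialized from pooled
#' empirical count frequencies.
#'
#' @param expr SingleCellExperiment (or counts matrix genes x cells).
#' @param genes selected genes from \code{\link{selectAssignmentGenes}}
#'   (carrying the clone x gene dosage attribute), or a character vector
#'   plus an explicit \code{cn_gene} matrix.
#' @param p an \code{\link{assignmentParams}} object.
#' @param cn_gene optional clone x gene copy-state matrix overriding the
#'   attribute on \code{genes}.
#' @return a \linkS4class{CloneAssignment}.
#' @export
assignClones <- function(expr, genes, p = assignmentParams(),
                         cn_gene = NULL) {
  if (is.null(cn_gene)) cn_gene <- attr(genes, "cn")
  if (is.null(cn_gene)) stop("no clone x gene copy states supplied")
  genes <- as.character(genes)
  if (!length(genes)) stop("empty gene list")
  m <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "counts") else expr
  genes <- intersect(genes, rownames(m))
  if (!length(genes)) stop("none of the selected genes are in the matrix")
  x <- t(as.matrix(m[genes, , drop = FALSE]))   # cells x genes
  cn_gene <- cn_gene[, genes, drop = FALSE]
  clones <- rownames(cn_gene)
  K <- length(clones)

  tot <- rowSums(x)
  keep <- tot >= p$min_counts_per_cell
  dropped <- rownames(x)[!keep]
  x <- x[keep, , drop = FALSE]
  if (!nrow(x)) stop("no cells left after the min_counts_per_cell filter")

  if (K == 1) {
    post <- matrix(1, nrow(x), 1, dimnames = list(rownames(x), clones))
    clone <- stats::setNames(rep(clones, nrow(x)), rownames(x))
    return(new("CloneAssignment", clone = clone, posterior = post,
               genes_used = genes, log_lik = 0, dropped_cells = dropped,
               params = unclass(p)))
  }

  dose <- pmax(cn_gene, 0.1)   # pseudo-dosage for copy 0
  ## pooled frequencies reflect mu_g times the prevalence-averaged dosage;
  ## dividing by the mean clone dosage anchors mu at baseline expression
  ## (the tied model is invariant to mu absorbing one clone's dose profile,
  ## so the anchor decides the basin the EM refines)
  mu0 <- (pmax(colSums(x), 0.5) / sum(x)) / colMeans(dose)
  set.seed(p$seed)
  best <- NULL
  for (r in seq_len(p$n_restarts)) {
    mu_start <- if (r == 1) mu0 else
      mu0 * exp(stats::rnorm(length(mu0), 0, 0.1))
    fit <- .em_fit(x, dose, mu_start, p$max_iter, p$tol)
    if (is.null(best) || max(fit$ll) > max(best$ll)) best <- fit
  }
  post <- best$resp
  dimnames(post) <- list(rownames(x), clones)
  frac <- colMeans(post)
  if (max(frac) > 0.99 && nrow(x) > 100)
    warning("degenerate mixture fit: one clone absorbed ",
            round(100 * max(frac)), "% of cells; the dosage signal of ",
            "these clone profiles may be too weak (saturated or ",
            "near-proportional copy states) for the simplified EM")
  map_idx <- max.col(post, ties.method = "first")
  clone <- clones[map_idx]
  clone[post[cbind(seq_len(nrow(post)), map_idx)] < p$min_posterior] <- NA
  names(clone) <- rownames(post)
  new("CloneAssignment", clone = clone, posterior = post,
      genes_used = genes, log_lik = best$ll, dropped_cells = dropped,
      params = unclass(p))
}

#' Clonal-proportion concordance between modalities
#'
#' Compares, per sample and clone, the clone proportions inferred from
#' scRNA-seq assignments with the proportions observed in the CN (DLP-style)
#' modality, and reports the Pearson correlation over all (sample, clone)
#' points.
#'
#' @param assign a \linkS4class{CloneAssignment}.
#' @param cn a \linkS4class{CNMatrix} (clone labels per CN cell).
#' @param expr_samples named character: sample per expression cell.
#' @param cn_samples named character: sample per CN cell.
#' @return list with \code{table} (sample, clone, prop_expr, prop_cn) and
#'   \code{r}, the Pearson correlation.
#' @export
proportionConcordance <- function(assign, cn, expr_samples, cn_samples) {
  ac <- cloneLabels(assign)
  ac <- ac[!is.na(ac)]
  cc <- cloneLabels(cn)
  clones <- sort(union(unique(ac), unique(cc)))
  if (!length(intersect(unique(ac), unique(cc))))
    stop("no shared clones between modalities")
  samples <- sort(union(unique(expr_samples[names(ac)]),
                        unique(cn_samples[names(cc)])))
  grid <- expand.grid(clone = clones, sample = samples,
                      stringsAsFactors = FALSE)
  prop <- function(lab, smp) {
    tab <- table(factor(smp, samples), factor(lab, clones))
    tab / pmax(rowSums(tab), 1)
  }
  pe <- prop(ac, expr_samples[names(ac)])
  pc <- prop(cc, cn_samples[names(cc)])
  grid$prop_expr <- pe[cbind(grid$sample, grid$clone)]
  grid$prop_cn <- pc[cbind(grid$sample, grid$clone)]
  r <- stats::cor(grid$prop_expr, grid$prop_cn)
  list(table = grid, r = r)
}
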