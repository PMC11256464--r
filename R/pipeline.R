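## End-to-end orchestration: YAML configuration, input loading with
## cross-checks, Fig-3a-style contrast-clone selection, and the staged
## pipeline qc -> assignment -> DE -> cis/trans -> dynamics -> enrichment
## -> trajectory -> chromatin with provenance-headed TSV outputs.

.default_config <- function() {
  list(
    qc = list(min_genes = 1000, max_mito = 0.2, max_ribo = 0.6, mad_k = 3),
    assign = list(cn_purity = 0.6, min_counts = 25, max_cn = 6,
                  n_restarts = 3, max_iter = 500),
    de = list(fdr = 0.01, lfc = 0.5, min_cells = 100),
    gsea = list(n_perm = 1000, lfc = 0.25),
    trajectory = list(n_hvg = 3000, n_pcs = 30, k = 8, n_perm = 200,
                      n_test_genes = 300),
    chromatin = list(alpha = 0.05),
    seed = 1L)
}

#' Load and validate a pipeline configuration
#'
#' @param path YAML file with input paths (counts, cn, genes, gene_sets,
#'   promoter_counts), per-stage parameter blocks and a seed; missing
#'   parameters take the package defaults.
#' @return validated config list (class \code{PipelineConfig}).
#' @export
pipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- .default_config()
  for (blk in names(def)) {
    if (is.null(cfg[[blk]])) cfg[[blk]] <- def[[blk]]
    else if (is.list(def[[blk]]))
      for (nm in names(def[[blk]]))
        if (is.null(cfg[[blk]][[nm]])) cfg[[blk]][[nm]] <- def[[blk]][[nm]]
  }
  base <- dirname(normalizePath(path))
  for (nm in c("counts", "cn", "genes", "gene_sets", "promoter_counts")) {
    if (is.null(cfg$inputs[[nm]])) next
    p <- cfg$inputs[[nm]]
    if (!file.exists(p) && file.exists(file.path(base, p)))
      cfg$inputs[[nm]] <- file.path(base, p)
    if (!file.exists(cfg$inputs[[nm]]))
      stop("missing input path: ", p)
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "PipelineConfig"
  cfg
}

## hash of the semantically meaningful config fields
.config_hash <- function(cfg) {
  core <- unclass(cfg)
  core$inputs <- lapply(core$inputs, basename)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(core[order(names(core))]), tmp)
  unname(tools::md5sum(tmp))
}

#' Load all pipeline inputs
#'
#' Reads the count bundle, CN table, gene annotation, gene sets and
#' promoter counts named in the config; enforces a unique gene-id
#' namespace and reports the cell-id overlap between the CN and expression
#' modalities.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return list: expr, cn, genes, gene_sets, promoter_counts.
#' @export
loadInputs <- function(config) {
  inp <- config$inputs
  expr <- readCountsMTX(inp$counts)
  cn <- readCNTable(inp$cn)
  genes <- readGeneBed(inp$genes)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in annotation")
  sets <- if (!is.null(inp$gene_sets)) readGMT(inp$gene_sets) else NULL
  chip <- if (!is.null(inp$promoter_counts))
    readPromoterCounts(inp$promoter_counts) else NULL
  shared <- length(intersect(colnames(expr), rownames(copyMatrix(cn))))
  message("cell-id overlap between CN and expression: ", shared, " cells")
  list(expr = expr, cn = cn, genes = genes, gene_sets = sets,
       promoter_counts = chip)
}

#' Select contrast clones per passage and condition pair
#'
#' For each passage and ordered condition pair, picks the clone with the
#' highest fitness (when a fitness map is supplied) or the most abundant
#' clone, requiring at least \code{min_cells} assigned cells on both sides;
#' under-powered contrasts are skipped with a warning.
#'
#' @param assign a \linkS4class{CloneAssignment}.
#' @param metadata data.frame with cell_id, passage, condition covering the
#'   assigned cells.
#' @param min_cells minimum assigned cells per clone (default 100).
#' @param fitness optional named clone-fitness map.
#' @param pairs condition pairs to form, as a list of c(A, B).
#' @return data.frame: passage, condA, cloneA, nA, condB, cloneB, nB.
#' @export
selectContrastClones <- function(assign, metadata, min_cells = 100,
                                 fitness = NULL,
                                 pairs = list(c("Rx", "UnRx"),
                                              c("RxH", "UnRx"),
                                              c("Rx", "RxH"))) {
  clone <- cloneLabels(assign)
  md <- metadata[match(names(clone), metadata$cell_id), ]
  pick <- function(passage, cond) {
    sel <- !is.na(clone) & md$passage == passage & md$condition == cond
    if (!any(sel)) return(NULL)
    tab <- table(clone[sel])
    tab <- tab[tab >= min_cells]
    if (!length(tab)) return(NULL)
    k <- if (!is.null(fitness)) {
      cand <- names(tab)
      cand[which.max(fitness[cand])]
    } else names(which.max(tab))
    list(clone = k, n = as.integer(tab[k]))
  }
  res <- list()
  for (p in sort(unique(md$passage))) for (pr in pairs) {
    a <- pick(p, pr[1]); b <- pick(p, pr[2])
    if (is.null(a) || is.null(b)) {
      warning("skipping contrast ", pr[1], " vs ", pr[2], " at passage ",
              p, ": no clone with >= ", min_cells, " cells")
      next
    }
    res[[length(res) + 1]] <- data.frame(
      passage = p, condA = pr[1], cloneA = a$clone, nA = a$n,
      condB = pr[2], cloneB = b$clone, nB = b$n,
      stringsAsFactors = FALSE)
  }
  if (!length(res)) return(data.frame())
  do.call(rbind, res)
}

#' Run the full clone-aware pipeline
#'
#' Executes qc, clone assignment, per-contrast differential expression,
#' cis/trans classification, gene dynamics (where Rx and RxH contrasts
#' co-exist at a passage), preranked pathway enrichment, trajectory
#' inference with gene modules, and promoter chromatin classification,
#' writing every stage's TSV (with provenance headers) under
#' \code{out_dir}. A rerun with the same config and seed is bit-identical.
#'
#' @param config a \code{\link{pipelineConfig}} (or path to one).
#' @param out_dir output directory.
#' @return invisibly, a list of in-memory stage results.
#' @export
runPipeline <- function(config, out_dir) {
  if (is.character(config)) config <- pipelineConfig(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  seed <- config$seed
  wtsv <- function(df, name) writeResultTSV(df, file.path(out_dir, name),
                                            seed = seed, config_hash = hash)
  inp <- loadInputs(config)

  ## --- qc ---
  th <- qcThresholds(min_genes = config$qc$min_genes,
                     max_mito_frac = config$qc$max_mito,
                     max_ribo_frac = config$qc$max_ribo,
                     mad_k = config$qc$mad_k)
  qc <- qcFilter(inp$expr, th)
  expr <- qc$expr
  rep_df <- data.frame(metric = names(qc$report)[1:10],
                       value = unlist(qc$report[1:10]))
  wtsv(rep_df, "qc_report.tsv")

  ## --- clone profiles, gene map, assignment ---
  profiles <- cloneMedianProfiles(inp$cn)
  map <- mapGenesToBins(inp$genes, cnBins(inp$cn))
  ap <- assignmentParams(cn_purity = config$assign$cn_purity,
                         min_counts_per_cell = config$assign$min_counts,
                         max_cn = config$assign$max_cn,
                         n_restarts = config$assign$n_restarts,
                         max_iter = config$assign$max_iter, seed = seed)
  genes_sel <- selectAssignmentGenes(inp$cn, map, ap)
  assign <- assignClones(expr, genes_sel, ap)
  wtsv(data.frame(cell = names(cloneLabels(assign)),
                  clone = cloneLabels(assign),
                  max_posterior = apply(posteriors(assign), 1, max)),
       "assignments.tsv")

  md <- as.data.frame(SummarizedExperiment::colData(expr))
  conc <- proportionConcordance(
    assign, inp$cn,
    stats::setNames(md$sample, md$cell_id),
    stats::setNames(sub("_c[0-9]+$", "", rownames(copyMatrix(inp$cn))),
                    rownames(copyMatrix(inp$cn))))
  wtsv(conc$table, "concordance.tsv")

  ## --- contrasts, DE, cis/trans ---
  contrasts <- selectContrastClones(assign, md,
                                    min_cells = config$de$min_cells)
  clone <- cloneLabels(assign)
  de_tabs <- list()
  ct_tabs <- list()
  for (i in seq_len(nrow(contrasts))) {
    cs <- contrasts[i, ]
    cellsA <- names(clone)[!is.na(clone) & clone == cs$cloneA &
      md[names(clone), "condition"] == cs$condA &
      md[names(clone), "passage"] == cs$passage]
    cellsB <- names(clone)[!is.na(clone) & clone == cs$cloneB &
      md[names(clone), "condition"] == cs$condB &
      md[names(clone), "passage"] == cs$passage]
    key <- paste0("X", cs$passage, "_", cs$condA, "_vs_", cs$condB)
    de <- deTest(expr[SummarizedExperiment::rowData(expr)$type == "gene", ],
                 cellsA, cellsB, min_cells = config$de$min_cells)
    de_tabs[[key]] <- de
    wtsv(de, paste0("de_", key, ".tsv"))
    sig <- deSignificant(de, fdr = config$de$fdr, lfc = config$de$lfc)
    if (nrow(sig)) {
      calls <- classifyCisTrans(sig, map, profiles, cs$cloneA, cs$cloneB)
      ct_tabs[[key]] <- calls
      wtsv(calls, paste0("cistrans_", key, ".tsv"))
      wtsv(summarizeProportions(calls), paste0("proportions_", key, ".tsv"))
    }
  }

  ## --- dynamics per passage with both Rx and RxH contrasts ---
  dyn_tabs <- list()
  for (p in unique(contrasts$passage)) {
    k_ru <- paste0("X", p, "_Rx_vs_UnRx")
    k_rh <- paste0("X", p, "_Rx_vs_RxH")
    if (!k_ru %in% names(de_tabs) || !k_rh %in% names(de_tabs)) next
    stab <- stableResponseGenes(de_tabs[[k_ru]], de_tabs[[k_rh]],
                                de_fdr = config$de$fdr,
                                de_lfc = config$de$lfc)
    rxrow <- contrasts[contrasts$passage == p & contrasts$condA == "Rx" &
                         contrasts$condB == "RxH", ][1, ]
    div <- holidayDivergence(de_tabs[[k_rh]], de_tabs[[k_ru]],
                             de_fdr = config$de$fdr,
                             de_lfc = config$de$lfc,
                             map = map, profiles = profiles,
                             cloneRx = rxrow$cloneA,
                             cloneRxH = rxrow$cloneB)
    dyn_tabs[[as.character(p)]] <- list(stable = stab, diverged = div)
    wtsv(stab, paste0("dynamics_stable_X", p, ".tsv"))
    if (nrow(div)) wtsv(div, paste0("dynamics_diverged_X", p, ".tsv"))
  }

  ## --- enrichment ---
  gsea_tabs <- list()
  if (!is.null(inp$gene_sets)) {
    for (key in names(de_tabs)) {
      sig <- deSignificant(de_tabs[[key]], fdr = config$de$fdr,
                           lfc = config$gsea$lfc, lfc_strict = FALSE)
      if (nrow(sig) < 10) next
      ranked <- stats::setNames(sig$logFC, sig$gene)
      gsea_tabs[[key]] <- prerankedGSEA(ranked, inp$gene_sets,
                                        n_perm = config$gsea$n_perm,
                                        seed = seed)
      wtsv(gsea_tabs[[key]][, setdiff(names(gsea_tabs[[key]]),
                                      "leading_edge")],
           paste0("gsea_", key, ".tsv"))
    }
    for (p in unique(contrasts$passage)) {
      k_ru <- paste0("X", p, "_Rx_vs_UnRx")
      k_hu <- paste0("X", p, "_RxH_vs_UnRx")
      if (k_ru %in% names(gsea_tabs) && k_hu %in% names(gsea_tabs) &&
          setequal(gsea_tabs[[k_ru]]$set, gsea_tabs[[k_hu]]$set))
        wtsv(pathwayChangeCategories(gsea_tabs[[k_ru]],
                                     gsea_tabs[[k_hu]]),
             paste0("pathway_changes_X", p, ".tsv"))
    }
  }

  ## --- trajectory ---
  lin <- inferLineages(expr, n_hvg = config$trajectory$n_hvg,
                       n_pcs = config$trajectory$n_pcs,
                       k = config$trajectory$k, seed = seed)
  pt <- pseudotimes(lin)
  pt_df <- data.frame(cell = rep(rownames(pt), ncol(pt)),
                      lineage = rep(colnames(pt), each = nrow(pt)),
                      t = as.vector(pt), weight = as.vector(lin@weights))
  wtsv(pt_df[!is.na(pt_df$t), ], "pseudotime.tsv")

  mods <- NULL
  if (length(lineages(lin)) >= 2) {
    norm <- logNormalizeCounts(expr)
    v <- apply(norm, 1, stats::var)
    test_genes <- names(sort(v, decreasing = TRUE))[
      seq_len(min(config$trajectory$n_test_genes, nrow(norm)))]
    tests <- lineageGeneTests(norm, lin, genes = test_genes,
                              n_perm = config$trajectory$n_perm,
                              seed = seed)
    wtsv(tests, "lineage_tests.tsv")
    sig_genes <- significantLineageGenes(tests)
    if (length(sig_genes) >= 10) {
      curves <- smoothedCurves(norm, lin, genes = sig_genes)
      mods <- clusterGeneModules(curves, seed = seed)
      cis_mat <- annotateLineageCisTrans(names(moduleLabels(mods)), lin,
                                         assign, profiles, map)
      wtsv(data.frame(gene = names(moduleLabels(mods)),
                      module = moduleLabels(mods),
                      as.data.frame(cis_mat)),
           "modules.tsv")
      ## --- chromatin ---
      if (!is.null(inp$promoter_counts)) {
        ratios <- chipInputRPM(inp$promoter_counts)
        ctrl <- grep("^ctrl_", inp$promoter_counts$gene, value = TRUE)
        mods <- classifyModules(mods, ratios, ctrl,
                                alpha = config$chromatin$alpha)
        det <- attr(mods, "detail")
        if (!is.null(det))
          wtsv(data.frame(module = rownames(det), det),
               "module_status.tsv")
      }
    }
  }

  invisible(list(qc = qc, assign = assign, profiles = profiles, map = map,
                 concordance = conc, contrasts = contrasts, de = de_tabs,
                 cistrans = ct_tabs, dynamics = dyn_tabs, gsea = gsea_tabs,
                 lineages = lin, modules = mods, out_dir = out_dir))
}

#' Write the bundled synthetic demo and its config
#'
#' Simulates a compact three-clone time series, writes every input file
#' plus a ready-to-run \code{config.yaml} into \code{dir}.
#'
#' @param dir destination directory.
#' @param seed generator seed.
#' @param ... overrides passed to \code{\link{simulationParams}}.
#' @return path to the written config.yaml.
#' @export
demoDataset <- function(dir, seed = 1L, ...) {
  params <- simulationParams(seed = seed, ...)
  truth <- simulateTruth(params)
  sim <- simulateCells(truth)
  writeDataset(truth, sim, dir)
  cfg <- list(
    inputs = list(counts = "counts", cn = "cn.tsv", genes = "genes.bed",
                  gene_sets = "gene_sets.gmt",
                  promoter_counts = "promoter_counts.tsv"),
    de = list(min_cells = 50),
    trajectory = list(n_hvg = 1000, n_pcs = 20, k = 6, n_perm = 100,
                      n_test_genes = 150),
    gsea = list(n_perm = 200, lfc = 0.25),
    seed = as.integer(seed))
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  path
}
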