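## On-disk formats: MatrixMarket count bundles (matrix.mtx + barcodes.tsv +
## features.tsv + meta.tsv), long-format copy-number TSV, BED-like gene
## annotation, promoter-count TSV, and provenance-headed result TSVs.
## Coordinates are 0-based half-open on disk and 1-based GRanges in memory.

.prov_header <- function(seed = NULL, config_hash = NULL) {
  v <- as.character(utils::packageVersion("cloneTx"))
  paste0("# cloneTx ", v,
         if (!is.null(seed)) paste0("; seed=", seed),
         if (!is.null(config_hash)) paste0("; config=", config_hash))
}

#' Write a results TSV with a provenance header
#'
#' @param df data.frame to write.
#' @param path destination.
#' @param seed,config_hash recorded in the "#"-prefixed header line.
#' @export
writeResultTSV <- function(df, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.prov_header(seed, config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results TSV, skipping provenance headers
#' @param path TSV path.
#' @return data.frame.
#' @export
readResultTSV <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a count matrix as an MTX bundle
#'
#' Emits \code{matrix.mtx} (MatrixMarket coordinate integer),
#' \code{barcodes.tsv}, \code{features.tsv} (id, type) and, for a
#' SingleCellExperiment, \code{meta.tsv} with the colData.
#'
#' @param expr SingleCellExperiment or genes x cells matrix.
#' @param dir output directory (created).
#' @export
writeCountsMTX <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "counts") else expr
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  ts <- Matrix::summary(m)
  con <- file(file.path(dir, "matrix.mtx"), "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(m), ncol(m), nrow(ts))), con)
  utils::write.table(data.frame(ts$i, ts$j, as.integer(ts$x)), con,
                     col.names = FALSE, row.names = FALSE, quote = FALSE)
  close(con)
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  type <- if (is(expr, "SummarizedExperiment") &&
              !is.null(SummarizedExperiment::rowData(expr)$type))
    SummarizedExperiment::rowData(expr)$type else rep("gene", nrow(m))
  utils::write.table(data.frame(rownames(m), type),
                     file.path(dir, "features.tsv"), sep = "\t",
                     col.names = FALSE, row.names = FALSE, quote = FALSE)
  if (is(expr, "SummarizedExperiment")) {
    cd <- as.data.frame(SummarizedExperiment::colData(expr))
    utils::write.table(cd, file.path(dir, "meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read an MTX count bundle
#'
#' Validates the header dimensions and the declared entry count against
#' the barcode/feature files and the triplet lines; duplicate gene ids are
#' an error.
#'
#' @param dir directory holding matrix.mtx, barcodes.tsv, features.tsv and
#'   optionally meta.tsv.
#' @return a SingleCellExperiment.
#' @export
readCountsMTX <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  lines <- readLines(mtx)
  body <- lines[!startsWith(lines, "%")]
  hdr <- as.numeric(strsplit(trimws(body[1]), "\\s+")[[1]])
  if (length(body) - 1 != hdr[3])
    stop("MTX header declares ", hdr[3], " entries but file has ",
         length(body) - 1)
  m <- as(Matrix::readMM(mtx), "CsparseMatrix")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  feat <- utils::read.delim(file.path(dir, "features.tsv"), header = FALSE,
                            stringsAsFactors = FALSE)
  if (nrow(m) != nrow(feat) || ncol(m) != length(barcodes))
    stop("MTX dimensions do not match barcode/feature files")
  if (anyDuplicated(feat[[1]])) stop("duplicate gene ids in features.tsv")
  dimnames(m) <- list(feat[[1]], barcodes)
  rd <- DataFrame(gene_id = feat[[1]],
                  type = if (ncol(feat) > 1) feat[[2]]
                         else rep("gene", nrow(feat)),
                  row.names = feat[[1]])
  meta_path <- file.path(dir, "meta.tsv")
  cd <- if (file.exists(meta_path)) {
    md <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    rownames(md) <- md$cell_id
    DataFrame(md[barcodes, , drop = FALSE])
  } else DataFrame(row.names = barcodes)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), rowData = rd, colData = cd)
}

#' Write a CNMatrix as a long-format TSV
#'
#' Columns cell_id, chrom, start, end, copy, clone with 0-based half-open
#' coordinates.
#'
#' @param cn a \linkS4class{CNMatrix}.
#' @param path destination TSV.
#' @export
writeCNTable <- function(cn, path) {
  bins <- cnBins(cn)
  copy <- copyMatrix(cn)
  df <- data.frame(
    cell_id = rep(rownames(copy), each = ncol(copy)),
    chrom = rep(as.character(seqnames(bins)), nrow(copy)),
    start = rep(start(bins) - 1L, nrow(copy)),
    end = rep(end(bins), nrow(copy)),
    copy = as.integer(t(copy)),
    clone = rep(cloneLabels(cn), each = ncol(copy)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a long-format CN TSV into a CNMatrix
#'
#' @param path TSV with columns cell_id, chrom, start, end, copy, clone
#'   (0-based half-open coordinates).
#' @return a \linkS4class{CNMatrix}.
#' @export
readCNTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  key <- paste(df$chrom, df$start, df$end, sep = ":")
  ub <- unique(df[, c("chrom", "start", "end")])
  ub <- ub[order(ub$chrom, ub$start), ]
  bins <- GRanges(ub$chrom, IRanges(ub$start + 1L, ub$end))
  bkey <- paste(ub$chrom, ub$start, ub$end, sep = ":")
  cells <- unique(df$cell_id)
  copy <- matrix(NA_integer_, length(cells), length(bins),
                 dimnames = list(cells, NULL))
  copy[cbind(match(df$cell_id, cells), match(key, bkey))] <- df$copy
  if (anyNA(copy)) stop("CN table is not complete over cells x bins")
  clone <- df$clone[!duplicated(df$cell_id)]
  names(clone) <- df$cell_id[!duplicated(df$cell_id)]
  new("CNMatrix", copy = copy, bins = bins, clone = clone[cells])
}

#' Write gene annotation as BED6
#'
#' chrom, 0-based start, end, gene_id, score 0, strand.
#'
#' @param genes GRanges with gene_id.
#' @param path destination.
#' @export
writeGeneBed <- function(genes, path) {
  df <- data.frame(as.character(seqnames(genes)), start(genes) - 1L,
                   end(genes), genes$gene_id, 0L,
                   as.character(strand(genes)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED-like gene annotation
#'
#' BED6 (0-based half-open on disk); a GTF can be converted via
#' \code{rtracklayer::import} upstream.
#'
#' @param path BED file.
#' @return GRanges with gene_id, named by gene id.
#' @export
readGeneBed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (any(df[[3]] <= df[[2]])) stop("malformed interval: end <= start")
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]),
                strand = if (ncol(df) >= 6) df[[6]] else "*")
  gr$gene_id <- df[[4]]
  names(gr) <- df[[4]]
  gr
}

#' Write / read promoter count tables
#'
#' TSV with a \code{#library_sizes} header line carrying
#' \code{track=size} pairs.
#'
#' @param counts promoter count data.frame with a library_sizes attribute.
#' @param path TSV path.
#' @export
writePromoterCounts <- function(counts, path) {
  lib <- attr(counts, "library_sizes")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#library_sizes\t",
                    paste(names(lib), lib, sep = "=", collapse = "\t")),
             con)
  utils::write.table(counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePromoterCounts
#' @export
readPromoterCounts <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#library_sizes"))
    stop("promoter count file lacks the #library_sizes header")
  kv <- strsplit(strsplit(first, "\t")[[1]][-1], "=")
  lib <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                         vapply(kv, `[`, "", 1))
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  attr(df, "library_sizes") <- lib
  df
}

#' Write a full synthetic dataset to disk
#'
#' Emits the MTX count bundle, the long-format CN TSV, the BED gene
#' annotation, a GMT with the planted program gene sets plus random decoy
#' sets, and the promoter-count TSV - everything \code{\link{loadInputs}}
#' needs.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param sim output of \code{\link{simulateCells}} on that truth.
#' @param dir output directory.
#' @param n_decoy_sets random gene sets added to the GMT (default 8).
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(truth, sim, dir, n_decoy_sets = 8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCountsMTX(sim$expr, file.path(dir, "counts"))
  writeCNTable(sim$cn, file.path(dir, "cn.tsv"))
  writeGeneBed(truth@genes, file.path(dir, "genes.bed"))
  prog <- truth@gene_program
  sets <- list(
    planted_induced = names(prog)[grepl("^induced", prog)],
    planted_repressed = names(prog)[grepl("^repressed", prog)],
    planted_reversible = names(prog)[grepl("reversible$", prog)])
  set.seed(truth@params@seed + 3L)
  for (i in seq_len(n_decoy_sets))
    sets[[sprintf("decoy_%02d", i)]] <- sample(names(prog), 40)
  writeGMT(sets, file.path(dir, "gene_sets.gmt"))
  chip <- simulateChipCounts(truth)
  writePromoterCounts(chip, file.path(dir, "promoter_counts.tsv"))
  invisible(dir)
}
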