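#' Load a UMI count matrix with cell metadata
#'
#' Reads either a 10x-style Matrix Market triplet directory
#' (`matrix.mtx`, `barcodes.tsv`, `features.tsv`) or a dense TSV
#' (orientation auto-detected from the header), together with a cell
#' metadata TSV. Cells present in the matrix but absent from the
#' metadata are an error naming the offending barcodes.
#'
#' @param path directory containing an MTX triplet, or a dense TSV file.
#' @param metadata_path TSV with columns `cell_id`, `sample_id`,
#'   `tissue_origin`, `lineage`, `subset`.
#' @return list with elements `matrix` (an [expression_matrix()]) and
#'   `annotation` (validated metadata, ordered as the matrix cells).
#' @export
load_counts <- function(path, metadata_path) {
  if (dir.exists(path)) {
    counts <- read_mtx_triplet(path)
  } else if (file.exists(path)) {
    counts <- read_dense_tsv(path)
  } else stop("no such file or directory: ", path)
  if (!file.exists(metadata_path)) stop("no such file: ", metadata_path)
  ann <- utils::read.delim(metadata_path, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  ann <- cell_annotation(ann)
  missing_cells <- setdiff(rownames(counts), ann$cell_id)
  if (length(missing_cells))
    stop("metadata missing for barcodes: ",
         paste(utils::head(missing_cells, 10), collapse = ", "),
         if (length(missing_cells) > 10) sprintf(" (and %d more)",
                                                 length(missing_cells) - 10))
  ann <- ann[match(rownames(counts), ann$cell_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(matrix = expression_matrix(counts), annotation = ann)
}

# MTX triplet on disk is genes x cells (10x convention); returned
# transposed to the package's cell-major layout.
read_mtx_triplet <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  bc  <- file.path(dir, "barcodes.tsv")
  ft  <- file.path(dir, "features.tsv")
  if (!file.exists(ft)) ft <- file.path(dir, "genes.tsv")
  for (f in c(mtx, bc, ft))
    if (!file.exists(f)) stop("missing triplet file: ", f)
  m <- Matrix::readMM(mtx)
  barcodes <- readLines(bc)
  features <- utils::read.delim(ft, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(features) || ncol(m) != length(barcodes))
    stop(sprintf(
      "matrix is %d x %d but features=%d, barcodes=%d: dimension mismatch",
      nrow(m), ncol(m), length(features), length(barcodes)))
  dimnames(m) <- list(features, barcodes)
  Matrix::t(m)
}

# Dense TSV: first column holds row names; orientation decided by
# matching the header against the first column of a metadata-like id
# pattern is not possible here, so the convention is a header token
# "cell_id" (cells x genes) or "gene_id" (genes x cells); otherwise
# rows are taken as genes (the common export orientation).
read_dense_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  first <- names(df)[1]
  rn <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rn
  if (identical(tolower(first), "cell_id")) m else t(m)
}

#' Write an ExpressionMatrix as an MTX triplet
#'
#' Inverse of the triplet branch of [load_counts()]; written genes x
#' cells per the 10x convention.
#'
#' @param m an `ExpressionMatrix`.
#' @param dir output directory (created if needed).
#' @export
write_mtx_triplet <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(m$counts), file.path(dir, "matrix.mtx"))
  writeLines(cell_ids(m), file.path(dir, "barcodes.tsv"))
  writeLines(gene_ids(m), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Cell and gene quality-control thresholds
#'
#' Defaults follow the atlas convention: at most 20% mitochondrial UMIs,
#' total UMI count within \[100, 150000\], detected genes within
#' \[200, 10000\] (all bounds inclusive), and genes kept only when
#' expressed in at least 0.1% of cells.
#'
#' @param max_mito_fraction maximum mitochondrial UMI fraction.
#' @param umi_range,gene_range inclusive `[lo, hi]` ranges.
#' @param min_gene_cell_fraction minimum expressing-cell fraction per gene.
#' @export
qc_thresholds <- function(max_mito_fraction = 0.20,
                          umi_range = c(100, 150000),
                          gene_range = c(200, 10000),
                          min_gene_cell_fraction = 0.001) {
  stopifnot(max_mito_fraction >= 0, max_mito_fraction <= 1,
            umi_range[1] <= umi_range[2], gene_range[1] <= gene_range[2],
            min_gene_cell_fraction >= 0, min_gene_cell_fraction <= 1)
  structure(list(max_mito_fraction = max_mito_fraction,
                 umi_range = umi_range, gene_range = gene_range,
                 min_gene_cell_fraction = min_gene_cell_fraction),
            class = "qc_thresholds")
}

#' Filter cells on mitochondrial fraction, UMI and gene counts
#'
#' A cell survives when its mitochondrial UMI fraction is at most
#' `max_mito_fraction` and both its total UMI count and number of
#' detected genes fall inside the (inclusive) configured ranges. Cell
#' order is preserved.
#'
#' @param m an `ExpressionMatrix` with a raw layer.
#' @param mito_genes character vector of mitochondrial gene symbols;
#'   defaults to symbols prefixed `MT-`.
#' @param thresholds a [qc_thresholds()] object.
#' @return the filtered `ExpressionMatrix`.
#' @export
qc_filter_cells <- function(m, mito_genes = NULL,
                            thresholds = qc_thresholds()) {
  if (is.null(mito_genes))
    mito_genes <- grep("^MT-", gene_ids(m), value = TRUE)
  extra <- setdiff(mito_genes, gene_ids(m))
  if (length(extra))
    stop("mito_genes not in matrix: ", paste(extra, collapse = ", "))
  total <- Matrix::rowSums(m$counts)
  n_genes <- Matrix::rowSums(m$counts > 0)
  mito <- if (length(mito_genes))
    Matrix::rowSums(m$counts[, mito_genes, drop = FALSE]) else
    rep(0, nrow(m$counts))
  mito_frac <- ifelse(total > 0, mito / total, 0)
  keep <- mito_frac <= thresholds$max_mito_fraction &
    total >= thresholds$umi_range[1] & total <= thresholds$umi_range[2] &
    n_genes >= thresholds$gene_range[1] &
    n_genes <= thresholds$gene_range[2]
  if (!any(keep)) warning("all cells removed by QC filters")
  m[keep, ]
}

#' Filter genes on expressing-cell fraction
#'
#' A gene is retained when it is expressed (count > 0) in at least
#' `ceiling(min_cell_fraction * n_cells)` cells.
#'
#' @param m an `ExpressionMatrix`.
#' @param min_cell_fraction minimum expressing-cell fraction.
#' @export
filter_genes <- function(m, min_cell_fraction = 0.001) {
  need <- ceiling(min_cell_fraction * nrow(m$counts))
  keep <- Matrix::colSums(m$counts > 0) >= need
  if (!any(keep)) warning("all genes removed by expression filter")
  m[, keep]
}

#' Log2 TPM-like normalization
#'
#' Per cell, counts are scaled to a fixed total (`scale`, default 1e6 so
#' values are transcripts-per-million-like) and transformed as
#' `log2(1 + scaled)`. Zero counts map to exactly zero.
#'
#' @param m an `ExpressionMatrix` with raw counts.
#' @param scale per-cell target total.
#' @export
normalize_log2_tpm <- function(m, scale = 1e6) {
  total <- Matrix::rowSums(m$counts)
  if (any(total <= 0))
    stop("cells with zero total UMI present; run qc_filter_cells first")
  # row-scale then log-transform the nonzero slot: zeros stay exact zeros
  scaled <- Matrix::Diagonal(x = scale / total) %*% m$counts
  scaled <- methods::as(scaled, "CsparseMatrix")
  scaled@x <- log2(1 + scaled@x)
  dimnames(scaled) <- dimnames(m$counts)
  m$lognorm <- scaled
  m$scale_factor <- scale
  m
}

#' Per-gene mean-centering with magnitude cap
#'
#' Subtracts each gene's mean log-normalized value across cells and
#' clips the result to `[-cap, cap]`. No variance scaling is applied.
#'
#' @param m an `ExpressionMatrix` with a lognorm layer.
#' @param cap absolute value ceiling (default 10).
#' @export
center_relative <- function(m, cap = 10) {
  if (is.null(m$lognorm)) stop("run normalize_log2_tpm first")
  ln <- as.matrix(m$lognorm)
  ctr <- sweep(ln, 2, colMeans(ln), `-`)
  ctr[ctr > cap] <- cap
  ctr[ctr < -cap] <- -cap
  m$centered <- ctr
  m$center_cap <- cap
  m
}
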