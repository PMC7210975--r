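#' Cell-by-gene expression container
#'
#' Holds the three expression layers every downstream statistic consumes:
#' raw UMI counts, log2 TPM-like normalized values, and per-gene
#' mean-centered (magnitude-capped) relative expression. Matrices are
#' cell-major: rows are cells, columns are genes. The raw and lognorm
#' layers share a sparsity pattern (a zero count maps to a zero
#' log-normalized value exactly); the centered layer is dense.
#'
#' @param counts cells x genes matrix of non-negative integer UMI counts
#'   (base matrix or any `Matrix` class; stored as `dgCMatrix`).
#' @param cell_ids,gene_ids optional character vectors overriding
#'   `dimnames(counts)`.
#' @return An object of class `ExpressionMatrix` with elements `counts`,
#'   `lognorm` (NULL until [normalize_log2_tpm()]), `centered` (NULL until
#'   [center_relative()]), and the normalization parameters used.
#' @examples
#' m <- expression_matrix(matrix(rpois(12, 2), 3, 4,
#'   dimnames = list(paste0("c", 1:3), paste0("g", 1:4))))
#' dim(m)
#' @export
expression_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (!is.null(cell_ids)) rownames(counts) <- cell_ids
  if (!is.null(gene_ids)) colnames(counts) <- gene_ids
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry cell ids (rownames) and gene ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate cell ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  x <- counts@x
  if (length(x) && (min(x) < 0 || any(abs(x - round(x)) > 1e-8)))
    stop("raw counts must be non-negative integers")
  structure(
    list(counts = counts, lognorm = NULL, centered = NULL,
         scale_factor = NULL, center_cap = NULL),
    class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$counts)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat(" layers:", paste(c("counts",
                          if (!is.null(x$lognorm)) "lognorm",
                          if (!is.null(x$centered)) "centered"),
                        collapse = ", "), "\n")
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
cell_ids <- function(x) rownames(x$counts)

#' @rdname expression_matrix
#' @export
gene_ids <- function(x) colnames(x$counts)

#' Subset an ExpressionMatrix by cells and/or genes
#'
#' All populated layers are subset consistently.
#'
#' @param x an `ExpressionMatrix`.
#' @param i,j cell and gene indices (any standard matrix index).
#' @param ... ignored.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  x$counts <- x$counts[i, j, drop = FALSE]
  if (!is.null(x$lognorm)) x$lognorm <- x$lognorm[i, j, drop = FALSE]
  if (!is.null(x$centered)) x$centered <- x$centered[i, j, drop = FALSE]
  x
}

#' Validate a per-cell annotation table
#'
#' Checks the mandatory columns (`cell_id`, `sample_id`, `tissue_origin`,
#' `lineage`, `subset`), uniqueness of cell ids, and that tissue origins
#' come from the closed vocabulary used throughout the package.
#'
#' @param df data.frame of per-cell annotations.
#' @param origins allowed tissue-origin labels.
#' @return the validated data.frame (invisibly unchanged).
#' @export
cell_annotation <- function(df, origins = tissue_origins()) {
  need <- c("cell_id", "sample_id", "tissue_origin", "lineage", "subset")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cell annotation lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell ids in annotation")
  bad <- setdiff(unique(df$tissue_origin), origins)
  if (length(bad))
    stop("unknown tissue origins: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(origins, collapse = ", "), ")")
  if (any(!nzchar(df$lineage)) || anyNA(df$lineage))
    stop("lineage must be non-empty for every cell")
  df
}

#' Tissue-origin vocabulary
#'
#' Normal lung (nLung), primary tumor lung (tLung), late-stage tumor
#' lung/bronchus biopsy (tL/B), normal and metastatic lymph node
#' (nLN/mLN), pleural effusion (PE), and brain metastasis (mBrain).
#' @export
tissue_origins <- function() {
  c("nLung", "tLung", "tL/B", "nLN", "mLN", "PE", "mBrain")
}

#' Validate a gene annotation table
#'
#' @param df data.frame with columns `gene_id`, `chromosome`, `start`
#'   (1-based bp).
#' @return validated data.frame.
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "chromosome", "start")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gene annotation lacks columns: ", paste(miss, collapse = ", "))
  if (any(df$start < 1 | is.na(df$start)))
    stop("gene start positions must be >= 1")
  df
}
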