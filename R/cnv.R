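#' Parameters of expression-inferred CNV malignancy calling
#'
#' The procedure classifies tumor-tissue epithelial cells as malignant
#' from the perturbation of chromosomally ordered gene expression:
#' putative malignant cells are diluted with normal spike-in cells to at
#' most `max_malignant_fraction`; uninformative genes (expressed in
#' fewer than `min_cells_per_gene` cells or mean log2 expression below
#' `min_mean_expression`) are removed; per-gene Z-scores clipped to
#' `[-z_clip, z_clip]` are smoothed by a moving average of `window_size`
#' genes within each chromosome and centered per cell; each cell is then
#' summarized by `ms` (mean of squared window values) and `corr`
#' (Pearson correlation with the average profile of the top
#' `top_reference_fraction` cells ranked by `ms`). A cell is malignant
#' when `ms > ms_threshold` or `corr > corr_threshold` (strict).
#'
#' @param max_malignant_fraction ceiling on the putative-malignant share
#'   of the reference mix (default 0.20).
#' @param min_cells_per_gene,min_mean_expression gene informativeness
#'   gates (defaults 10 cells, 0.1 log2 units; both inclusive).
#' @param z_clip symmetric Z-score cap (default 3).
#' @param window_size moving-average width in genes (default 100).
#' @param top_reference_fraction share of most-perturbed cells averaged
#'   into the reference profile (default 0.05).
#' @param ms_threshold,corr_threshold strict malignancy cutoffs
#'   (defaults 0.02 and 0.2).
#' @export
cnv_params <- function(max_malignant_fraction = 0.20,
                       min_cells_per_gene = 10,
                       min_mean_expression = 0.1,
                       z_clip = 3,
                       window_size = 100,
                       top_reference_fraction = 0.05,
                       ms_threshold = 0.02,
                       corr_threshold = 0.2) {
  stopifnot(max_malignant_fraction > 0, max_malignant_fraction < 1,
            window_size >= 2, top_reference_fraction > 0,
            top_reference_fraction < 1, z_clip > 0,
            ms_threshold > 0, corr_threshold > 0)
  structure(as.list(environment()), class = "cnv_params")
}

#' Dilute putative malignant cells with normal spike-ins
#'
#' Samples cells without replacement from a normal pool until the
#' putative malignant cells are at most `max_malignant_fraction` of the
#' returned set. If the pool is too small the entire pool is used and a
#' warning raised.
#'
#' @param tumor_cells character vector of putative malignant cell ids.
#' @param normal_pool character vector of candidate normal cell ids
#'   (disjoint from `tumor_cells`).
#' @param params a [cnv_params()] object.
#' @param seed integer seed for the sampling.
#' @return list with `cells` (tumor then sampled normals), `spike_in`
#'   (logical, parallel to `cells`).
#' @export
assemble_reference_mix <- function(tumor_cells, normal_pool,
                                   params = cnv_params(), seed = 1L) {
  if (!length(tumor_cells)) stop("tumor_cells is empty")
  if (length(intersect(tumor_cells, normal_pool)))
    stop("tumor_cells and normal_pool overlap")
  n_t <- length(tumor_cells)
  # smallest normal count giving n_t / (n_t + n_n) <= fraction
  n_needed <- ceiling(n_t / params$max_malignant_fraction) - n_t
  if (n_needed > length(normal_pool)) {
    warning(sprintf(
      "normal pool (%d) too small to dilute %d tumor cells below %.0f%%; using entire pool",
      length(normal_pool), n_t, 100 * params$max_malignant_fraction))
    picked <- normal_pool
  } else {
    rng <- local_rng(seed)
    picked <- sample(normal_pool, n_needed)
    rng()
  }
  list(cells = c(tumor_cells, picked),
       spike_in = c(rep(FALSE, n_t), rep(TRUE, length(picked))))
}

# Scoped RNG: returns a restore function; keeps global RNG untouched.
local_rng <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
    invisible(NULL)
  }
}

#' Remove uninformative genes before CNV inference
#'
#' Keeps genes expressed in at least `min_cells_per_gene` cells and with
#' mean log-normalized expression of at least `min_mean_expression`
#' across all cells (both bounds inclusive).
#'
#' @inheritParams assemble_reference_mix
#' @param m an `ExpressionMatrix` with a lognorm layer.
#' @export
cnv_gene_filter <- function(m, params = cnv_params()) {
  if (is.null(m$lognorm)) stop("run normalize_log2_tpm first")
  n_expr <- Matrix::colSums(m$lognorm > 0)
  mu <- Matrix::colMeans(m$lognorm)
  m[, n_expr >= params$min_cells_per_gene &
      mu >= params$min_mean_expression]
}

#' Per-gene Z-score with symmetric clipping
#'
#' Z uses the population standard deviation across cells (denominator
#' n). Zero-variance genes are dropped with a warning. Values are
#' clipped to `[-z_clip, z_clip]`.
#'
#' @param m an `ExpressionMatrix` with a lognorm layer (gene-filtered).
#' @param params a [cnv_params()] object.
#' @return dense cells x genes matrix of clipped Z-scores.
#' @export
zscore_clip <- function(m, params = cnv_params()) {
  ln <- as.matrix(m$lognorm)
  n <- nrow(ln)
  mu <- colMeans(ln)
  sd_pop <- sqrt(colMeans(ln^2) - mu^2)
  sd_pop[sd_pop < 0] <- 0  # guard tiny negative rounding
  keep <- sd_pop > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance gene(s) dropped before Z-scoring")
  z <- sweep(sweep(ln[, keep, drop = FALSE], 2, mu[keep], `-`),
             2, sd_pop[keep], `/`)
  z[z > params$z_clip] <- params$z_clip
  z[z < -params$z_clip] <- -params$z_clip
  z
}

#' Chromosome-wise moving-average smoothing of Z-scores
#'
#' Genes are sorted by (chromosome, start); within each chromosome with
#' at least `window_size` genes the windows are all contiguous stride-1
#' spans of `window_size` genes (n - w + 1 windows); shorter chromosomes
#' collapse to a single window over all their genes and are flagged.
#'
#' @param z cells x genes clipped Z matrix from [zscore_clip()].
#' @param genes gene annotation data.frame (`gene_id`, `chromosome`,
#'   `start`) covering every column of `z`.
#' @param params a [cnv_params()] object.
#' @return list with `windows` (cells x n_windows matrix) and `info`
#'   (data.frame: chromosome, first/last gene index in sorted order,
#'   short-chromosome flag).
#' @export
windowed_smooth <- function(z, genes, params = cnv_params()) {
  genes <- gene_annotation(genes)
  idx <- match(colnames(z), genes$gene_id)
  if (anyNA(idx))
    stop("genes missing position annotation: ",
         paste(utils::head(colnames(z)[is.na(idx)], 10), collapse = ", "))
  ga <- genes[idx, , drop = FALSE]
  ord <- order(ga$chromosome, ga$start)
  z <- z[, ord, drop = FALSE]
  chr <- ga$chromosome[ord]
  w <- params$window_size
  out <- list(); info <- list()
  for (cc in unique(chr)) {
    cols <- which(chr == cc)
    n <- length(cols)
    zc <- z[, cols, drop = FALSE]
    if (n < w) {
      out[[cc]] <- matrix(rowMeans(zc), ncol = 1)
      info[[cc]] <- data.frame(chromosome = cc, n_genes = n,
                               n_windows = 1L, short = TRUE)
    } else {
      # moving average via cumulative sums along genes
      cs <- t(apply(zc, 1, cumsum))
      k <- n - w + 1
      win <- (cs[, w:n, drop = FALSE] -
                cbind(0, cs[, seq_len(k - 1), drop = FALSE])) / w
      out[[cc]] <- win
      info[[cc]] <- data.frame(chromosome = cc, n_genes = n,
                               n_windows = k, short = FALSE)
    }
  }
  windows <- do.call(cbind, out)
  rownames(windows) <- rownames(z)
  list(windows = windows, info = do.call(rbind, info))
}

#' Center each cell's window profile
#'
#' Subtracts the per-cell mean of the window vector; idempotent.
#'
#' @param w cells x windows matrix from [windowed_smooth()].
#' @export
center_cells <- function(w) {
  w - rowMeans(w)
}

#' Summarize CNV perturbation per cell
#'
#' `ms` is the mean of squared window values. The reference profile is
#' the element-wise mean of the window vectors of the top
#' `ceiling(top_reference_fraction * n)` cells ranked by `ms`; `corr` is
#' each cell's Pearson correlation with it. Cells with a zero-variance
#' window vector get `corr = NA` (treated as never exceeding the
#' correlation threshold).
#'
#' @param w centered cells x windows matrix.
#' @param params a [cnv_params()] object.
#' @return data.frame: `cell_id`, `ms`, `corr`, `n_windows`.
#' @export
score_cells <- function(w, params = cnv_params()) {
  n <- nrow(w)
  if (n < 20)
    stop("need at least 20 cells to form a top-5% reference; ",
         "enlarge the reference mix")
  ms <- rowMeans(w^2)
  n_top <- ceiling(params$top_reference_fraction * n)
  top <- order(ms, decreasing = TRUE)[seq_len(n_top)]
  ref <- colMeans(w[top, , drop = FALSE])
  corr <- rep(NA_real_, n)
  if (stats::sd(ref) > 0) {
    ok <- apply(w, 1, stats::sd) > 0
    corr[ok] <- as.vector(stats::cor(t(w[ok, , drop = FALSE]), ref))
  }
  data.frame(cell_id = rownames(w), ms = ms, corr = corr,
             n_windows = ncol(w), row.names = NULL)
}

#' Apply the malignancy decision rule
#'
#' Malignant iff `ms > ms_threshold` OR `corr > corr_threshold`, both
#' strict; undefined correlations never pass the correlation arm.
#'
#' @param scores data.frame from [score_cells()].
#' @param params a [cnv_params()] object.
#' @export
classify_malignant <- function(scores, params = cnv_params()) {
  corr_ok <- !is.na(scores$corr) & scores$corr > params$corr_threshold
  scores$malignant <- scores$ms > params$ms_threshold | corr_ok
  scores
}

#' End-to-end CNV malignancy calling
#'
#' Assembles the reference mix, filters genes, Z-scores, smooths,
#' centers, scores and classifies. Spike-in normal cells are scored and
#' classified alongside tumor cells but flagged in the output.
#'
#' @param m an `ExpressionMatrix` with a lognorm layer covering at least
#'   `tumor_cells` and `normal_pool`.
#' @param genes gene annotation data.frame.
#' @param tumor_cells,normal_pool cell-id vectors as in
#'   [assemble_reference_mix()].
#' @param params a [cnv_params()] object.
#' @param seed seed for the spike-in sampling.
#' @return data.frame: `cell_id`, `ms`, `corr`, `malignant`,
#'   `is_spike_in`, `n_windows`; attribute `seed` records the seed.
#' @export
infer_cnv <- function(m, genes, tumor_cells, normal_pool,
                      params = cnv_params(), seed = 1L) {
  mix <- assemble_reference_mix(tumor_cells, normal_pool, params, seed)
  sub <- m[mix$cells, ]
  sub <- cnv_gene_filter(sub, params)
  z <- zscore_clip(sub, params)
  sm <- windowed_smooth(z, genes, params)
  ctr <- center_cells(sm$windows)
  scores <- classify_malignant(score_cells(ctr, params), params)
  scores$is_spike_in <- mix$spike_in[match(scores$cell_id, mix$cells)]
  attr(scores, "seed") <- seed
  scores
}
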