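#' Select variably expressed genes
#'
#' Mean/dispersion selection in the style of early droplet-data
#' toolkits: genes are kept when their mean log-normalized expression
#' lies strictly inside `(mean_low, mean_high)` and their standardized
#' dispersion exceeds `min_dispersion`. Dispersion is variance/mean of
#' the log-normalized values, Z-standardized within `n_bins` equal-count
#' bins of the mean (so highly expressed genes are not trivially the
#' most dispersed).
#'
#' @param m an `ExpressionMatrix` with a lognorm layer.
#' @param mean_low,mean_high mean-expression window (defaults 0.0125, 3).
#' @param min_dispersion standardized-dispersion cutoff (default 0.5).
#' @param n_bins number of mean bins (default 20).
#' @return character vector of selected gene ids.
#' @export
select_variable_genes <- function(m, mean_low = 0.0125, mean_high = 3,
                                  min_dispersion = 0.5, n_bins = 20) {
  ln <- m$lognorm
  mu <- Matrix::colMeans(ln)
  n <- nrow(ln)
  v <- (Matrix::colMeans(ln^2) - mu^2) * n / max(1, n - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  in_window <- mu > mean_low & mu < mean_high
  genes <- gene_ids(m)[in_window]
  if (!length(genes)) return(character())
  mu_w <- mu[in_window]; disp_w <- disp[in_window]
  n_bins <- min(n_bins, length(genes))
  bins <- if (n_bins < 2) rep(1L, length(genes)) else
    cut(rank(mu_w, ties.method = "first"), breaks = n_bins,
        labels = FALSE)
  zdisp <- disp_w
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(disp_w[i])
    zdisp[i] <- if (is.na(s) || s == 0) 0 else
      (disp_w[i] - mean(disp_w[i])) / s
  }
  genes[zdisp > min_dispersion]
}

#' Split a mixed stromal population along the first principal component
#'
#' PCA is run on the per-gene centered log-normalized matrix restricted
#' to variable genes. The sign of PC1 is oriented so cells with high
#' average expression of `markers_a` score positive; cells on the
#' positive side are candidate `A`, negative side candidate `B`. A final
#' label additionally requires the cell's average log-normalized
#' expression of the corresponding marker set to exceed `marker_min`,
#' otherwise the cell is `undetermined`.
#'
#' @param m an `ExpressionMatrix` with a lognorm layer.
#' @param markers_a,markers_b marker gene sets for the two populations
#'   (e.g. endothelial versus fibroblast markers).
#' @param marker_min average log-normalized expression floor (default 1,
#'   strict).
#' @param variable_genes genes to feed the PCA (default:
#'   [select_variable_genes()]).
#' @return list: `label` (factor A/B/undetermined per cell), `pc1`
#'   (oriented scores), `variable_genes`.
#' @export
pc1_partition <- function(m, markers_a, markers_b, marker_min = 1,
                          variable_genes = NULL) {
  if (nrow(m$counts) < 2) stop("need at least 2 cells")
  for (set in list(markers_a, markers_b))
    if (!length(intersect(set, gene_ids(m))))
      stop("marker set absent from matrix")
  if (is.null(variable_genes)) variable_genes <- select_variable_genes(m)
  if (length(variable_genes) < 2)
    stop("fewer than 2 variable genes; supply variable_genes explicitly")
  x <- as.matrix(m$lognorm[, variable_genes, drop = FALSE])
  x <- sweep(x, 2, colMeans(x))
  pc1 <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = 1)$x[, 1]
  avg_a <- Matrix::rowMeans(
    m$lognorm[, intersect(markers_a, gene_ids(m)), drop = FALSE])
  avg_b <- Matrix::rowMeans(
    m$lognorm[, intersect(markers_b, gene_ids(m)), drop = FALSE])
  # orient: markers_a-high cells positive
  if (stats::cor(pc1, avg_a - avg_b) < 0) pc1 <- -pc1
  side_a <- pc1 > 0
  label <- ifelse(side_a & avg_a > marker_min, "A",
                  ifelse(!side_a & avg_b > marker_min, "B",
                         "undetermined"))
  list(label = factor(stats::setNames(label, cell_ids(m)),
                      levels = c("A", "B", "undetermined")),
       pc1 = stats::setNames(pc1, cell_ids(m)),
       variable_genes = variable_genes)
}
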