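#' Thresholds for marker / signature gene selection
#'
#' Subset and cell-state signatures use up-regulated genes only with
#' `log2FC > 1`; pairwise stage comparisons use `|log2FC| > 0.585`
#' (about log2 of 1.5) in either direction. Both use a two-sided
#' equal-variance Student's t test at p < 0.01, Bonferroni-adjusted
#' p < 0.01, and require expression in more than 25% of cells in at
#' least one group (all strict).
#'
#' @param min_abs_log2fc minimum |log2 fold change| (strict).
#' @param max_p,max_adj_p raw and Bonferroni-adjusted p ceilings (strict).
#' @param min_pct minimum expressing-cell fraction in the better group
#'   (strict).
#' @param direction `"up"` (group-1-high only) or `"both"`.
#' @export
marker_thresholds <- function(min_abs_log2fc = 1, max_p = 0.01,
                              max_adj_p = 0.01, min_pct = 0.25,
                              direction = c("up", "both")) {
  direction <- match.arg(direction)
  stopifnot(min_abs_log2fc > 0, max_p > 0, max_adj_p > 0, min_pct > 0)
  structure(list(min_abs_log2fc = min_abs_log2fc, max_p = max_p,
                 max_adj_p = max_adj_p, min_pct = min_pct,
                 direction = direction), class = "marker_thresholds")
}

#' Fraction of cells expressing each gene
#'
#' "Expressed" means log-normalized value strictly greater than zero.
#'
#' @param m an `ExpressionMatrix` with a lognorm layer.
#' @param cells cell ids (or logical/integer index) defining the group.
#' @return named per-gene fraction vector.
#' @export
percent_expressing <- function(m, cells) {
  sub <- m$lognorm[cells, , drop = FALSE]
  if (!nrow(sub)) stop("empty cell set")
  Matrix::colSums(sub > 0) / nrow(sub)
}

#' Log2 fold change as difference of log2-scale group means
#'
#' Data are already on the log2 scale, so the fold change is the
#' difference of group means. `method = "expm"` instead de-logs, averages
#' and re-logs (log2 of ratio of linear-scale means).
#'
#' @param m an `ExpressionMatrix` with a lognorm layer.
#' @param group_a,group_b disjoint non-empty cell-id sets.
#' @param method `"logmeans"` (default) or `"expm"`.
#' @return named per-gene log2FC (A relative to B).
#' @export
log2_fold_change <- function(m, group_a, group_b,
                             method = c("logmeans", "expm")) {
  method <- match.arg(method)
  if (length(intersect(group_a, group_b)))
    stop("groups overlap")
  a <- m$lognorm[group_a, , drop = FALSE]
  b <- m$lognorm[group_b, , drop = FALSE]
  if (!nrow(a) || !nrow(b)) stop("empty group")
  if (method == "logmeans") {
    Matrix::colMeans(a) - Matrix::colMeans(b)
  } else {
    log2(Matrix::colMeans(2^a - 1) + 1) - log2(Matrix::colMeans(2^b - 1) + 1)
  }
}

# Vectorized two-sided equal-variance Student's t test per gene
# (columns). Genes with zero pooled variance get p = 1 and a flag.
col_t_test <- function(a, b) {
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- colSums(sweep(a, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(b, 2, m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)
  degenerate <- se == 0
  p[degenerate] <- 1
  tstat[degenerate] <- 0
  list(t = tstat, p = p, degenerate = degenerate)
}

#' Differential marker selection between two cell groups
#'
#' Genes first pass the expressing-fraction gate (PCT strictly above
#' `min_pct` in at least one group); those genes are tested with a
#' two-sided equal-variance Student's t on log-normalized values and
#' Bonferroni-adjusted over the number of genes tested. A gene passes
#' when log2FC (per `direction`), raw p, adjusted p and PCT thresholds
#' are all met. Results are sorted by log2FC descending.
#'
#' @inheritParams log2_fold_change
#' @param thresholds a [marker_thresholds()] object.
#' @param fc_method passed to [log2_fold_change()].
#' @return data.frame: `gene_id`, `log2fc`, `p_value`, `adj_p`, `pct1`,
#'   `pct2`, `degenerate`, `passed`.
#' @export
differential_markers <- function(m, group_a, group_b,
                                 thresholds = marker_thresholds(),
                                 fc_method = "logmeans") {
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs at least 3 cells")
  pct1 <- percent_expressing(m, group_a)
  pct2 <- percent_expressing(m, group_b)
  tested <- pct1 > thresholds$min_pct | pct2 > thresholds$min_pct
  genes <- gene_ids(m)[tested]
  if (!length(genes)) {
    return(data.frame(gene_id = character(), log2fc = numeric(),
                      p_value = numeric(), adj_p = numeric(),
                      pct1 = numeric(), pct2 = numeric(),
                      degenerate = logical(), passed = logical()))
  }
  sub <- m[, genes]
  lfc <- log2_fold_change(sub, group_a, group_b, method = fc_method)
  tt <- col_t_test(as.matrix(sub$lognorm[group_a, , drop = FALSE]),
                   as.matrix(sub$lognorm[group_b, , drop = FALSE]))
  adj_p <- pmin(1, tt$p * length(genes))
  fc_ok <- if (thresholds$direction == "up")
    lfc > thresholds$min_abs_log2fc else
    abs(lfc) > thresholds$min_abs_log2fc
  res <- data.frame(gene_id = genes, log2fc = lfc, p_value = tt$p,
                    adj_p = adj_p, pct1 = pct1[genes], pct2 = pct2[genes],
                    degenerate = tt$degenerate,
                    passed = fc_ok & tt$p < thresholds$max_p &
                      adj_p < thresholds$max_adj_p,
                    row.names = NULL)
  res[order(res$log2fc, decreasing = TRUE), , drop = FALSE]
}

#' Pairwise stage-comparison markers
#'
#' [differential_markers()] preset for early- versus advanced-stage (or
#' primary versus metastatic) cancer-cell comparisons: both directions,
#' |log2FC| > 0.585.
#'
#' @inheritParams differential_markers
#' @export
stage_comparison_markers <- function(m, group_a, group_b) {
  differential_markers(m, group_a, group_b,
                       marker_thresholds(min_abs_log2fc = 0.585,
                                         direction = "both"))
}

#' Mean-expression signature score
#'
#' Per-cell score is the mean log-normalized expression over the
#' gene set (intersected with the matrix); optionally also averaged per
#' sample.
#'
#' @param m an `ExpressionMatrix` with a lognorm layer.
#' @param gene_set character vector of gene ids.
#' @param cells cell ids to score (default: all).
#' @param samples optional named per-cell sample labels for per-sample
#'   means (names or order matching `cells`).
#' @return list: `cell_scores` (named), `sample_scores` (or NULL),
#'   `missing_genes`.
#' @export
signature_score <- function(m, gene_set, cells = cell_ids(m),
                            samples = NULL) {
  present <- intersect(gene_set, gene_ids(m))
  missing <- setdiff(gene_set, gene_ids(m))
  if (!length(present))
    stop("no signature genes present in matrix; missing: ",
         paste(utils::head(missing, 10), collapse = ", "))
  sc <- Matrix::rowMeans(m$lognorm[cells, present, drop = FALSE])
  names(sc) <- cells
  sample_scores <- NULL
  if (!is.null(samples))
    sample_scores <- tapply(sc, samples, mean)
  list(cell_scores = sc, sample_scores = sample_scores,
       missing_genes = missing)
}

#' Quartile stratification of per-sample signature scores
#'
#' Samples at or below the 25th percentile are `low`, at or above the
#' 75th `high`, the middle half `excluded`. Percentiles use linear
#' (type 7) interpolation.
#'
#' @param scores named numeric per-sample scores (>= 8 samples).
#' @return factor with levels `low`, `excluded`, `high`, named as
#'   `scores`.
#' @export
stratify_percentiles <- function(scores) {
  if (length(scores) < 8) stop("need at least 8 samples")
  if (stats::sd(scores) == 0)
    stop("all scores identical; no stratification possible")
  q <- stats::quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
  cls <- ifelse(scores <= q[1], "low",
                ifelse(scores >= q[2], "high", "excluded"))
  factor(stats::setNames(cls, names(scores)),
         levels = c("low", "excluded", "high"))
}

#' Survival comparison between signature-high and -low samples
#'
#' Stratifies samples by [stratify_percentiles()], truncates follow-up
#' at `censor_years` (deaths beyond it become censored observations at
#' the truncation time; `exclude_beyond = TRUE` instead drops those
#' samples), and runs a two-sided log-rank test.
#'
#' @param surv data.frame: `sample_id`, `time_days`, `event` (1 death),
#'   `score`.
#' @param censor_years follow-up truncation horizon (default 10).
#' @param exclude_beyond drop instead of censor samples with events past
#'   the horizon.
#' @return list: `classes`, `data` (analyzed table), `chisq`, `p_value`.
#' @export
survival_stratified <- function(surv, censor_years = 10,
                                exclude_beyond = FALSE) {
  need <- c("sample_id", "time_days", "event", "score")
  miss <- setdiff(need, names(surv))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cls <- stratify_percentiles(stats::setNames(surv$score, surv$sample_id))
  surv$class <- cls[surv$sample_id]
  d <- surv[surv$class != "excluded", , drop = FALSE]
  horizon <- censor_years * 365.25
  beyond <- d$time_days > horizon
  if (exclude_beyond) {
    d <- d[!(beyond & d$event == 1), , drop = FALSE]
    beyond <- d$time_days > horizon
  }
  d$event[beyond] <- 0
  d$time_days[beyond] <- horizon
  fit <- survival::survdiff(
    survival::Surv(time_days, event) ~ class, data = d)
  p <- stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE)
  list(classes = cls, data = d, chisq = unname(fit$chisq), p_value = p)
}
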