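#' Subset x tissue-origin contingency statistics
#'
#' Builds the observed subset-by-origin cell-count table, the expected
#' table under independence (row total x column total / grand total),
#' Pearson residuals `(O - E) / sqrt(E)` and observed/expected ratios
#' `R_O/E = O / E`, together with the chi-square statistic. Rows or
#' columns whose margin is zero are dropped with a warning.
#'
#' @param ann cell annotation data.frame.
#' @param subset_field,origin_field column names (defaults `subset`,
#'   `tissue_origin`).
#' @return object of class `contingency_stats`: `observed`, `expected`,
#'   `pearson_residual`, `roe`, `chi2`, `dof`, `p_value`.
#' @export
contingency <- function(ann, subset_field = "subset",
                        origin_field = "tissue_origin") {
  obs <- table(ann[[subset_field]], ann[[origin_field]])
  zr <- rowSums(obs) == 0; zc <- colSums(obs) == 0
  if (any(zr) || any(zc)) {
    warning("dropping zero margins: ",
            paste(c(rownames(obs)[zr], colnames(obs)[zc]), collapse = ", "))
    obs <- obs[!zr, !zc, drop = FALSE]
  }
  if (nrow(obs) < 2 || ncol(obs) < 2)
    stop("need at least 2 subsets and 2 origins")
  obs <- unclass(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  resid <- (obs - expd) / sqrt(expd)
  roe <- obs / expd
  chi2 <- sum(resid[expd > 0]^2)
  dof <- as.integer((nrow(obs) - 1) * (ncol(obs) - 1))
  structure(list(observed = obs, expected = expd,
                 pearson_residual = resid, roe = roe, chi2 = chi2,
                 dof = dof,
                 p_value = stats::pchisq(chi2, dof, lower.tail = FALSE)),
            class = "contingency_stats")
}

#' @export
print.contingency_stats <- function(x, ...) {
  cat(sprintf("contingency_stats: %d subsets x %d origins, chi2 = %.4g (dof %d, p = %.3g)\n",
              nrow(x$observed), ncol(x$observed), x$chi2, x$dof, x$p_value))
  invisible(x)
}

#' Observed/expected tissue-preference ratio
#'
#' Extracts the R_O/E table; entries with expected count zero are NA.
#'
#' @param stats a `contingency_stats` object.
#' @export
roe <- function(stats) {
  out <- stats$roe
  out[stats$expected == 0] <- NA_real_
  out
}

#' Per-sample cell-subset proportions within a compartment
#'
#' Computes each subset's fraction of a sample's cells after excluding
#' the listed lineages from the denominator. The default excludes only
#' the epithelial lineage (the "non-epithelial compartment"); pass
#' `exclude_lineages = c("Epithelial", "Fibroblast", "Endothelial")` for
#' the immune-only variant. Samples with no qualifying cells are
#' omitted with a warning.
#'
#' @param ann cell annotation data.frame.
#' @param exclude_lineages lineages removed from the denominator.
#' @return data.frame: `sample_id`, `subset`, `n`, `fraction` (fractions
#'   sum to 1 within each sample).
#' @export
immune_proportions <- function(ann, exclude_lineages = "Epithelial") {
  keep <- !(ann$lineage %in% exclude_lineages)
  dropped <- setdiff(unique(ann$sample_id), unique(ann$sample_id[keep]))
  if (length(dropped))
    warning("samples without qualifying cells omitted: ",
            paste(dropped, collapse = ", "))
  d <- ann[keep, , drop = FALSE]
  tab <- as.data.frame(table(sample_id = d$sample_id, subset = d$subset),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tot <- tapply(tab$n, tab$sample_id, sum)
  tab$fraction <- tab$n / tot[tab$sample_id]
  tab[order(tab$sample_id, tab$subset), , drop = FALSE]
}

#' Compare per-sample subset fractions between origin groups
#'
#' Two-sided equal-variance Student's t test on per-sample fractions of
#' each subset between two groups of samples.
#'
#' @param fractions output of [immune_proportions()].
#' @param groups named character vector: sample_id -> group label.
#' @param group_a,group_b the two group labels to compare.
#' @return data.frame: `subset`, `mean_a`, `mean_b`, `t`, `p_value`.
#' @export
group_comparison <- function(fractions, groups, group_a, group_b) {
  fractions$group <- groups[fractions$sample_id]
  d <- fractions[fractions$group %in% c(group_a, group_b), , drop = FALSE]
  out <- lapply(split(d, d$subset), function(s) {
    xa <- s$fraction[s$group == group_a]
    xb <- s$fraction[s$group == group_b]
    if (length(xa) < 2 || length(xb) < 2)
      stop("each group needs at least 2 samples (subset ", s$subset[1], ")")
    tt <- stats::t.test(xa, xb, var.equal = TRUE)
    data.frame(subset = s$subset[1], mean_a = mean(xa), mean_b = mean(xb),
               t = unname(tt$statistic), p_value = tt$p.value)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a contingency result as a long table
#'
#' @param stats a `contingency_stats` object.
#' @param path optional TSV destination.
#' @return long data.frame: `subset`, `origin`, `observed`, `expected`,
#'   `residual`, `roe`.
#' @export
composition_table <- function(stats, path = NULL) {
  long <- expand.grid(subset = rownames(stats$observed),
                      origin = colnames(stats$observed),
                      stringsAsFactors = FALSE)
  idx <- cbind(match(long$subset, rownames(stats$observed)),
               match(long$origin, colnames(stats$observed)))
  long$observed <- stats$observed[idx]
  long$expected <- stats$expected[idx]
  long$residual <- stats$pearson_residual[idx]
  long$roe <- stats$roe[idx]
  if (!is.null(path))
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  long
}
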