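#' Load a ligand-receptor pair table
#'
#' TSV with at least `ligand` and `receptor` columns (an optional
#' `pair_id` is kept, otherwise generated as `ligand_receptor`).
#' Duplicate (ligand, receptor) rows are collapsed with a warning.
#'
#' @param path TSV file.
#' @param genes optional gene universe; pairs with either partner
#'   outside it are kept but flagged `usable = FALSE`.
#' @return data.frame: `pair_id`, `ligand`, `receptor`, `usable`.
#' @export
load_lr_pairs <- function(path, genes = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty ligand-receptor table: ", path)
  need <- c("ligand", "receptor")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  key <- paste(df$ligand, df$receptor, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate pair(s) collapsed")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  if (is.null(df$pair_id))
    df$pair_id <- paste(df$ligand, df$receptor, sep = "_")
  df$usable <- if (is.null(genes)) TRUE else
    df$ligand %in% genes & df$receptor %in% genes
  rownames(df) <- NULL
  df[, c("pair_id", "ligand", "receptor", "usable")]
}

#' Ligand-receptor interaction score for one cluster pair
#'
#' Defined only when the ligand is expressed in more than `min_pct` of
#' the ligand-side cluster's cells and the receptor in more than
#' `min_pct` of the receptor-side cluster's; then the score is the mean
#' of the two cluster-mean log-normalized expressions.
#'
#' @param m an `ExpressionMatrix` with a lognorm layer.
#' @param labels named per-cell cluster labels (names = cell ids).
#' @param ligand,receptor gene ids.
#' @param cluster_a ligand-side cluster; `cluster_b` receptor-side.
#' @param cluster_b see above.
#' @param min_pct expressing-fraction gate (default 0.25, strict).
#' @return numeric score, or `NA` when gated out.
#' @export
interaction_score <- function(m, labels, ligand, receptor,
                              cluster_a, cluster_b, min_pct = 0.25) {
  for (cl in c(cluster_a, cluster_b))
    if (!cl %in% labels) stop("unknown cluster: ", cl)
  cells_a <- names(labels)[labels == cluster_a]
  cells_b <- names(labels)[labels == cluster_b]
  la <- m$lognorm[cells_a, ligand]
  rb <- m$lognorm[cells_b, receptor]
  if (mean(la > 0) <= min_pct || mean(rb > 0) <= min_pct)
    return(NA_real_)
  (mean(la) + mean(rb)) / 2
}

#' Permutation test for all pair x cluster-pair combinations
#'
#' For every usable ligand-receptor pair and every ordered cluster pair
#' (a: ligand side, b: receptor side), the observed score is computed as
#' in [interaction_score()]; cluster labels are then permuted uniformly
#' `n_perm` times (one shared seeded permutation stream for all pairs)
#' and the one-sided p-value is the fraction of permuted scores at least
#' as large as the observed one. Combinations whose observed score is
#' undefined (expressing-fraction gate) get `p = 1`.
#'
#' @param m an `ExpressionMatrix` with a lognorm layer.
#' @param labels named per-cell cluster labels.
#' @param pairs data.frame from [load_lr_pairs()] (or with columns
#'   `pair_id`, `ligand`, `receptor`).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param min_pct expressing-fraction gate.
#' @param pseudocount use `(k + 1) / (n + 1)` instead of `k / n` for p.
#' @param include_self score same-cluster combinations too (default
#'   TRUE; the lineage filter usually removes them later).
#' @return data.frame: `pair_id`, `ligand`, `receptor`, `cluster_a`,
#'   `cluster_b`, `score`, `p_value`.
#' @export
permutation_test <- function(m, labels, pairs, n_perm = 1000, seed = 1L,
                             min_pct = 0.25, pseudocount = FALSE,
                             include_self = TRUE) {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value grid")
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  if ("usable" %in% names(pairs)) pairs <- pairs[pairs$usable, , drop = FALSE]
  used <- unique(c(pairs$ligand, pairs$receptor))
  absent <- setdiff(used, gene_ids(m))
  if (length(absent))
    stop("pair genes absent from matrix: ", paste(absent, collapse = ", "))
  cells <- names(labels)
  expr <- as.matrix(m$lognorm[cells, used, drop = FALSE])
  lab <- factor(labels, levels = clusters)

  n_by <- tabulate(lab, nbins = length(clusters))
  sums <- rowsum(expr, lab)
  means_obs <- sums / n_by
  pct_obs <- rowsum((expr > 0) + 0, lab) / n_by
  rownames(means_obs) <- rownames(pct_obs) <- clusters

  grid <- expand.grid(pair = seq_len(nrow(pairs)),
                      a = clusters, b = clusters,
                      stringsAsFactors = FALSE)
  if (!include_self) grid <- grid[grid$a != grid$b, , drop = FALSE]
  li <- match(pairs$ligand[grid$pair], used)
  ri <- match(pairs$receptor[grid$pair], used)
  ai <- match(grid$a, clusters)
  bi <- match(grid$b, clusters)
  gate <- pct_obs[cbind(ai, li)] > min_pct & pct_obs[cbind(bi, ri)] > min_pct
  obs <- (means_obs[cbind(ai, li)] + means_obs[cbind(bi, ri)]) / 2

  rng <- local_rng(seed)
  ge <- integer(nrow(grid))
  for (p in seq_len(n_perm)) {
    fp <- factor(sample(as.character(lab)), levels = clusters)
    mp <- rowsum(expr, fp) / tabulate(fp, nbins = length(clusters))
    sp <- (mp[cbind(ai, li)] + mp[cbind(bi, ri)]) / 2
    ge <- ge + (sp >= obs)
  }
  rng()
  p_val <- if (pseudocount) (ge + 1) / (n_perm + 1) else ge / n_perm
  p_val[!gate] <- 1
  data.frame(pair_id = pairs$pair_id[grid$pair],
             ligand = pairs$ligand[grid$pair],
             receptor = pairs$receptor[grid$pair],
             cluster_a = grid$a, cluster_b = grid$b,
             score = ifelse(gate, obs, NA_real_),
             p_value = p_val, row.names = NULL)
}

#' Four-step filtering of interaction results
#'
#' Applies, in any order (the filters commute): (1) remove pairs whose
#' ligand or receptor is a collagen gene (symbol matching
#' `collagen_regex`); (2) remove combinations where both clusters belong
#' to the same lineage; (3) remove combinations involving a cluster
#' comprising at most `min_subset_fraction` of the immune + stromal
#' cells; (4) keep p-values strictly below `alpha` as significant.
#'
#' @param results data.frame from [permutation_test()].
#' @param ann cell annotation data.frame (provides cluster -> lineage
#'   and cluster sizes; clusters are `subset` values).
#' @param min_subset_fraction subset-size floor within the immune +
#'   stromal compartment (default 0.001).
#' @param alpha significance level (default 0.05, strict).
#' @param collagen_regex gene-symbol pattern for collagens.
#' @param epithelial_lineages lineages excluded from the subset-floor
#'   denominator.
#' @return filtered results with a `significant` column (all TRUE).
#' @export
filter_interactions <- function(results, ann, min_subset_fraction = 0.001,
                                alpha = 0.05,
                                collagen_regex = "^COL[0-9]",
                                epithelial_lineages = "Epithelial") {
  lineage_of <- tapply(ann$lineage, ann$subset, function(x) x[1])
  clusters_used <- unique(c(results$cluster_a, results$cluster_b))
  miss <- clusters_used[!clusters_used %in% names(lineage_of)]
  if (length(miss))
    stop("no lineage known for cluster(s): ", paste(miss, collapse = ", "))
  # (1) collagen pairs
  keep <- !(grepl(collagen_regex, results$ligand) |
              grepl(collagen_regex, results$receptor))
  # (2) same-lineage cluster pairs
  keep <- keep & lineage_of[results$cluster_a] != lineage_of[results$cluster_b]
  # (3) subset floor over immune + stromal cells; epithelial clusters
  # are not part of that compartment and pass through
  nonepi <- ann[!(ann$lineage %in% epithelial_lineages), , drop = FALSE]
  frac <- table(nonepi$subset) / nrow(nonepi)
  small <- names(frac)[as.vector(frac) <= min_subset_fraction]
  keep <- keep & !(results$cluster_a %in% small) &
    !(results$cluster_b %in% small)
  # (4) permutation significance
  keep <- keep & results$p_value < alpha
  out <- results[keep, , drop = FALSE]
  out$significant <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Count significant interactions per directed cluster pair
#'
#' @param results filtered results from [filter_interactions()].
#' @param clusters optional cluster universe fixing matrix dimensions.
#' @return integer matrix; entry (a, b) counts significant ligand (from
#'   a) to receptor (on b) pairs.
#' @export
count_significant <- function(results, clusters = NULL) {
  if (is.null(clusters))
    clusters <- sort(unique(c(results$cluster_a, results$cluster_b)))
  out <- matrix(0L, length(clusters), length(clusters),
                dimnames = list(clusters, clusters))
  if (nrow(results)) {
    tab <- table(factor(results$cluster_a, levels = clusters),
                 factor(results$cluster_b, levels = clusters))
    out[] <- as.integer(tab)
  }
  out
}
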