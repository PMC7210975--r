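# Shared fixture builders and independent oracles. Oracles are written
# as plain loops over definitions, deliberately sharing no code with
# the package internals they check.

dense_em <- function(mat, cells = NULL, genes = NULL) {
  if (is.null(rownames(mat)))
    rownames(mat) <- if (is.null(cells)) sprintf("c%02d", seq_len(nrow(mat))) else cells
  if (is.null(colnames(mat)))
    colnames(mat) <- if (is.null(genes)) sprintf("g%02d", seq_len(ncol(mat))) else genes
  expression_matrix(mat)
}

# ExpressionMatrix with a lognorm layer injected directly (bypasses
# normalization when a test wants exact lognorm values).
em_with_lognorm <- function(lognorm) {
  if (is.null(rownames(lognorm)))
    rownames(lognorm) <- sprintf("c%02d", seq_len(nrow(lognorm)))
  if (is.null(colnames(lognorm)))
    colnames(lognorm) <- sprintf("g%02d", seq_len(ncol(lognorm)))
  m <- expression_matrix(matrix(1L, nrow(lognorm), ncol(lognorm),
                                dimnames = dimnames(lognorm)))
  m$lognorm <- methods::as(methods::as(lognorm, "generalMatrix"),
                           "CsparseMatrix")
  m
}

# small, fast cohort for unit tests
small_sim_config <- function(seed = 1, ...) {
  groups <- data.frame(
    name = c("Malignant", "AT2", "Tcell", "Endo"),
    lineage = c("Epithelial", "Epithelial", "T/NK", "Endothelial"),
    nLung = c(0, 120, 30, 30),
    tLung = c(40, 20, 30, 30),
    stringsAsFactors = FALSE)
  # baseline high enough that cells clear the 200-detected-genes QC floor
  sim_config(n_genes = 600, genes_per_chromosome = 100, groups = groups,
             samples_per_origin = 2,
             baseline_lognormal = c(0, 0.8),
             marker_blocks = data.frame(
               group = c("Malignant", "AT2", "Tcell", "Endo"),
               first_gene = c(301, 341, 381, 421), n_genes = 30,
               effect = 2, stringsAsFactors = FALSE),
             cnv_segments = data.frame(group = "Malignant",
                                       chromosome = 1:2, start_gene = 1,
                                       end_gene = 100, fold = 2,
                                       stringsAsFactors = FALSE),
             lr_signals = data.frame(ligand_gene = 501, receptor_gene = 502,
                                     source_group = "Tcell",
                                     target_group = "Endo", effect = 2.5,
                                     stringsAsFactors = FALSE),
             seed = seed, ...)
}

# ---- independent oracle: the full CNV scoring chain ------------------
# Plain-loop re-implementation of Z-clip -> chromosome-wise moving
# average -> per-cell centering -> ms / top-5% correlation.
oracle_cnv_chain <- function(lognorm, genes, window = 100, clip = 3,
                             top_frac = 0.05) {
  n <- nrow(lognorm)
  z <- matrix(NA_real_, n, 0)
  keep_names <- character()
  for (g in colnames(lognorm)) {
    v <- lognorm[, g]
    mu <- mean(v)
    sdp <- sqrt(sum((v - mu)^2) / n)
    if (sdp == 0) next
    zz <- (v - mu) / sdp
    zz[zz > clip] <- clip
    zz[zz < -clip] <- -clip
    z <- cbind(z, zz)
    keep_names <- c(keep_names, g)
  }
  colnames(z) <- keep_names
  ga <- genes[match(keep_names, genes$gene_id), ]
  ord <- order(ga$chromosome, ga$start)
  z <- z[, ord, drop = FALSE]
  chr <- ga$chromosome[ord]
  wins <- NULL
  for (cc in unique(chr)) {
    cols <- which(chr == cc)
    nc <- length(cols)
    if (nc < window) {
      wins <- cbind(wins, rowMeans(z[, cols, drop = FALSE]))
    } else {
      for (s in 1:(nc - window + 1))
        wins <- cbind(wins, rowMeans(z[, cols[s:(s + window - 1)],
                                       drop = FALSE]))
    }
  }
  ctr <- wins
  for (i in 1:n) ctr[i, ] <- wins[i, ] - mean(wins[i, ])
  ms <- numeric(n)
  for (i in 1:n) ms[i] <- mean(ctr[i, ]^2)
  n_top <- ceiling(top_frac * n)
  ref <- colMeans(ctr[order(ms, decreasing = TRUE)[1:n_top], ,
                      drop = FALSE])
  corr <- numeric(n)
  for (i in 1:n) corr[i] <- suppressWarnings(cor(ctr[i, ], ref))
  list(windows = ctr, ms = ms, corr = corr)
}

# ---- independent oracle: per-gene equal-variance t test --------------
oracle_t_table <- function(a, b) {
  out <- data.frame(gene = colnames(a), t = NA_real_, p = NA_real_)
  for (j in seq_len(ncol(a))) {
    tt <- t.test(a[, j], b[, j], var.equal = TRUE)
    out$t[j] <- unname(tt$statistic)
    out$p[j] <- tt$p.value
  }
  out
}
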