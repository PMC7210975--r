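#' Synthetic cohort configuration
#'
#' Describes a seeded negative-binomial droplet cohort with the
#' structure the downstream statistics assume: chromosome-annotated
#' genes, cell groups spread over tissue origins with known preferences,
#' per-group marker blocks, planted copy-number gain/loss segments in a
#' "malignant" group, planted ligand-receptor signals between chosen
#' groups, and a controlled mitochondrial UMI fraction.
#'
#' Defaults emulate a small multi-tissue lung-tumor cohort: 1,200 cells
#' in 6 groups over 3 origins, 5,000 genes on 10 chromosomes, whole
#' chromosome fold-2 gains on the first two chromosomes in the malignant
#' group, 40-gene marker blocks (log2 effect 2) per group, and two
#' planted ligand-receptor signals. The gene count keeps enough
#' effectively independent smoothing windows per cell (about 50) that
#' profile correlations of unperturbed cells with the reference stay
#' well below the malignancy threshold, as on a real transcriptome.
#'
#' @param n_genes total number of genes (including mitochondrial).
#' @param genes_per_chromosome chromosome size; `n_genes` must be a
#'   multiple.
#' @param groups data.frame: `name`, `lineage`, then one column per
#'   tissue origin giving the cell count.
#' @param samples_per_origin donors simulated per tissue origin.
#' @param baseline_lognormal `c(meanlog, sdlog)` of per-gene base mean
#'   UMI counts.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion mu^2).
#' @param library_size_lognormal `c(meanlog, sdlog)` of per-cell library
#'   size factors.
#' @param marker_blocks data.frame: `group`, `first_gene` (global
#'   index), `n_genes`, `effect` (log2 mean shift).
#' @param cnv_segments data.frame: `group`, `chromosome` (index),
#'   `start_gene`, `end_gene` (within-chromosome indices), `fold`
#'   (linear factor on the mean).
#' @param lr_signals data.frame: `ligand_gene`, `receptor_gene` (global
#'   indices), `source_group`, `target_group`, `effect` (log2).
#' @param n_mito_genes number of genes renamed `MT-SIM..` at the genome
#'   tail.
#' @param mito_fraction expected mitochondrial share of a cell's UMIs.
#' @param seed mandatory integer seed.
#' @export
sim_config <- function(n_genes = 5000, genes_per_chromosome = 500,
                       groups = default_sim_groups(),
                       samples_per_origin = 3,
                       baseline_lognormal = c(log(0.2), 1),
                       nb_dispersion = 0.5,
                       library_size_lognormal = c(0, 0.3),
                       marker_blocks = default_marker_blocks(),
                       cnv_segments = default_cnv_segments(),
                       lr_signals = default_lr_signals(),
                       n_mito_genes = 10, mito_fraction = 0.02,
                       seed = 1L) {
  stopifnot(n_genes %% genes_per_chromosome == 0,
            nb_dispersion > 0, mito_fraction >= 0, mito_fraction < 1,
            samples_per_origin >= 1, is.numeric(seed))
  origin_cols <- setdiff(names(groups), c("name", "lineage"))
  bad <- setdiff(origin_cols, tissue_origins())
  if (length(bad)) stop("unknown tissue origins: ", paste(bad, collapse = ", "))
  if (nrow(marker_blocks) &&
      any(marker_blocks$first_gene + marker_blocks$n_genes - 1 > n_genes))
    stop("marker block exceeds n_genes")
  if (nrow(cnv_segments)) {
    if (any(cnv_segments$end_gene > genes_per_chromosome) ||
        any(cnv_segments$start_gene < 1))
      stop("CNV segment outside chromosome")
    if (any(cnv_segments$fold <= 0)) stop("fold factors must be > 0")
  }
  structure(list(
    n_genes = n_genes, genes_per_chromosome = genes_per_chromosome,
    n_chromosomes = n_genes / genes_per_chromosome,
    groups = groups, origin_cols = origin_cols,
    samples_per_origin = samples_per_origin,
    baseline_lognormal = baseline_lognormal,
    nb_dispersion = nb_dispersion,
    library_size_lognormal = library_size_lognormal,
    marker_blocks = marker_blocks, cnv_segments = cnv_segments,
    lr_signals = lr_signals, n_mito_genes = n_mito_genes,
    mito_fraction = mito_fraction, seed = as.integer(seed)),
    class = "sim_config")
}

#' @rdname sim_config
#' @export
default_sim_groups <- function() {
  data.frame(
    name = c("Malignant", "AT2", "Tcell", "moMac", "Fibroblast",
             "Endothelial"),
    lineage = c("Epithelial", "Epithelial", "T/NK", "Myeloid",
                "Fibroblast", "Endothelial"),
    nLung = c(0, 600, 50, 40, 40, 50),
    tLung = c(80, 50, 50, 60, 30, 50),
    mBrain = c(20, 0, 20, 30, 10, 20),
    stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_marker_blocks <- function() {
  data.frame(
    group = c("Malignant", "AT2", "Tcell", "moMac", "Fibroblast",
              "Endothelial"),
    first_gene = c(2001, 2041, 2081, 2121, 2161, 2201),
    n_genes = 40, effect = 2, stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_cnv_segments <- function() {
  data.frame(group = "Malignant", chromosome = c(1, 2),
             start_gene = 1, end_gene = 500, fold = 2,
             stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_lr_signals <- function() {
  data.frame(ligand_gene = c(3001, 3003), receptor_gene = c(3002, 3004),
             source_group = c("moMac", "Malignant"),
             target_group = c("Endothelial", "Endothelial"),
             effect = c(2, 2.5), stringsAsFactors = FALSE)
}

#' Null cohort configuration
#'
#' Identical-mean groups with no planted markers, copy-number segments
#' or ligand-receptor signals: the generator behind every type-I-error /
#' calibration check downstream.
#'
#' @param seed integer seed.
#' @param n_cells_per_group,n_groups cohort shape.
#' @param n_genes,genes_per_chromosome genome shape.
#' @param origins tissue origins to populate (equal counts).
#' @return a [sim_config()].
#' @export
null_sim_config <- function(seed, n_cells_per_group = 50, n_groups = 2,
                            n_genes = 1000, genes_per_chromosome = 100,
                            origins = "nLung") {
  groups <- data.frame(name = paste0("grp", seq_len(n_groups)),
                       lineage = paste0("lin", seq_len(n_groups)),
                       stringsAsFactors = FALSE)
  for (o in origins) groups[[o]] <- n_cells_per_group
  sim_config(n_genes = n_genes,
             genes_per_chromosome = genes_per_chromosome,
             groups = groups, samples_per_origin = 1,
             baseline_lognormal = c(log(1), 0.5),
             marker_blocks = default_marker_blocks()[0, ],
             cnv_segments = default_cnv_segments()[0, ],
             lr_signals = default_lr_signals()[0, ],
             n_mito_genes = 0, mito_fraction = 0, seed = seed)
}

# gene names: G0001.. with the tail n_mito renamed MT-SIM01..
sim_gene_names <- function(cfg) {
  nm <- sprintf("G%04d", seq_len(cfg$n_genes))
  if (cfg$n_mito_genes > 0) {
    idx <- (cfg$n_genes - cfg$n_mito_genes + 1):cfg$n_genes
    nm[idx] <- sprintf("MT-SIM%02d", seq_len(cfg$n_mito_genes))
  }
  nm
}

#' Synthetic gene annotation table
#'
#' Evenly spaced 1-based positions on `chr01..chrNN` (zero-padded so
#' lexicographic chromosome order matches genomic order).
#'
#' @param cfg a [sim_config()].
#' @export
sim_gene_annotation <- function(cfg) {
  chr <- rep(sprintf("chr%02d", seq_len(cfg$n_chromosomes)),
             each = cfg$genes_per_chromosome)
  pos <- rep(seq_len(cfg$genes_per_chromosome) * 10000L,
             times = cfg$n_chromosomes)
  gene_annotation(data.frame(gene_id = sim_gene_names(cfg),
                             chromosome = chr, start = pos,
                             stringsAsFactors = FALSE))
}

#' Apply planted copy-number segments to group mean profiles
#'
#' Multiplies the mean of every gene inside each segment by the
#' segment's fold factor, for the segment's target group only.
#' Overlapping segments within one group are an error.
#'
#' @param means groups x genes matrix of expected counts (rownames are
#'   group names).
#' @param cfg a [sim_config()] supplying `cnv_segments` and the genome
#'   layout.
#' @export
embed_cnv <- function(means, cfg) {
  seg <- cfg$cnv_segments
  if (!nrow(seg)) return(means)
  for (g in unique(seg$group)) {
    s <- seg[seg$group == g, , drop = FALSE]
    touched <- integer()
    for (i in seq_len(nrow(s))) {
      off <- (s$chromosome[i] - 1) * cfg$genes_per_chromosome
      idx <- off + s$start_gene[i]:s$end_gene[i]
      if (length(intersect(touched, idx)))
        stop("overlapping CNV segments for group ", g)
      touched <- c(touched, idx)
      means[g, idx] <- means[g, idx] * s$fold[i]
    }
  }
  means
}

#' Deterministic planted cell composition
#'
#' Builds the per-cell annotation implied by the configuration: exact
#' (group, origin) counts, lineages, and a seeded assignment of cells to
#' `samples_per_origin` donors within each origin.
#'
#' @param cfg a [sim_config()].
#' @return cell annotation data.frame with an extra `malignant` column
#'   (TRUE for groups targeted by a fold != 1 CNV segment).
#' @export
plant_composition <- function(cfg) {
  rng <- local_rng(cfg$seed + 1L)
  on.exit(rng())
  rows <- list()
  for (i in seq_len(nrow(cfg$groups))) {
    for (o in cfg$origin_cols) {
      n <- cfg$groups[[o]][i]
      if (n > 0)
        rows[[length(rows) + 1]] <- data.frame(
          group = cfg$groups$name[i], lineage = cfg$groups$lineage[i],
          tissue_origin = o, stringsAsFactors = FALSE)[rep(1, n), ]
    }
  }
  ann <- do.call(rbind, rows)
  ann$cell_id <- sprintf("cell%05d", seq_len(nrow(ann)))
  ann$sample_id <- NA_character_
  for (o in unique(ann$tissue_origin)) {
    i <- which(ann$tissue_origin == o)
    ann$sample_id[i] <- sprintf("%s_s%d", gsub("/", "", o),
                                sample.int(cfg$samples_per_origin,
                                           length(i), replace = TRUE))
  }
  malignant_groups <- unique(cfg$cnv_segments$group[cfg$cnv_segments$fold != 1])
  ann$malignant <- ann$group %in% malignant_groups
  ann$subset <- ann$group
  rownames(ann) <- NULL
  ann[, c("cell_id", "sample_id", "tissue_origin", "lineage", "subset",
          "group", "malignant")]
}

#' Simulate a seeded synthetic cohort
#'
#' Draws UMI counts from a negative binomial with per-cell library-size
#' factors and per-group gene mean profiles carrying the configured
#' marker blocks, ligand-receptor signals and copy-number segments.
#'
#' @param cfg a [sim_config()].
#' @return list: `matrix` (an [expression_matrix()]), `annotation`
#'   (validated cell annotation), `genes` (annotation table), `truth`
#'   (ground-truth list), `config`.
#' @export
simulate_counts <- function(cfg = sim_config()) {
  ann <- plant_composition(cfg)
  rng <- local_rng(cfg$seed)
  on.exit(rng())
  ng <- cfg$n_genes
  base <- stats::rlnorm(ng, cfg$baseline_lognormal[1],
                        cfg$baseline_lognormal[2])
  # fix the expected mitochondrial share of the library
  if (cfg$n_mito_genes > 0 && cfg$mito_fraction > 0) {
    mi <- (ng - cfg$n_mito_genes + 1):ng
    base[mi] <- cfg$mito_fraction / (1 - cfg$mito_fraction) *
      sum(base[-mi]) / cfg$n_mito_genes
  }
  means <- matrix(rep(base, each = nrow(cfg$groups)),
                  nrow = nrow(cfg$groups),
                  dimnames = list(cfg$groups$name, sim_gene_names(cfg)))
  mb <- cfg$marker_blocks
  for (i in seq_len(nrow(mb))) {
    idx <- mb$first_gene[i]:(mb$first_gene[i] + mb$n_genes[i] - 1)
    means[mb$group[i], idx] <- means[mb$group[i], idx] * 2^mb$effect[i]
  }
  lr <- cfg$lr_signals
  for (i in seq_len(nrow(lr))) {
    means[lr$source_group[i], lr$ligand_gene[i]] <-
      means[lr$source_group[i], lr$ligand_gene[i]] * 2^lr$effect[i]
    means[lr$target_group[i], lr$receptor_gene[i]] <-
      means[lr$target_group[i], lr$receptor_gene[i]] * 2^lr$effect[i]
  }
  means <- embed_cnv(means, cfg)

  n_cells <- nrow(ann)
  lib <- stats::rlnorm(n_cells, cfg$library_size_lognormal[1],
                       cfg$library_size_lognormal[2])
  size <- 1 / cfg$nb_dispersion
  counts <- matrix(0L, n_cells, ng,
                   dimnames = list(ann$cell_id, sim_gene_names(cfg)))
  for (g in cfg$groups$name) {
    i <- which(ann$group == g)
    if (!length(i)) next
    mu <- outer(lib[i], means[g, ])
    counts[i, ] <- stats::rnbinom(length(mu), mu = mu, size = size)
  }
  truth <- list(
    cells = ann,
    genes = sim_gene_annotation(cfg),
    group_means = means,
    marker_blocks = cfg$marker_blocks,
    cnv_segments = cfg$cnv_segments,
    lr_signals = cfg$lr_signals,
    composition = unclass(table(ann$group, ann$tissue_origin)))
  meta <- ann[, c("cell_id", "sample_id", "tissue_origin", "lineage",
                  "subset")]
  list(matrix = expression_matrix(counts),
       annotation = cell_annotation(meta),
       genes = truth$genes, truth = truth, config = cfg)
}

#' Write a simulated cohort to disk as plain-text fixtures
#'
#' Emits the MTX triplet, cell metadata TSV, gene annotation TSV, the
#' planted ligand-receptor pair table, and a ground-truth JSON. The
#' files round-trip exactly through [load_counts()].
#'
#' @param sim output of [simulate_counts()].
#' @param dir destination directory.
#' @return named vector of written paths.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mtx_triplet(sim$matrix, dir)
  meta <- file.path(dir, "metadata.tsv")
  utils::write.table(sim$annotation, meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  genes <- file.path(dir, "genes.tsv")
  utils::write.table(sim$genes, genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pairs <- file.path(dir, "lr_pairs.tsv")
  lr <- sim$config$lr_signals
  gn <- sim_gene_names(sim$config)
  utils::write.table(
    data.frame(pair_id = sprintf("planted%02d", seq_len(nrow(lr))),
               ligand = gn[lr$ligand_gene], receptor = gn[lr$receptor_gene]),
    pairs, sep = "\t", quote = FALSE, row.names = FALSE)
  tj <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(
    cells = sim$truth$cells,
    cnv_segments = sim$truth$cnv_segments,
    marker_blocks = sim$truth$marker_blocks,
    lr_signals = sim$truth$lr_signals,
    composition = as.data.frame.table(sim$truth$composition,
                                      stringsAsFactors = FALSE),
    seed = sim$config$seed), tj, auto_unbox = TRUE, digits = NA)
  c(dir = dir, metadata = meta, genes = genes, pairs = pairs, truth = tj)
}
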