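#' Run the atlas statistics pipeline end to end
#'
#' Stages run in dependency order: load + QC + normalization always;
#' then, as enabled, CNV malignancy calling, per-subset marker
#' selection, composition statistics, the receptor-ligand permutation
#' network, and the GO-Jaccard gene network. Stages communicate through
#' files in the documented plain-text formats so any stage can be re-run
#' standalone; a manifest records every artifact with its checksum, the
#' parameters actually applied, the seed, and the package version.
#'
#' @param config a list, or path to a JSON file, with elements:
#'   * `input`: `counts` (MTX triplet dir or dense TSV), `metadata`,
#'     `genes`, optional `lr_pairs`, optional `go_mapping`;
#'   * `output_dir`; `seed`;
#'   * `stages`: named logicals `cnv`, `markers`, `composition`,
#'     `interactions`, `gonet` (all default TRUE when inputs allow);
#'   * optional parameter blocks `qc`, `cnv`, `markers`, `interactions`
#'     overriding the respective defaults.
#' @return the manifest (also written to `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  out <- config$output_dir
  if (is.null(out)) stop("config$output_dir is required")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- config$stages
  enabled <- function(s, default = TRUE)
    if (is.null(stages[[s]])) default else isTRUE(stages[[s]])
  manifest <- list(package_version = as.character(utils::packageVersion("scatlas")),
                   seed = seed, stages = list(), artifacts = list())
  emit <- function(stage, name, path, params = NULL) {
    manifest$artifacts[[name]] <<- list(
      stage = stage, path = path,
      md5 = unname(tools::md5sum(path)))
    if (!is.null(params)) manifest$stages[[stage]] <<- params
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- qc / normalize ------------------------------------------------
  qc_par <- utils::modifyList(unclass(qc_thresholds()),
                              as.list(config$qc))
  thr <- do.call(qc_thresholds, qc_par)
  dat <- run_stage("load", load_counts(config$input$counts,
                                       config$input$metadata))
  genes <- run_stage("load", gene_annotation(
    utils::read.delim(config$input$genes, stringsAsFactors = FALSE)))
  m <- run_stage("qc", {
    m <- qc_filter_cells(dat$matrix, thresholds = thr)
    filter_genes(m, thr$min_gene_cell_fraction)
  })
  ann <- dat$annotation[dat$annotation$cell_id %in% cell_ids(m), ,
                        drop = FALSE]
  m <- run_stage("normalize", center_relative(normalize_log2_tpm(m)))
  qc_path <- file.path(out, "qc_cells.tsv")
  utils::write.table(
    data.frame(cell_id = cell_ids(m)), qc_path, sep = "\t",
    quote = FALSE, row.names = FALSE)
  emit("qc", "qc_cells", qc_path, qc_par)

  # -- cnv -----------------------------------------------------------
  tumor_origins <- c("tLung", "tL/B", "mLN", "mBrain", "PE")
  if (enabled("cnv")) {
    cnv_par <- do.call(cnv_params, as.list(config$cnv))
    tumor_cells <- ann$cell_id[ann$lineage == "Epithelial" &
                                 ann$tissue_origin %in% tumor_origins]
    pool <- ann$cell_id[ann$lineage == "Epithelial" &
                          ann$tissue_origin == "nLung"]
    if (length(tumor_cells)) {
      scores <- run_stage("cnv",
                          infer_cnv(m, genes, tumor_cells, pool,
                                    cnv_par, seed = seed))
      scores$sample_id <- ann$sample_id[match(scores$cell_id, ann$cell_id)]
      p <- file.path(out, "cnv_scores.tsv")
      utils::write.table(scores[, c("cell_id", "sample_id", "ms", "corr",
                                    "malignant", "is_spike_in",
                                    "n_windows")],
                         p, sep = "\t", quote = FALSE, row.names = FALSE)
      emit("cnv", "cnv_scores", p, unclass(cnv_par))
    } else manifest$stages$cnv <- "skipped: no tumor epithelial cells"
  } else manifest$stages$cnv <- "disabled"

  # -- markers (one subset vs rest) ---------------------------------
  if (enabled("markers")) {
    mk_par <- utils::modifyList(unclass(marker_thresholds()),
                                as.list(config$markers))
    mk_par$direction <- match.arg(mk_par$direction, c("up", "both"))
    thr_m <- do.call(marker_thresholds, mk_par)
    all_mk <- run_stage("markers", {
      res <- lapply(unique(ann$subset), function(s) {
        ga <- ann$cell_id[ann$subset == s]
        gb <- setdiff(ann$cell_id, ga)
        if (length(ga) < 3 || length(gb) < 3) return(NULL)
        r <- differential_markers(m, ga, gb, thr_m)
        if (nrow(r)) r$subset <- s
        r
      })
      do.call(rbind, res[!vapply(res, is.null, TRUE)])
    })
    p <- file.path(out, "markers.tsv")
    utils::write.table(all_mk, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("markers", "markers", p, mk_par)
  } else manifest$stages$markers <- "disabled"

  # -- composition ---------------------------------------------------
  if (enabled("composition")) {
    comp <- run_stage("composition", contingency(ann))
    p <- file.path(out, "composition.tsv")
    composition_table(comp, p)
    emit("composition", "composition", p,
         list(subset_field = "subset", origin_field = "tissue_origin"))
  } else manifest$stages$composition <- "disabled"

  # -- interactions --------------------------------------------------
  if (enabled("interactions", default = !is.null(config$input$lr_pairs))) {
    if (is.null(config$input$lr_pairs))
      stop("stage 'interactions' enabled but no input$lr_pairs given")
    int_par <- utils::modifyList(
      list(n_perm = 1000, min_pct = 0.25, min_subset_fraction = 0.001,
           alpha = 0.05), as.list(config$interactions))
    res <- run_stage("interactions", {
      pairs <- load_lr_pairs(config$input$lr_pairs, gene_ids(m))
      labels <- stats::setNames(ann$subset, ann$cell_id)
      raw <- permutation_test(m, labels, pairs,
                              n_perm = int_par$n_perm, seed = seed,
                              min_pct = int_par$min_pct)
      sig <- filter_interactions(raw, ann,
                                 min_subset_fraction = int_par$min_subset_fraction,
                                 alpha = int_par$alpha)
      list(raw = raw, sig = sig, counts = count_significant(sig))
    })
    p1 <- file.path(out, "interactions.tsv")
    utils::write.table(res$raw, p1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p2 <- file.path(out, "interactions_significant.tsv")
    utils::write.table(res$sig, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p3 <- file.path(out, "interaction_counts.tsv")
    utils::write.table(res$counts, p3, sep = "\t", quote = FALSE,
                       col.names = NA)
    emit("interactions", "interactions", p1, int_par)
    emit("interactions", "interactions_significant", p2)
    emit("interactions", "interaction_counts", p3)
  } else manifest$stages$interactions <- "disabled"

  # -- gene network --------------------------------------------------
  if (enabled("gonet", default = FALSE)) {
    if (is.null(config$input$go_mapping))
      stop("stage 'gonet' enabled but no input$go_mapping given")
    net <- run_stage("gonet", {
      go <- read_go_mapping(config$input$go_mapping)
      mk <- utils::read.delim(file.path(out, "markers.tsv"),
                              stringsAsFactors = FALSE)
      passed <- mk[mk$passed, , drop = FALSE]
      build_gene_network(
        data.frame(gene_id = unique(passed$gene_id),
                   direction = "up", stringsAsFactors = FALSE), go)
    })
    p <- file.path(out, "gene_network_edges.tsv")
    write_gene_network(net, p)
    emit("gonet", "gene_network_edges", p, list(threshold = net$threshold))
  } else manifest$stages$gonet <- "disabled"

  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Thin argument parser over [run_pipeline()] and [simulate_counts()].
#' Subcommands: `run --config run.json`, and
#' `simulate --out dir --seed N`. Installed as `inst/scripts/atlas`.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return exit status (0 ok, 2 validation error, 3 stage failure).
#' @export
atlas_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  opts <- function(a) {
    keys <- grep("^--", a)
    stats::setNames(as.list(a[keys + 1]), sub("^--", "", a[keys]))
  }
  if (!length(args)) { message("usage: atlas <run|simulate> [--opts]"); return(2L) }
  cmd <- args[1]; o <- opts(args[-1])
  status <- tryCatch({
    if (cmd == "run") {
      if (is.null(o$config)) stop("run requires --config", call. = FALSE)
      run_pipeline(o$config)
      0L
    } else if (cmd == "simulate") {
      if (is.null(o$out)) stop("simulate requires --out", call. = FALSE)
      seed <- if (is.null(o$seed)) 1L else as.integer(o$seed)
      cfg <- if (is.null(o$config)) sim_config(seed = seed) else {
        cl <- jsonlite::read_json(o$config, simplifyVector = TRUE)
        cl$seed <- seed
        do.call(sim_config, cl)
      }
      write_fixture(simulate_counts(cfg), o$out)
      0L
    } else { message("unknown subcommand: ", cmd); 2L }
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("stage '", conditionMessage(e))) 3L else 2L
  })
  status
}
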