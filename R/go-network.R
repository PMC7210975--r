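#' Read a gene -> GO Biological Process mapping
#'
#' Accepts either a plain TSV with columns `gene_id`, `go_id` and
#' optionally `namespace` (rows outside the requested namespace are
#' dropped), or a GAF 2.x file (lines starting with `!` are headers;
#' column 3 is the symbol, column 5 the GO id, column 9 the aspect,
#' `P` = Biological Process).
#'
#' @param path TSV or GAF file.
#' @param namespace namespace to keep: `"BP"` (TSV) / `"P"` (GAF).
#' @return named list: gene id -> character vector of GO term ids.
#' @export
read_go_mapping <- function(path, namespace = "BP") {
  first <- readLines(path, n = 1)
  if (startsWith(first, "!")) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    df <- data.frame(
      gene_id = vapply(parts, `[`, "", 3),
      go_id = vapply(parts, `[`, "", 5),
      namespace = vapply(parts, `[`, "", 9),
      stringsAsFactors = FALSE)
    df <- df[df$namespace == "P", , drop = FALSE]
  } else {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("gene_id", "go_id") %in% names(df)))
      stop("expected columns gene_id, go_id in ", path)
    if ("namespace" %in% names(df))
      df <- df[df$namespace == namespace, , drop = FALSE]
  }
  lapply(split(df$go_id, df$gene_id), unique)
}

#' Jaccard similarity of two term sets
#'
#' Intersection over union; both sets must be non-empty.
#'
#' @param a,b character vectors of term ids.
#' @export
jaccard <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty term set")
  length(intersect(a, b)) / length(union(a, b))
}

#' Gene-gene functional association network from GO term overlap
#'
#' Every unordered pair of marker genes is scored by the Jaccard index
#' of their GO Biological Process term sets; edges with similarity
#' strictly above `threshold` are kept and isolated genes dropped from
#' the node list. Genes without any GO term are excluded before pairing
#' and reported.
#'
#' @param genes data.frame with `gene_id` and optionally `direction`
#'   (e.g. up/down regulation tag carried onto the nodes), or a
#'   character vector of gene ids.
#' @param go mapping from [read_go_mapping()].
#' @param threshold minimum Jaccard similarity (default 0.05, strict).
#' @return object of class `gene_network`: `nodes` (gene_id, direction,
#'   n_terms), `edges` (gene1, gene2, jaccard), `unannotated`.
#' @export
build_gene_network <- function(genes, go, threshold = 0.05) {
  if (is.character(genes)) genes <- data.frame(gene_id = genes)
  if (is.null(genes$direction)) genes$direction <- NA_character_
  ann <- genes$gene_id %in% names(go) &
    vapply(go[genes$gene_id], function(x) length(x) > 0, TRUE)
  ann[is.na(ann)] <- FALSE
  unannotated <- genes$gene_id[!ann]
  g <- genes[ann, , drop = FALSE]
  if (!nrow(g)) stop("no marker gene has GO terms")
  ids <- g$gene_id
  edges <- NULL
  if (length(ids) >= 2) {
    combs <- utils::combn(length(ids), 2)
    jc <- apply(combs, 2, function(ij)
      jaccard(go[[ids[ij[1]]]], go[[ids[ij[2]]]]))
    keep <- jc > threshold
    edges <- data.frame(gene1 = ids[combs[1, keep]],
                        gene2 = ids[combs[2, keep]],
                        jaccard = jc[keep], stringsAsFactors = FALSE)
  }
  if (is.null(edges))
    edges <- data.frame(gene1 = character(), gene2 = character(),
                        jaccard = numeric())
  connected <- unique(c(edges$gene1, edges$gene2))
  nodes <- g[g$gene_id %in% connected, , drop = FALSE]
  nodes$n_terms <- vapply(go[nodes$gene_id], length, 1L)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 unannotated = unannotated), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges (jaccard > %g)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Export a gene network
#'
#' Writes the weighted edge list as TSV and, optionally, GraphML.
#'
#' @param net a `gene_network`.
#' @param edge_path TSV destination for the edge list.
#' @param graphml_path optional GraphML destination.
#' @export
write_gene_network <- function(net, edge_path, graphml_path = NULL) {
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(edge_path)
}

#' Read a gene network edge list back
#'
#' @param edge_path TSV written by [write_gene_network()].
#' @export
read_gene_network_edges <- function(edge_path) {
  utils::read.delim(edge_path, sep = "\t", stringsAsFactors = FALSE)
}
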