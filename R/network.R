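#' Build the pathway cross-talk network
#'
#' Nodes are pathways with at least `min_genes` detected genes; an
#' undirected edge joins two surviving pathways whenever the link table
#' relates them (a product of one pathway consumed as substrate by the
#' other). Reciprocal links collapse to one edge; self-links are dropped;
#' links naming unknown pathways are skipped with a warning.
#'
#' @param link_table data frame (or 2-column matrix) of pathway-id pairs.
#' @param gene_membership named list: pathway id -> detected gene symbols.
#' @param min_genes minimum detected-gene count per node, default 5.
#' @return an undirected `igraph` graph with node attribute
#'   `detected_gene_count`.
#' @export
build_network <- function(link_table, gene_membership, min_genes = 5L) {
  counts <- lengths(gene_membership)
  keep <- names(counts)[counts >= min_genes]
  lt <- as.data.frame(link_table, stringsAsFactors = FALSE)
  if (nrow(lt) && ncol(lt) < 2)
    stop("build_network: link table needs two pathway-id columns")
  if (nrow(lt)) {
    a <- as.character(lt[[1]]); b <- as.character(lt[[2]])
    unknown <- setdiff(c(a, b), names(counts))
    if (length(unknown)) {
      warning("build_network: skipping link(s) with unknown pathway(s): ",
              paste(unknown, collapse = ", "))
      ok <- a %in% names(counts) & b %in% names(counts)
      a <- a[ok]; b <- b[ok]
    }
    ok <- a %in% keep & b %in% keep & a != b
    a <- a[ok]; b <- b[ok]
    e <- unique(data.frame(from = pmin(a, b), to = pmax(a, b),
                           stringsAsFactors = FALSE))
  } else {
    e <- data.frame(from = character(), to = character())
  }
  igraph::graph_from_data_frame(
    e, directed = FALSE,
    vertices = data.frame(name = keep,
                          detected_gene_count = as.integer(counts[keep]),
                          stringsAsFactors = FALSE))
}

#' Annotate network nodes with enrichment statistics
#'
#' Sets per-node attributes from a GSEA result table: `NES`, `nominal_p`,
#' `size_attr` = log10(1/nominal p) (drives node size in a rendering), and
#' optionally a functional `category`.
#'
#' @param network graph from [build_network()].
#' @param gsea_results data frame with columns set_id, nes, nominal_p
#'   covering every node.
#' @param categories optional data frame (pathway_id, category).
#' @return the annotated graph.
#' @export
annotate_nodes <- function(network, gsea_results, categories = NULL) {
  ids <- igraph::V(network)$name
  m <- match(ids, gsea_results$set_id)
  if (anyNA(m))
    stop("annotate_nodes: no GSEA result for pathway(s): ",
         paste(ids[is.na(m)], collapse = ", "))
  p <- gsea_results$nominal_p[m]
  igraph::V(network)$NES <- gsea_results$nes[m]
  igraph::V(network)$nominal_p <- p
  igraph::V(network)$size_attr <- log10(1 / p)
  if (!is.null(categories)) {
    cm <- match(ids, categories$pathway_id)
    igraph::V(network)$category <-
      ifelse(is.na(cm), "unassigned", categories$category[cm])
  }
  network
}

#' Write a pathway network as GraphML plus a flat edge list
#'
#' @param network annotated graph.
#' @param graphml_path GraphML output file.
#' @param edgelist_path optional edge-list TSV output file.
#' @return invisibly, the GraphML path.
#' @export
write_pathway_network <- function(network, graphml_path,
                                  edgelist_path = NULL) {
  igraph::write_graph(network, graphml_path, format = "graphml")
  if (!is.null(edgelist_path)) {
    el <- igraph::as_edgelist(network)
    utils::write.table(
      data.frame(pathway_a = el[, 1], pathway_b = el[, 2]),
      edgelist_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(graphml_path)
}

#' Read a pathway link table (two-column TSV of pathway-id pairs)
#' @param path TSV file with columns naming the two linked pathways.
#' @export
read_link_table <- function(path) {
  lt <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(lt) < 2)
    stop("read_link_table: need two pathway-id columns")
  lt[, 1:2]
}
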