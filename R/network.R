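#' Cluster-level co-cluster network
#'
#' Builds the bipartite network between gene clusters and DC clusters: one
#' edge per co-cluster block, weighted by the block's mean transformed fold
#' change (aLFCGE) and classed `"up"`, `"down"` or `"insignificant"` from
#' the control-chart call. The network is complete bipartite over GCs x
#' DCCs.
#'
#' @param fit an `hcoclust` fit (its grid must carry significance calls).
#' @return an [igraph::igraph] with vertex attributes `name`, `type`
#'   (`"gene-cluster"`/`"dc-cluster"`), edge attributes `weight`, `class`,
#'   and graph attribute `level = "cluster"`.
#' @export
cocluster_graph <- function(fit) {
  stopifnot(inherits(fit, "hcoclust"))
  g <- fit$grid
  if (any(is.na(g$significance))) stop("grid lacks significance calls")
  edges <- data.frame(from = paste0("GC", g$gc),
                      to = paste0("DCC", g$dcc),
                      weight = g$aLFCGE,
                      class = g$significance)
  verts <- data.frame(
    name = c(paste0("GC", sort(unique(g$gc))),
             paste0("DCC", sort(unique(g$dcc)))),
    type = rep(c("gene-cluster", "dc-cluster"),
               c(length(unique(g$gc)), length(unique(g$dcc)))))
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                      vertices = verts)
  igraph::graph_attr(gr, "level") <- "cluster"
  gr
}

#' Member-level gene-DC network through co-clusters
#'
#' Expands co-cluster blocks into complete bipartite edges between their
#' member genes and DCs, each edge inheriting the block's weight (aLFCGE)
#' and significance class. With `significant_only = TRUE` (default) only
#' biomarker co-clusters (up- or down-regulatory) are expanded, giving the
#' network of differentially expressed genes and their chemical regulators;
#' with `FALSE` the edges partition all N x C gene-DC pairs.
#'
#' @param fit an `hcoclust` fit.
#' @param significant_only include only significant blocks?
#' @return an [igraph::igraph]; vertex attribute `type`
#'   (`"gene"`/`"dc"`), edge attributes `weight`, `class`, graph attribute
#'   `level = "member"`.
#' @export
member_graph <- function(fit, significant_only = TRUE) {
  stopifnot(inherits(fit, "hcoclust"))
  g <- fit$grid
  if (any(is.na(g$significance))) stop("grid lacks significance calls")
  keep <- if (significant_only) g$significance != "insignificant"
          else rep(TRUE, nrow(g))
  edge_list <- lapply(which(keep), function(i) {
    genes <- names(fit$gene_clusters)[fit$gene_clusters == g$gc[i]]
    dcs <- names(fit$dc_clusters)[fit$dc_clusters == g$dcc[i]]
    if (!length(genes) || !length(dcs)) return(NULL)
    data.frame(from = rep(genes, each = length(dcs)),
               to = rep(dcs, length(genes)),
               weight = g$aLFCGE[i],
               class = g$significance[i])
  })
  edges <- do.call(rbind, edge_list)
  verts <- data.frame(
    name = c(names(fit$gene_clusters), names(fit$dc_clusters)),
    type = rep(c("gene", "dc"),
               c(length(fit$gene_clusters), length(fit$dc_clusters))))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), class = character())
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                      vertices = verts)
  igraph::graph_attr(gr, "level") <- "member"
  gr
}

#' Export a co-cluster network to disk
#'
#' Writes either a tab-separated edge list (columns `source`, `target`,
#' `weight`, `class`, `level`) or GraphML with the same attributes.
#' [read_network()] reads both back; the edge multiset round-trips
#' losslessly.
#'
#' @param graph an igraph from [cocluster_graph()] or [member_graph()].
#' @param path output file path.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(graph, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    ne <- igraph::ecount(graph)
    df <- data.frame(source = as.character(el[, 1L]),
                     target = as.character(el[, 2L]),
                     weight = signif(igraph::E(graph)$weight %||% numeric(0), 6),
                     class = igraph::E(graph)$class %||% character(0),
                     level = rep(igraph::graph_attr(graph, "level") %||%
                                   NA_character_, ne))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
read_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") return(igraph::read_graph(path, format = "graphml"))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gr <- igraph::graph_from_data_frame(df[, c("source", "target", "weight",
                                             "class")], directed = FALSE)
  if (nrow(df)) igraph::graph_attr(gr, "level") <- df$level[1L]
  gr
}
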