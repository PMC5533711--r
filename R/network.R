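# Cell-specific network construction: restrict a scored association network
# (STRING-style, combined score >= 700) to the genes called expressed in the
# cell type, and summarise the topology of the result.

#' Restrict a network to expressed genes
#'
#' Keeps exactly the edges whose both endpoints belong to `expressed`.
#' Isolated nodes do not exist in edgelist representation, so restriction
#' also removes any node left without edges.
#'
#' @param network an [edge_list()].
#' @param expressed a [gene_set()] or character vector of gene ids.
#' @return an [edge_list()] (possibly empty).
#' @export
restrict_to_genes <- function(network, expressed) {
  .assert(inherits(network, "edge_list"), "network must be an edge_list")
  ids <- as_gene_ids(expressed)
  keep <- network$gene_a %in% ids & network$gene_b %in% ids
  edge_list(network$gene_a[keep], network$gene_b[keep], network$score[keep])
}

#' Summarise network topology
#'
#' Computes the metrics used to compare a full association network with its
#' cell-restricted counterpart: node and edge counts, number of connected
#' components, average local clustering coefficient (nodes of degree < 2
#' contribute 0), and degree assortativity (Pearson correlation of endpoint
#' degrees over both orientations of every edge).
#'
#' On an empty network the counts are 0 and the two coefficient metrics are
#' `NA` (undefined); assortativity is also `NA` when all degrees are equal
#' (zero variance).
#'
#' @param network an [edge_list()].
#' @return list of class `topology_summary` with elements `n_nodes`,
#'   `n_edges`, `n_components`, `avg_clustering`, `degree_assortativity`.
#' @export
topology_summary <- function(network) {
  .assert(inherits(network, "edge_list"), "network must be an edge_list")
  if (nrow(network) == 0L) {
    out <- list(n_nodes = 0L, n_edges = 0L, n_components = 0L,
                avg_clustering = NA_real_, degree_assortativity = NA_real_)
    class(out) <- "topology_summary"
    return(out)
  }
  g <- igraph::graph_from_data_frame(network[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  lc <- igraph::transitivity(g, type = "local", isolates = "zero")
  lc[is.na(lc)] <- 0  # degree-1 nodes
  deg <- igraph::degree(g)
  ea <- match(network$gene_a, igraph::V(g)$name)
  eb <- match(network$gene_b, igraph::V(g)$name)
  dx <- c(deg[ea], deg[eb])   # both orientations of each undirected edge
  dy <- c(deg[eb], deg[ea])
  assort <- if (stats::sd(dx) == 0) NA_real_ else stats::cor(dx, dy)
  out <- list(n_nodes = as.integer(igraph::vcount(g)),
              n_edges = as.integer(igraph::ecount(g)),
              n_components = as.integer(igraph::components(g)$no),
              avg_clustering = mean(lc),
              degree_assortativity = assort)
  class(out) <- "topology_summary"
  out
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(paste0("network topology: %d nodes, %d edges, %d components\n",
                     "  avg clustering %.4f, degree assortativity %s\n"),
              x$n_nodes, x$n_edges, x$n_components, x$avg_clustering,
              ifelse(is.na(x$degree_assortativity), "NA",
                     sprintf("%.4f", x$degree_assortativity))))
  invisible(x)
}
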