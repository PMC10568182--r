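# DEG-induced protein-protein interaction subnetwork and degree-ranked hubs.

#' Induce the DEG subnetwork of a PPI edge list
#'
#' Keeps only edges whose two endpoints are both significant in the supplied
#' DE table, removing self-loops and duplicate unordered pairs, and annotates
#' every remaining node with its regulation direction and degree.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b` and optionally
#'   `score` (e.g. a STRING combined score).
#' @param de A `de_table`; its `significant` flags select the nodes.
#' @param min_score Optional minimum on the `score` column, applied before
#'   induction (for real STRING exports; ignored when no score is present).
#' @return An `interaction_graph`: list with `graph` (igraph object),
#'   `nodes` (`gene_id`, `direction`, `log2fc`, `degree`) and `edges`
#'   (the retained, canonicalised pairs). An empty result is valid.
#' @export
induce_deg_subgraph <- function(edges, de, min_score = NULL) {
  if (!is.data.frame(edges) || !all(c("gene_a", "gene_b") %in% names(edges))) {
    stop_invalid("`edges` must have columns gene_a, gene_b")
  }
  if (!is.null(min_score)) {
    if (!"score" %in% names(edges)) {
      stop_invalid("`min_score` given but `edges` has no score column")
    }
    edges <- edges[edges$score >= min_score, , drop = FALSE]
  }
  sig <- de[de$significant, , drop = FALSE]
  keep <- edges$gene_a %in% sig$gene_id & edges$gene_b %in% sig$gene_id &
    edges$gene_a != edges$gene_b
  e <- edges[keep, c("gene_a", "gene_b"), drop = FALSE]
  # canonical unordered representation, then de-duplicate
  lo <- pmin(e$gene_a, e$gene_b)
  hi <- pmax(e$gene_a, e$gene_b)
  e <- data.frame(gene_a = lo, gene_b = hi, stringsAsFactors = FALSE)
  e <- e[!duplicated(paste(e$gene_a, e$gene_b)), , drop = FALSE]
  e <- e[order(e$gene_a, e$gene_b), , drop = FALSE]
  rownames(e) <- NULL

  node_ids <- sort(unique(c(e$gene_a, e$gene_b)))
  idx <- match(node_ids, sig$gene_id)
  nodes <- data.frame(
    gene_id = node_ids,
    direction = sig$direction[idx],
    log2fc = sig$log2fc[idx],
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = nodes)
  nodes$degree <- if (length(node_ids)) {
    as.integer(igraph::degree(g)[nodes$gene_id])
  } else {
    integer(0)
  }
  structure(list(graph = g, nodes = nodes, edges = e),
            class = "interaction_graph")
}

#' Select degree-ranked hub genes
#'
#' Orders the nodes of an induced interaction graph by degree (descending)
#' and returns the top `k` as the hub table, tagging each with the
#' conventional display colour: red for upregulated, blue for downregulated.
#' Ties in degree are broken by larger `|log2fc|`, then lexicographic
#' gene id.
#'
#' @param graph An `interaction_graph` from [induce_deg_subgraph()].
#' @param k Number of hubs to keep (all nodes if fewer exist).
#' @return Data frame `rank`, `gene_id`, `degree`, `direction`, `log2fc`,
#'   `color`.
#' @export
select_hubs <- function(graph, k = 50) {
  if (!inherits(graph, "interaction_graph")) {
    stop_invalid("`graph` must come from induce_deg_subgraph()")
  }
  if (!is_scalar_count(k, positive = TRUE)) {
    stop_invalid("`k` must be a positive integer")
  }
  nodes <- graph$nodes
  ord <- order(-nodes$degree, -abs(nodes$log2fc), nodes$gene_id)
  hubs <- head(nodes[ord, , drop = FALSE], k)
  hubs$color <- ifelse(hubs$direction == "up", "red", "blue")
  if (nrow(hubs)) {
    hubs <- cbind(data.frame(rank = seq_len(nrow(hubs))), hubs)
  } else {
    hubs <- cbind(data.frame(rank = integer()), hubs)
  }
  rownames(hubs) <- NULL
  hubs
}
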