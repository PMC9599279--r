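#' Assemble the in-memory genome network
#'
#' Joins the edge list, the clustering overview, and the reference
#' taxonomy into the object all downstream algorithms consume. Node kind
#' is decided by the reference table: accessions it annotates are
#' references, every other node is a vOTU. Nodes present in the network
#' but missing from the overview default to status `Outlier` (a
#' conservative choice: it blocks genus-level inheritance through the
#' cluster path). Genomes listed in the overview but absent from the
#' edges are retained as degree-0 nodes.
#'
#' @param edges Data frame from [read_network()] (or
#'   [build_network()]`$edges`).
#' @param overview Data frame from [read_overview()].
#' @param refs Data frame from [read_reference_taxonomy()].
#' @param ranks Rank list (default [votu_ranks()]).
#' @return A `genome_network` object: undirected, positively weighted,
#'   simple graph plus one annotation row per node.
#' @export
assemble_network <- function(edges, overview, refs, ranks = votu_ranks()) {
  stopifnot(is.data.frame(edges), is.data.frame(overview),
            is.data.frame(refs))
  if (nrow(edges)) {
    if (any(edges$weight <= 0)) stop("edge weights must be positive",
                                     call. = FALSE)
    if (any(edges$source == edges$target)) stop("self-edges not allowed",
                                                call. = FALSE)
    key <- paste(pmin(edges$source, edges$target),
                 pmax(edges$source, edges$target))
    if (anyDuplicated(key)) stop("duplicate edges for an unordered pair",
                                 call. = FALSE)
  }
  if (anyDuplicated(overview$genome)) {
    stop("conflicting duplicate annotations for genome(s): ",
         paste(sQuote(unique(overview$genome[duplicated(overview$genome)])),
               collapse = ", "), call. = FALSE)
  }
  ids <- sort(unique(c(edges$source, edges$target, overview$genome)),
              method = "radix")
  ov <- overview[match(ids, overview$genome), , drop = FALSE]
  nodes <- data.frame(
    id = ids,
    kind = ifelse(ids %in% refs$accession, "reference", "votu"),
    status = ifelse(is.na(ov$genome), "Outlier", ov$status),
    overlap_count = ov$overlap_count,
    cluster_id = ov$cluster_id,
    subcluster_id = ov$subcluster_id,
    stringsAsFactors = FALSE
  )
  ref_rows <- match(ids, refs$accession)
  for (r in ranks) {
    nodes[[r]] <- ifelse(nodes$kind == "reference", refs[[r]][ref_rows],
                         NA_character_)
  }
  nodes$host <- ifelse(nodes$kind == "reference", refs$host[ref_rows],
                       NA_character_)
  rownames(nodes) <- nodes$id
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "weight"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  structure(list(graph = g, nodes = nodes, ranks = ranks),
            class = "genome_network")
}

#' @export
print.genome_network <- function(x, ...) {
  n_ref <- sum(x$nodes$kind == "reference")
  cat("<genome_network> ", nrow(x$nodes), " nodes (", n_ref,
      " references, ", nrow(x$nodes) - n_ref, " vOTUs), ",
      igraph::ecount(x$graph), " edges\n", sep = "")
  invisible(x)
}

.check_node <- function(net, node) {
  if (!node %in% net$nodes$id) {
    stop("unknown node ", sQuote(node), call. = FALSE)
  }
}

#' Neighbors of a node, strongest first
#'
#' Direct neighbors ordered by descending edge weight; ties are broken by
#' ascending node id, so the order is stable and independent of input
#' file order.
#'
#' @param net A `genome_network`.
#' @param node Node id.
#' @return Data frame with columns `id` and `weight` (possibly 0 rows).
#' @export
neighbors_sorted <- function(net, node) {
  .check_node(net, node)
  es <- igraph::incident(net$graph, node)
  if (length(es) == 0L) {
    return(data.frame(id = character(0), weight = numeric(0)))
  }
  ends <- igraph::ends(net$graph, es)
  nb <- ifelse(ends[, 1] == node, ends[, 2], ends[, 1])
  w <- igraph::edge_attr(net$graph, "weight", es)
  o <- order(-w, nb, method = "radix")
  data.frame(id = nb[o], weight = w[o], stringsAsFactors = FALSE,
             row.names = NULL)
}

# Annotation row for one node (1-row data frame).
.node_ann <- function(net, node) net$nodes[node, , drop = FALSE]
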