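.role_colors <- c(target = "red", source = "green",
                  "same-subcluster" = "orange", "same-cluster" = "yellow",
                  other = "neutral")

.lineage_string <- function(lineage) {
  lineage <- lineage[!is.na(lineage)]
  if (!length(lineage)) "" else paste(lineage, collapse = "; ")
}

#' Extract a vOTU's annotated ego subgraph
#'
#' The first-order neighborhood of a classified vOTU with the induced
#' edges among its members, annotated for interactive display: the vOTU
#' itself is the `target` (red), the reference it inherits from is the
#' `source` (green), nodes sharing its subcluster are orange, nodes only
#' sharing its cluster are yellow, everything else neutral. References
#' render as triangles, vOTUs as circles. Each edge carries its weight
#' plus a normalized `strength` in (0, 1]: weight over the maximum weight
#' in the subgraph (so the strongest edge always has strength 1).
#'
#' @param net A `genome_network`.
#' @param result One-row classification for the vOTU (from
#'   [classify_votu()] or a row of [classify_all()]).
#' @return A `votu_subgraph`: list with `votu`, `nodes` (id, role, color,
#'   shape, kind, status, cluster, subcluster, lineage) and `edges`
#'   (source, target, weight, strength).
#' @export
extract_subgraph <- function(net, result) {
  stopifnot(is.data.frame(result), nrow(result) == 1L)
  votu <- result$votu
  .check_node(net, votu)
  nb <- neighbors_sorted(net, votu)
  members <- c(votu, nb$id)
  sub <- igraph::induced_subgraph(net$graph, members)
  ann <- net$nodes[members, , drop = FALSE]
  vcl <- ann[votu, "cluster_id"]
  vsub <- ann[votu, "subcluster_id"]
  role <- rep("other", length(members))
  same_cl <- !is.na(vcl) & !is.na(ann$cluster_id) & ann$cluster_id == vcl
  same_sub <- !is.na(vsub) & !is.na(ann$subcluster_id) &
    ann$subcluster_id == vsub
  role[same_cl] <- "same-cluster"
  role[same_sub & same_cl] <- "same-subcluster"
  if (!is.na(result$source_accession)) {
    role[members == result$source_accession] <- "source"
  }
  role[members == votu] <- "target"
  lineage <- vapply(members, function(id) {
    if (id == votu) {
      .lineage_string(unlist(result[1, net$ranks]))
    } else {
      .lineage_string(unlist(net$nodes[id, net$ranks]))
    }
  }, character(1))
  nodes <- data.frame(
    id = members, role = role,
    color = unname(.role_colors[role]),
    shape = ifelse(ann$kind == "reference", "triangle", "circle"),
    kind = ann$kind,
    status = ann$status,
    cluster = ann$cluster_id, subcluster = ann$subcluster_id,
    lineage = unname(lineage),
    stringsAsFactors = FALSE, row.names = NULL)
  el <- igraph::as_data_frame(sub, what = "edges")
  edges <- data.frame(source = character(0), target = character(0),
                      weight = numeric(0), strength = numeric(0))
  if (nrow(el)) {
    edges <- data.frame(source = el$from, target = el$to,
                        weight = el$weight,
                        strength = el$weight / max(el$weight),
                        stringsAsFactors = FALSE)
  }
  structure(list(votu = votu, nodes = nodes, edges = edges),
            class = "votu_subgraph")
}

#' Serialize a vOTU subgraph
#'
#' Writes the annotated subgraph as GraphML (loadable by Cytoscape,
#' Gephi, igraph, networkx) or as a JSON node-link document
#' (`{"nodes": [...], "links": [...]}`). All node and edge attributes
#' from [extract_subgraph()] are preserved.
#'
#' @param subgraph A `votu_subgraph`.
#' @param path Output path.
#' @param format `"graphml"` or `"json"`.
#' @return Invisibly, the path.
#' @export
write_subgraph <- function(subgraph, path, format = c("graphml", "json")) {
  stopifnot(inherits(subgraph, "votu_subgraph"))
  format <- match.arg(format)
  nodes <- subgraph$nodes
  edges <- subgraph$edges
  if (format == "graphml") {
    nodes_g <- nodes
    names(nodes_g)[names(nodes_g) == "id"] <- "name"
    # GraphML writer rejects NA attribute values; serialize as ""
    for (col in names(nodes_g)) {
      nodes_g[[col]][is.na(nodes_g[[col]])] <- ""
    }
    g <- igraph::graph_from_data_frame(
      if (nrow(edges)) edges[, c("source", "target", "weight", "strength")]
      else data.frame(source = character(0), target = character(0),
                      weight = numeric(0), strength = numeric(0)),
      directed = FALSE, vertices = nodes_g)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    doc <- list(directed = FALSE, votu = subgraph$votu,
                nodes = nodes, links = edges)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
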