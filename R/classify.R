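#' Candidate reference genomes for a vOTU
#'
#' Two-stage neighbor search. Stage 1: among the vOTU's direct neighbors
#' that share its cluster, scan in weight order and keep reference
#' genomes; if any are found the search stops there (the `same-cluster`
#' path). Stage 2 (only when stage 1 yields nothing, or the vOTU has no
#' cluster at all): reference genomes among all direct neighbors,
#' regardless of clustering (the `any-neighbor` path). Inheritance is
#' strictly from direct neighbors — never transitive.
#'
#' @param net A `genome_network`.
#' @param votu A vOTU node id.
#' @return List with `path` (`"same-cluster"`, `"any-neighbor"` or
#'   `"none"`) and `candidates`, a data frame of reference `id`/`weight`
#'   rows in descending weight order (ties by ascending id).
#' @export
candidate_references <- function(net, votu) {
  .check_node(net, votu)
  ann <- .node_ann(net, votu)
  if (ann$kind != "votu") {
    stop(sQuote(votu), " is a reference genome; only vOTUs are classified",
         call. = FALSE)
  }
  nb <- neighbors_sorted(net, votu)
  nb_kind <- net$nodes[nb$id, "kind"]
  if (!is.na(ann$cluster_id)) {
    same <- !is.na(net$nodes[nb$id, "cluster_id"]) &
      net$nodes[nb$id, "cluster_id"] == ann$cluster_id
    cand <- nb[same & nb_kind == "reference", , drop = FALSE]
    if (nrow(cand)) {
      rownames(cand) <- NULL
      return(list(path = "same-cluster", candidates = cand))
    }
  }
  cand <- nb[nb_kind == "reference", , drop = FALSE]
  if (nrow(cand)) {
    rownames(cand) <- NULL
    return(list(path = "any-neighbor", candidates = cand))
  }
  list(path = "none",
       candidates = data.frame(id = character(0), weight = numeric(0)))
}

#' Assignment depth from clustering status and search path
#'
#' The confidence policy that truncates inherited lineages: taxonomy
#' inherited from outside the vOTU's cluster stops at family, whatever
#' the status; within the cluster, a vOTU whose status is
#' `Clustered/Singleton` or `Overlap` stops at subfamily; otherwise the
#' full lineage down to genus is retained.
#'
#' @param status A clustering status label (see [votu_statuses()]).
#' @param path `"same-cluster"` or `"any-neighbor"`.
#' @return `"genus"`, `"subfamily"` or `"family"`.
#' @export
#' @examples
#' assignment_level("Clustered", "same-cluster")   # genus
#' assignment_level("Overlap", "same-cluster")     # subfamily
#' assignment_level("Clustered", "any-neighbor")   # family
assignment_level <- function(status, path) {
  stopifnot(status %in% votu_statuses())
  path <- match.arg(path, c("same-cluster", "any-neighbor"))
  if (path == "any-neighbor") return("family")
  if (status %in% c("Clustered/Singleton", "Overlap")) return("subfamily")
  "genus"
}

.unclassified_result <- function(net, votu, ann) {
  res <- data.frame(
    votu = votu, source_accession = NA_character_, weight = NA_real_,
    status = ann$status, overlap_count = ann$overlap_count,
    level = "unclassified", path = "none", stringsAsFactors = FALSE
  )
  for (r in net$ranks) res[[r]] <- NA_character_
  res$host <- NA_character_
  res
}

#' Classify one vOTU by taxonomy inheritance
#'
#' The vOTU inherits the lineage of the first reference genome on the
#' candidate list from [candidate_references()] (highest edge weight,
#' ties broken by ascending id), truncated at the depth given by
#' [assignment_level()]. With no reference reachable, the vOTU stays
#' unclassified. The reported level records the confidence policy, not
#' lineage completeness: a reference with gaps contributes whatever
#' shallower ranks it has.
#'
#' @param net A `genome_network`.
#' @param votu A vOTU node id.
#' @return One-row data frame: `votu`, `source_accession`, `weight`,
#'   `status`, `overlap_count`, `level`, `path`, one column per rank,
#'   `host`.
#' @export
classify_votu <- function(net, votu) {
  ann <- .node_ann(net, votu)
  cand <- candidate_references(net, votu)
  if (cand$path == "none") {
    res <- .unclassified_result(net, votu, ann)
  } else {
    src <- cand$candidates[1L, ]
    level <- assignment_level(ann$status, cand$path)
    lineage <- unlist(net$nodes[src$id, net$ranks])
    names(lineage) <- net$ranks
    lineage <- truncate_lineage(lineage, level, net$ranks)
    res <- data.frame(
      votu = votu, source_accession = src$id, weight = src$weight,
      status = ann$status, overlap_count = ann$overlap_count,
      level = level, path = cand$path, stringsAsFactors = FALSE
    )
    for (r in net$ranks) res[[r]] <- unname(lineage[[r]])
    res$host <- net$nodes[src$id, "host"]
  }
  attr(res, "ranks") <- net$ranks
  rownames(res) <- NULL
  res
}

#' Classify every vOTU in the network
#'
#' Runs [classify_votu()] on each vOTU-kind node independently; no vOTU
#' ever inherits from another vOTU, and results do not depend on input
#' order (rows are sorted by vOTU id).
#'
#' @param net A `genome_network`.
#' @return Data frame with one row per vOTU (see [classify_votu()]),
#'   with the rank list attached as attribute `"ranks"`.
#' @export
classify_all <- function(net) {
  votus <- sort(net$nodes$id[net$nodes$kind == "votu"], method = "radix")
  res <- do.call(rbind, lapply(votus, classify_votu, net = net))
  if (is.null(res)) {
    res <- .unclassified_result(net, character(0),
                                net$nodes[0, , drop = FALSE])[0, ]
  }
  rownames(res) <- NULL
  attr(res, "ranks") <- net$ranks
  res
}
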