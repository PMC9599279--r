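#' Taxonomic ranks used by the classifier
#'
#' The ordered rank list over which lineages are stored and truncated,
#' from the shallowest (realm) to the deepest rank the inheritance
#' algorithm assigns (genus). All lineage tables in the package carry one
#' column per rank, in this order; truncation at a rank clears every
#' deeper rank and only those.
#'
#' @return Character vector of rank names, shallow to deep.
#' @export
#' @examples
#' votu_ranks()
votu_ranks <- function() {
  c("realm", "phylum", "class", "order", "family", "subfamily", "genus")
}

#' Clustering status vocabulary
#'
#' The per-genome labels emitted by gene-sharing network clustering:
#' `Clustered` (the sequence falls clearly within one cluster and
#' subcluster), `Overlap` (it fits two or more clusters equally well),
#' `Clustered/Singleton` (its subcluster holds only one sequence),
#' `Outlier` (no cluster could be assigned) and `Singleton` (never placed
#' in any cluster). `Overlap` may carry a parenthetical count of the
#' clusters involved, e.g. `"Overlap (2)"`.
#'
#' @return Character vector of accepted status labels.
#' @export
votu_statuses <- function() {
  c("Clustered", "Clustered/Singleton", "Overlap", "Outlier", "Singleton")
}

#' Parse a clustering status string
#'
#' Normalizes a raw status token into its label plus, for `Overlap`, an
#' optional cluster count parsed from a parenthetical suffix
#' (`"Overlap (2)"` or `"Overlap(2)"`).
#'
#' @param x Single status string.
#' @return List with elements `label` (one of [votu_statuses()]) and
#'   `overlap_count` (positive integer or `NA`).
#' @export
#' @examples
#' parse_cluster_status("Overlap (2)")
parse_cluster_status <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  raw <- trimws(x)
  overlap_count <- NA_integer_
  m <- regmatches(raw, regexec("^(.*?)\\s*\\((\\d+)\\)$", raw))[[1]]
  if (length(m) == 3L) {
    label <- m[2]
    overlap_count <- as.integer(m[3])
  } else {
    label <- raw
  }
  if (!label %in% votu_statuses()) {
    stop("unknown clustering status ", sQuote(raw), "; accepted labels: ",
         paste(sQuote(votu_statuses()), collapse = ", "), call. = FALSE)
  }
  if (!is.na(overlap_count) && label != "Overlap") {
    stop("parenthetical count is only valid for 'Overlap' status, got ",
         sQuote(raw), call. = FALSE)
  }
  list(label = label, overlap_count = overlap_count)
}

#' @rdname parse_cluster_status
#' @param label Status label.
#' @param overlap_count Optional overlap count (`NA` to omit).
#' @return `format_cluster_status()` returns the printable status string.
#' @export
format_cluster_status <- function(label, overlap_count = NA_integer_) {
  if (!is.na(overlap_count)) paste0(label, " (", overlap_count, ")") else label
}

#' An empty lineage
#'
#' @param ranks Rank list (default [votu_ranks()]).
#' @return Named character vector, one `NA` per rank.
#' @export
empty_lineage <- function(ranks = votu_ranks()) {
  stats::setNames(rep(NA_character_, length(ranks)), ranks)
}

#' Truncate a lineage at an assignment level
#'
#' Clears every rank strictly deeper than `level`, leaving shallower
#' ranks untouched (gaps in the source lineage are preserved as-is).
#' `level = "unclassified"` clears all ranks.
#'
#' @param lineage Named character vector over `ranks` (`NA` = unassigned).
#' @param level A rank name, or `"unclassified"`.
#' @param ranks Rank list, shallow to deep.
#' @return The truncated lineage (same names, same order).
#' @export
#' @examples
#' lin <- c(realm = "Duplodnaviria", phylum = NA, class = NA, order = NA,
#'          family = "Drexlerviridae", subfamily = NA, genus = "Guelphvirus")
#' truncate_lineage(lin, "family")
truncate_lineage <- function(lineage, level, ranks = votu_ranks()) {
  stopifnot(setequal(names(lineage), ranks))
  lineage <- lineage[ranks]
  if (identical(level, "unclassified")) {
    return(empty_lineage(ranks))
  }
  pos <- match(level, ranks)
  if (is.na(pos)) {
    stop("unknown assignment level ", sQuote(level), call. = FALSE)
  }
  if (pos < length(ranks)) {
    lineage[(pos + 1L):length(ranks)] <- NA_character_
  }
  lineage
}

# Cells treated as "no assignment" when reading reference taxonomy tables.
.taxonomy_sentinels <- c("", "na", "unclassified")

.is_taxon_sentinel <- function(x) {
  is.na(x) | tolower(trimws(x)) %in% .taxonomy_sentinels
}
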