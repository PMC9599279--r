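#' Read a gene-sharing network edge list
#'
#' Parses the whitespace-separated `source target weight` dialect used by
#' vConTACT2 (`c1.ntw`): no header, one undirected weighted edge per line.
#' Duplicate unordered pairs are merged keeping the maximum weight (with a
#' warning), so symmetric or concatenated dumps read cleanly. The returned
#' edge set is independent of line order.
#'
#' @param path Path to the edge-list file.
#' @return A data frame with columns `source`, `target` (character) and
#'   `weight` (positive numeric), one row per unique unordered node pair,
#'   sorted by the unordered pair for determinism. Orientation of each
#'   pair follows its first occurrence in the file.
#' @export
#' @examples
#' f <- tempfile(fileext = ".ntw")
#' writeLines("vOTU_1 NC_001416 31.5", f)
#' read_network(f)
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  n <- length(lines)
  src <- character(n); tgt <- character(n); w <- numeric(n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 3L) {
      stop("malformed edge at line ", lineno[i],
           ": expected 'source target weight', got ", sQuote(lines[i]),
           call. = FALSE)
    }
    wt <- suppressWarnings(as.numeric(tok[3]))
    if (is.na(wt)) {
      stop("malformed edge at line ", lineno[i], ": non-numeric weight ",
           sQuote(tok[3]), call. = FALSE)
    }
    if (wt <= 0) {
      stop("malformed edge at line ", lineno[i],
           ": weight must be positive, got ", tok[3], call. = FALSE)
    }
    if (tok[1] == tok[2]) {
      stop("self-edge at line ", lineno[i], ": ", sQuote(tok[1]),
           call. = FALSE)
    }
    src[i] <- tok[1]; tgt[i] <- tok[2]; w[i] <- wt
  }
  edges <- data.frame(source = src, target = tgt, weight = w,
                      stringsAsFactors = FALSE)
  key <- paste(pmin(edges$source, edges$target),
               pmax(edges$source, edges$target))
  if (anyDuplicated(key)) {
    warning("duplicate edges for ", sum(duplicated(key)),
            " unordered pair(s); keeping the maximum weight", call. = FALSE)
    maxw <- tapply(edges$weight, key, max)
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges$weight <- as.numeric(maxw[paste(pmin(edges$source, edges$target),
                                          pmax(edges$source, edges$target))])
    key <- key[!duplicated(key)]
  }
  edges <- edges[order(key, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Read a genome-by-genome clustering overview table
#'
#' Reads the per-node cluster assignment CSV produced alongside the
#' network: one row per genome with its clustering status and a combined
#' cluster/subcluster token of the form `VC_<c>_<s>` (parsed into cluster
#' `VC_<c>` and subcluster `VC_<c>_<s>`; a token without the subcluster
#' part yields cluster only). Column names are remappable via `columns`.
#'
#' @param path Path to the CSV file (header required).
#' @param columns Named character vector mapping the logical fields
#'   `genome`, `status`, `cluster` to header names in the file.
#' @return Data frame with columns `genome`, `status` (label),
#'   `overlap_count`, `cluster_id`, `subcluster_id` (`NA` where absent).
#' @export
read_overview <- function(path,
                          columns = c(genome = "Genome",
                                      status = "VC Status",
                                      cluster = "VC")) {
  stopifnot(all(c("genome", "status", "cluster") %in% names(columns)))
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character",
                        stringsAsFactors = FALSE)
  missing <- setdiff(unname(columns), names(df))
  if (length(missing)) {
    stop("overview table lacks column(s): ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  genome <- df[[columns[["genome"]]]]
  if (anyDuplicated(genome)) {
    stop("duplicate genome id(s) in overview: ",
         paste(sQuote(unique(genome[duplicated(genome)])), collapse = ", "),
         call. = FALSE)
  }
  parsed <- lapply(df[[columns[["status"]]]], parse_cluster_status)
  status <- vapply(parsed, `[[`, character(1), "label")
  overlap_count <- vapply(parsed, `[[`, integer(1), "overlap_count")
  vc <- trimws(df[[columns[["cluster"]]]])
  vc[is.na(vc)] <- ""
  cl <- sub <- rep(NA_character_, nrow(df))
  has <- nzchar(vc)
  for (i in which(has)) {
    parts <- strsplit(vc[i], "_", fixed = TRUE)[[1]]
    if (length(parts) >= 3L) {
      cl[i] <- paste(parts[1:2], collapse = "_")
      sub[i] <- vc[i]
    } else {
      cl[i] <- vc[i]
    }
  }
  # an Outlier has, by definition, no cluster membership
  drop <- status == "Outlier" & !is.na(cl)
  if (any(drop)) {
    warning(sum(drop), " Outlier row(s) carried a cluster label; ",
            "cluster membership ignored for those", call. = FALSE)
    cl[drop] <- NA_character_
    sub[drop] <- NA_character_
  }
  data.frame(genome = genome, status = status,
             overlap_count = overlap_count,
             cluster_id = cl, subcluster_id = sub,
             stringsAsFactors = FALSE)
}

#' Read a reference taxonomy table
#'
#' Reads an INPHARED-style CSV of curated phage genomes: an accession
#' column, any subset of the configured rank columns (matched
#' case-insensitively against the rank names), and an optional host
#' column. Blank, `NA` or `Unclassified` cells (case-insensitive) yield
#' unassigned ranks; gaps in a lineage are allowed.
#'
#' @param path Path to the CSV file.
#' @param ranks Rank list (default [votu_ranks()]).
#' @param accession_col Header name of the accession column.
#' @param host_col Header name of the host column (absent is fine).
#' @return Data frame with columns `accession`, one per rank, and `host`.
#' @export
read_reference_taxonomy <- function(path, ranks = votu_ranks(),
                                    accession_col = "Accession",
                                    host_col = "Host") {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character",
                        stringsAsFactors = FALSE)
  acc_idx <- match(tolower(accession_col), tolower(names(df)))
  if (is.na(acc_idx)) {
    stop("reference taxonomy table lacks the accession column ",
         sQuote(accession_col), call. = FALSE)
  }
  accession <- df[[acc_idx]]
  if (anyDuplicated(accession)) {
    stop("duplicate accession(s): ",
         paste(sQuote(unique(accession[duplicated(accession)])),
               collapse = ", "), call. = FALSE)
  }
  out <- data.frame(accession = accession, stringsAsFactors = FALSE)
  for (r in ranks) {
    idx <- match(tolower(r), tolower(names(df)))
    col <- if (is.na(idx)) rep(NA_character_, nrow(df)) else df[[idx]]
    col[.is_taxon_sentinel(col)] <- NA_character_
    out[[r]] <- col
  }
  host_idx <- match(tolower(host_col), tolower(names(df)))
  host <- if (is.na(host_idx)) rep(NA_character_, nrow(df)) else df[[host_idx]]
  host[.is_taxon_sentinel(host)] <- NA_character_
  out$host <- host
  out
}

#' Write the per-vOTU taxonomy table
#'
#' Serializes classification results to CSV: one row per vOTU, in the
#' order given, with the closest reference, its clustering `Status`, the
#' edge `Weight` (3 decimal places; empty when unclassified), the
#' assignment `Level`, one column per rank and the reference's host.
#' Re-reading the file with a generic CSV reader reproduces every field.
#'
#' @param results Classification results from [classify_all()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_taxonomy_table <- function(results, path) {
  stopifnot(is.data.frame(results), nrow(results) > 0L)
  ranks <- attr(results, "ranks")
  if (is.null(ranks)) ranks <- votu_ranks()
  status <- mapply(format_cluster_status, results$status,
                   results$overlap_count, USE.NAMES = FALSE)
  out <- data.frame(
    vOTU = results$votu,
    ClosestReference = ifelse(is.na(results$source_accession), "",
                              results$source_accession),
    Status = status,
    Weight = ifelse(is.na(results$weight), "",
                    sprintf("%.3f", results$weight)),
    Level = results$level,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (r in ranks) {
    col <- results[[r]]
    nice <- paste0(toupper(substring(r, 1, 1)), substring(r, 2))
    out[[nice]] <- ifelse(is.na(col), "", col)
  }
  out$Host <- ifelse(is.na(results$host), "", results$host)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a vOTU-by-sample count table
#'
#' First column: vOTU ids; header row: sample ids. Separator inferred
#' from the extension (`.tsv`/`.txt` tab, otherwise comma).
#'
#' @param path Path to the CSV/TSV file.
#' @return Integer matrix, vOTUs as rows, samples as columns.
#' @export
read_count_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate vOTU ids in count table",
                               call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(is.na(m))) stop("non-numeric entries in count table", call. = FALSE)
  if (any(m < 0)) stop("negative entries in count table", call. = FALSE)
  rownames(m) <- ids
  m
}

#' Read a vOTU-to-miner membership table
#'
#' Long-format CSV with columns `votu,miner`, one membership per row.
#'
#' @param path Path to the CSV file.
#' @return Named list mapping each vOTU id to its set of miner names.
#' @export
read_miner_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (!all(c("votu", "miner") %in% tolower(names(df)))) {
    stop("miner table needs columns 'votu' and 'miner'", call. = FALSE)
  }
  names(df) <- tolower(names(df))
  split(df$miner, df$votu)
}

#' Read protein-cluster profiles
#'
#' Long-format CSV with columns `genome,pc`, one PC membership per row;
#' duplicate memberships collapse (set semantics).
#'
#' @param path Path to the CSV file.
#' @return Named list mapping each genome id to its PC identifier set.
#' @export
read_pc_profiles <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (!all(c("genome", "pc") %in% tolower(names(df)))) {
    stop("profile table needs columns 'genome' and 'pc'", call. = FALSE)
  }
  names(df) <- tolower(names(df))
  lapply(split(df$pc, df$genome), unique)
}
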