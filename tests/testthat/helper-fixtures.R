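# Hand-built 8-node network: 5 references, 3 vOTUs, mixed statuses.
# Exercises stage-1 cluster filtering, the tie-break, the out-of-cluster
# fallback, lineage gaps and the absence of transitive inheritance.
toy_edges <- function() {
  data.frame(
    source = c("vOTU_1", "vOTU_1", "vOTU_1", "vOTU_1", "vOTU_2", "vOTU_3"),
    target = c("RefA", "RefE", "RefC", "vOTU_2", "RefD", "vOTU_2"),
    weight = c(50, 50, 80, 90, 30, 10),
    stringsAsFactors = FALSE
  )
}

toy_overview <- function() {
  data.frame(
    genome = c("RefA", "RefB", "RefC", "RefD", "RefE",
               "vOTU_1", "vOTU_2", "vOTU_3"),
    status = c("Clustered", "Clustered", "Clustered", "Outlier",
               "Clustered", "Clustered", "Overlap", "Clustered/Singleton"),
    overlap_count = c(NA, NA, NA, NA, NA, NA, 2L, NA),
    cluster_id = c("VC_1", "VC_1", "VC_2", NA, "VC_1",
                   "VC_1", NA, "VC_1"),
    subcluster_id = c("VC_1_1", "VC_1_2", "VC_2_1", NA, "VC_1_1",
                      "VC_1_1", NA, "VC_1_3"),
    stringsAsFactors = FALSE
  )
}

toy_refs <- function() {
  data.frame(
    accession = c("RefA", "RefB", "RefC", "RefD", "RefE"),
    realm = "Duplodnaviria", phylum = "Uroviricota",
    class = "Caudoviricetes", order = "Caudovirales",
    family = c("F1viridae", "F1viridae", "F2viridae", "F3viridae",
               "F1viridae"),
    subfamily = c("SF1virinae", "SF2virinae", "SF3virinae", NA,
                  "SF1virinae"),
    genus = c("G1virus", "G2virus", "G3virus", "G4virus", "G5virus"),
    host = c("Escherichia coli", "Escherichia coli", "Bacillus subtilis",
             "Salmonella enterica", "Escherichia coli"),
    stringsAsFactors = FALSE
  )
}

toy_network <- function() {
  assemble_network(toy_edges(), toy_overview(), toy_refs())
}

# Write the toy fixture in the on-disk dialects.
write_toy_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ed <- toy_edges()
  writeLines(sprintf("%s %s %.1f", ed$source, ed$target, ed$weight),
             file.path(dir, "network.ntw"))
  ov <- toy_overview()
  vc <- ifelse(is.na(ov$subcluster_id), "", ov$subcluster_id)
  st <- mapply(votunet::format_cluster_status, ov$status, ov$overlap_count,
               USE.NAMES = FALSE)
  write.csv(data.frame(Genome = ov$genome, `VC Status` = st, VC = vc,
                       check.names = FALSE),
            file.path(dir, "overview.csv"), row.names = FALSE)
  rf <- toy_refs()
  names(rf) <- c("Accession", "Realm", "Phylum", "Class", "Order",
                 "Family", "Subfamily", "Genus", "Host")
  write.csv(rf, file.path(dir, "taxonomy.csv"), row.names = FALSE)
  dir
}

# Exact brute-force hypergeometric upper tail, independent of the
# log-space implementation: direct sum of binomial-coefficient ratios.
brute_tail <- function(c, a, b, n) {
  if (c == 0) return(1)
  i <- c:min(a, b)
  sum(choose(b, i) * choose(n - b, a - i)) / choose(n, a)
}
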