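test_that("edge lists parse, merge duplicates by max weight, reject bad lines", {
  f <- withr::local_tempfile(fileext = ".ntw")

  writeLines("vOTU_1 NC_001416 31.5", f)
  ed <- read_network(f)
  expect_equal(nrow(ed), 1L)
  expect_setequal(c(ed$source, ed$target), c("vOTU_1", "NC_001416"))
  expect_equal(ed$weight, 31.5)

  writeLines(c("A B 2.0", "B A 3.0"), f)
  expect_warning(ed <- read_network(f), "duplicate")
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$weight, 3.0)

  writeLines("A A 5.0", f)
  expect_error(read_network(f), "self-edge at line 1")
  writeLines(c("A B 1.0", "C D"), f)
  expect_error(read_network(f), "line 2")
  writeLines("A B xyz", f)
  expect_error(read_network(f), "non-numeric")
  writeLines("A B -1", f)
  expect_error(read_network(f), "positive")
})

test_that("edge parsing is insensitive to line order", {
  f1 <- withr::local_tempfile(fileext = ".ntw")
  f2 <- withr::local_tempfile(fileext = ".ntw")
  lines <- c("A B 2.5", "B C 1.25", "A C 9", "D A 4")
  writeLines(lines, f1)
  writeLines(rev(lines), f2)
  e1 <- read_network(f1)
  e2 <- read_network(f2)
  key <- function(e) paste(pmin(e$source, e$target),
                           pmax(e$source, e$target), e$weight)
  expect_setequal(key(e1), key(e2))
})

test_that("overview rows parse cluster/subcluster tokens and statuses", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Genome,VC Status,VC",
               "vOTU_7,Clustered,VC_22_1",
               "vOTU_9,Outlier,",
               "vOTU_3,Overlap (2),",
               "vOTU_4,Clustered/Singleton,VC_5"), f)
  ov <- read_overview(f)
  r7 <- ov[ov$genome == "vOTU_7", ]
  expect_equal(r7$cluster_id, "VC_22")
  expect_equal(r7$subcluster_id, "VC_22_1")
  r9 <- ov[ov$genome == "vOTU_9", ]
  expect_equal(r9$status, "Outlier")
  expect_true(is.na(r9$cluster_id))
  r3 <- ov[ov$genome == "vOTU_3", ]
  expect_equal(r3$status, "Overlap")
  expect_equal(r3$overlap_count, 2L)
  expect_true(is.na(r3$cluster_id))
  r4 <- ov[ov$genome == "vOTU_4", ]
  expect_equal(r4$cluster_id, "VC_5")
  expect_true(is.na(r4$subcluster_id))
  # subcluster implies a cluster whose label is its prefix
  with_sub <- !is.na(ov$subcluster_id)
  expect_true(all(startsWith(ov$subcluster_id[with_sub],
                             ov$cluster_id[with_sub])))
})

test_that("overview rejects unknown statuses and duplicate genomes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Genome,VC Status,VC", "a,Oddball,"), f)
  expect_error(read_overview(f), "accepted labels")
  writeLines(c("Genome,VC Status,VC", "a,Clustered,VC_1_1",
               "a,Outlier,"), f)
  expect_error(read_overview(f), "duplicate genome")
  writeLines(c("id,state,vc", "a,Clustered,VC_1_1"), f)
  expect_error(read_overview(f), "lacks column")
  ov <- read_overview(f, columns = c(genome = "id", status = "state",
                                     cluster = "vc"))
  expect_equal(ov$genome, "a")
})

test_that("reference taxonomy handles sentinels, gaps and missing columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Accession,Family,Genus,Host",
               "NC_1,Drexlerviridae,Guelphvirus,Escherichia coli",
               "NC_2,NA,unclassified,",
               "NC_3,Straboviridae,,Klebsiella"), f)
  rt <- read_reference_taxonomy(f)
  expect_equal(names(rt), c("accession", votu_ranks(), "host"))
  r1 <- rt[rt$accession == "NC_1", ]
  expect_equal(r1$family, "Drexlerviridae")
  expect_equal(r1$genus, "Guelphvirus")
  expect_true(is.na(r1$realm))        # column absent from the file
  expect_true(is.na(r1$subfamily))
  r2 <- rt[rt$accession == "NC_2", ]
  expect_true(all(is.na(unlist(r2[votu_ranks()]))))
  expect_true(is.na(r2$host))
  expect_equal(rt[rt$accession == "NC_3", "host"], "Klebsiella")

  writeLines(c("Genome,Family", "NC_1,F"), f)
  expect_error(read_reference_taxonomy(f), "accession column")
  writeLines(c("Accession,Family", "NC_1,F", "NC_1,G"), f)
  expect_error(read_reference_taxonomy(f), "duplicate accession")
})

test_that("taxonomy table writes classified and unclassified rows and round-trips", {
  net <- toy_network()
  res <- classify_all(net)
  f <- withr::local_tempfile(fileext = ".csv")
  write_taxonomy_table(res, f)
  back <- read.csv(f, colClasses = "character", check.names = FALSE)
  expect_equal(nrow(back), 3L)
  expect_equal(back$vOTU, res$votu)

  r1 <- back[back$vOTU == "vOTU_1", ]
  expect_equal(r1$ClosestReference, "RefA")
  expect_equal(r1$Weight, "50.000")
  expect_equal(r1$Level, "genus")
  r2 <- back[back$vOTU == "vOTU_2", ]
  expect_equal(r2$Status, "Overlap (2)")
  r3 <- back[back$vOTU == "vOTU_3", ]
  expect_equal(r3$ClosestReference, "")
  expect_equal(r3$Weight, "")
  expect_true(all(r3[, c("Realm", "Family", "Genus")] == ""))

  # field-for-field round trip against the in-memory results
  for (i in seq_len(nrow(res))) {
    row <- back[i, ]
    expect_equal(row$vOTU, res$votu[i])
    for (r in votu_ranks()) {
      nice <- paste0(toupper(substring(r, 1, 1)), substring(r, 2))
      expect_equal(row[[nice]],
                   ifelse(is.na(res[[r]][i]), "", res[[r]][i]))
    }
    expect_equal(row$Host, ifelse(is.na(res$host[i]), "", res$host[i]))
  }
})

test_that("count and miner tables read their long/wide dialects", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("vOTU,s1,s2", "v1,3,0", "v2,7,5"), f)
  m <- read_count_table(f)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["v2", "s2"], 5)
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("vOTU\ts1", "v1\t4"), ftsv)
  expect_equal(read_count_table(ftsv)["v1", "s1"], 4)

  fm <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("votu,miner", "v1,A", "v1,B", "v2,A"), fm)
  mm <- read_miner_table(fm)
  expect_setequal(mm$v1, c("A", "B"))
  expect_equal(mm$v2, "A")

  fp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("genome,pc", "g1,p1", "g1,p1", "g1,p2"), fp)
  expect_setequal(read_pc_profiles(fp)$g1, c("p1", "p2"))
})
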