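test_that("miner combinations tally exact assignment sets", {
  out <- miner_overlap(list(v1 = "A", v2 = c("A", "B"), v3 = c("B", "A")),
                       universe = c("A", "B", "C"))
  expect_equal(out$count[out$combination == "A&B"], 2L)
  expect_equal(out$count[out$combination == "A"], 1L)
  expect_equal(nrow(out), 2L)
  expect_equal(sum(out$count), 3L)

  all5 <- miner_overlap(setNames(rep(list(LETTERS[1:5]), 7),
                                 paste0("v", 1:7)), LETTERS[1:5])
  expect_equal(nrow(all5), 1L)
  expect_equal(all5$combination, "A&B&C&D&E")
  expect_equal(all5$n_miners, 5L)
  expect_equal(all5$count, 7L)

  expect_error(miner_overlap(list(v1 = "Z"), LETTERS[1:5]), "universe")
  expect_error(miner_overlap(list(v1 = character(0)), LETTERS[1:5]),
               "empty")
})

test_that("miner combination counts match brute-force subset enumeration", {
  set.seed(21)
  universe <- c("dvf", "vibrant", "phigaro", "virsorter2")
  assign <- lapply(1:50, function(i) {
    sample(universe, sample(1:4, 1))
  })
  names(assign) <- sprintf("v%02d", 1:50)
  out <- miner_overlap(assign, universe)
  # enumerate all 15 non-empty subsets and count matches directly
  total <- 0L
  for (k in 1:4) {
    combos <- combn(universe, k, simplify = FALSE)
    for (s in combos) {
      n <- sum(vapply(assign, function(m) setequal(m, s), logical(1)))
      key <- paste(universe[universe %in% s], collapse = "&")
      got <- out$count[out$combination == key]
      expect_equal(if (length(got)) got else 0L, n)
      total <- total + n
    }
  }
  expect_equal(total, 50L)
  expect_equal(sum(out$count), 50L)
})

test_that("RPM normalization rescales columns to one million", {
  m <- matrix(c(2, 3, 5, 7, 0, 0), ncol = 2,
              dimnames = list(paste0("v", 1:3), c("s1", "s2")))
  r <- rpm_normalize(m)
  expect_equal(r[, "s1"], c(v1 = 2e5, v2 = 3e5, v3 = 5e5))
  expect_equal(unname(r["v1", "s2"]), 1e6)
  expect_equal(colSums(r), c(s1 = 1e6, s2 = 1e6), tolerance = 1e-6)
  # proportions within a sample are untouched
  expect_equal(r[2, 1] / r[1, 1], m[2, 1] / m[1, 1])
  m0 <- cbind(m, s3 = c(0, 0, 0))
  expect_error(rpm_normalize(m0), "s3")
})

test_that("alpha diversity matches its closed forms", {
  u <- matrix(c(5, 5, 5, 5), ncol = 1, dimnames = list(NULL, "s"))
  expect_equal(unname(alpha_diversity(u, "shannon")), log(4),
               tolerance = 1e-12)
  expect_equal(unname(alpha_diversity(u, "simpson")), 0.75,
               tolerance = 1e-12)
  expect_equal(unname(alpha_diversity(u, "observed")), 4)

  x <- matrix(c(1, 1, 2, 2, 3), ncol = 1, dimnames = list(NULL, "s"))
  # F1 = 2, F2 = 2: chao1 = 5 + 2*1/(2*3)
  expect_equal(unname(alpha_diversity(x, "chao1")), 5 + 2 * 1 / (2 * 3),
               tolerance = 1e-9)
  # no singletons: chao1 collapses to observed richness
  y <- matrix(c(2, 2, 3), ncol = 1, dimnames = list(NULL, "s"))
  expect_equal(unname(alpha_diversity(y, "chao1")), 3, tolerance = 1e-12)
  expect_gte(unname(alpha_diversity(x, "ace")),
             unname(alpha_diversity(x, "observed")))
  expect_error(alpha_diversity(x, "unheard"))
})

test_that("fisher's alpha satisfies its defining equation", {
  set.seed(4)
  for (i in 1:10) {
    x <- matrix(rpois(30, 3) + rbinom(30, 1, 0.5), ncol = 1,
                dimnames = list(NULL, "s"))
    S <- sum(x > 0); N <- sum(x)
    if (S == 0 || S >= N) next
    a <- unname(alpha_diversity(x, "fisher"))
    expect_equal(a * log1p(N / a), S, tolerance = 1e-8)
  }
  ones <- matrix(c(1, 1, 1), ncol = 1, dimnames = list(NULL, "s"))
  expect_error(alpha_diversity(ones, "fisher"), "undefined")
  half <- matrix(c(2.5), ncol = 1, dimnames = list(NULL, "s"))
  expect_error(alpha_diversity(half, "fisher"), "integer")
})

test_that("beta diversity behaves on identical, disjoint and hand-worked samples", {
  m <- matrix(c(2, 1, 0, 2, 1, 0, 0, 1, 2), ncol = 3,
              dimnames = list(paste0("v", 1:3), c("a", "b", "c")))
  for (metric in c("bray-curtis", "jaccard")) {
    d <- beta_diversity(m, metric)
    expect_equal(dim(d), c(3L, 3L))
    expect_equal(d, t(d))
    expect_equal(diag(d), c(a = 0, b = 0, c = 0))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d["a", "b"], 0)          # identical columns
  }
  # x = (2,1,0), y = (0,1,2): bray = 4/6, binary jaccard = 1 - 1/3
  expect_equal(beta_diversity(m, "bray-curtis")["a", "c"], 4 / 6,
               tolerance = 1e-12)
  expect_equal(beta_diversity(m, "jaccard")["a", "c"], 2 / 3,
               tolerance = 1e-12)
  disj <- matrix(c(1, 1, 0, 0, 0, 0, 2, 3), ncol = 2,
                 dimnames = list(paste0("v", 1:4), c("a", "b")))
  expect_equal(beta_diversity(disj, "bray-curtis")["a", "b"], 1)
  expect_equal(beta_diversity(disj, "jaccard")["a", "b"], 1)
  zz <- matrix(0, 3, 2, dimnames = list(paste0("v", 1:3), c("a", "b")))
  expect_error(beta_diversity(zz, "jaccard"), "all-zero")
  expect_error(beta_diversity(m[, 1, drop = FALSE], "jaccard"),
               "two samples")
})

test_that("taxonomy summaries count taxa and vOTUs per rank", {
  net <- toy_network()
  res <- classify_all(net)
  ts <- taxonomy_summary(res)
  expect_equal(ts$rank, votu_ranks())
  # vOTU_1 reaches genus, vOTU_2 stops at family, vOTU_3 unclassified
  expect_equal(ts$n_votus[ts$rank == "family"], 2L)
  expect_equal(ts$n_taxa[ts$rank == "family"], 2L)
  expect_equal(ts$n_votus[ts$rank == "genus"], 1L)
  expect_equal(ts$n_taxa[ts$rank == "genus"], 1L)
  expect_equal(ts$n_votus[ts$rank == "realm"], 2L)
  expect_equal(ts$n_taxa[ts$rank == "realm"], 1L)

  # all unclassified: zero everywhere
  ov <- toy_overview()
  empty <- classify_all(assemble_network(toy_edges()[6, ], ov[6:8, ],
                                         toy_refs()))
  ts0 <- taxonomy_summary(empty)
  expect_true(all(ts0$n_taxa == 0L))
  expect_true(all(ts0$n_votus == 0L))
})
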