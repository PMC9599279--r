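#' Miner-overlap combination counts
#'
#' Tallies, for every combination of phage miners that occurs as an
#' exact assignment set, how many vOTUs were found by precisely that
#' combination — the counts behind an UpSet plot. Combinations with zero
#' vOTUs are omitted, so the counts always sum to the number of vOTUs.
#'
#' @param assign Named list mapping each vOTU id to a non-empty set of
#'   miner names (as returned by [read_miner_table()]).
#' @param universe Character vector of all declared miner names.
#' @return Data frame with columns `combination` (miner names joined by
#'   `"&"`, in `universe` order), `n_miners` and `count`, sorted by
#'   decreasing count then combination.
#' @export
#' @examples
#' miner_overlap(list(v1 = "A", v2 = c("A", "B"), v3 = c("B", "A")),
#'               universe = c("A", "B", "C"))
miner_overlap <- function(assign, universe) {
  stopifnot(is.list(assign), length(universe) >= 1L)
  if (anyDuplicated(universe)) stop("duplicate miner in universe",
                                    call. = FALSE)
  keys <- vapply(assign, function(m) {
    m <- unique(m)
    if (!length(m)) stop("empty miner set for a vOTU", call. = FALSE)
    bad <- setdiff(m, universe)
    if (length(bad)) {
      stop("miner(s) outside the declared universe: ",
           paste(sQuote(bad), collapse = ", "), call. = FALSE)
    }
    paste(universe[universe %in% m], collapse = "&")
  }, character(1))
  tab <- table(keys)
  out <- data.frame(combination = names(tab),
                    n_miners = lengths(strsplit(names(tab), "&",
                                                fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$combination, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reads-per-million normalization
#'
#' Scales each sample (column) of a count table so its total is one
#' million: `x_ij * 1e6 / sum_i(x_ij)`. Within-sample proportions are
#' preserved exactly.
#'
#' @param counts Non-negative numeric matrix, vOTUs as rows, samples as
#'   columns; every column sum must be positive.
#' @return Matrix of the same shape with column sums equal to `1e6`.
#' @export
rpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  cs <- colSums(counts)
  if (any(cs == 0)) {
    bad <- colnames(counts)[cs == 0]
    if (is.null(bad)) bad <- which(cs == 0)
    stop("zero-sum sample(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  sweep(counts, 2L, cs, "/") * 1e6
}

# Fisher's log-series alpha: solves S = alpha * ln(1 + N / alpha) by
# bracketed root finding. alpha -> N as a -> Inf, so a finite solution
# needs S < N.
.fisher_alpha <- function(S, N) {
  if (S < 1) stop("fisher alpha needs a non-empty sample", call. = FALSE)
  if (S >= N) {
    stop("fisher alpha undefined when every individual is a distinct ",
         "taxon (S = N)", call. = FALSE)
  }
  f <- function(a) a * log1p(N / a) - S
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  r <- stats::uniroot(f, lower = hi / 2^20, upper = hi,
                      tol = .Machine$double.eps^0.75)
  # polish to tight relative tolerance
  a <- r$root
  for (i in 1:5) {
    g <- log1p(N / a) - (N / a) / (1 + N / a)  # d/da of a*log1p(N/a)
    a <- a - f(a) / g
  }
  a
}

#' Per-sample alpha diversity
#'
#' Within-sample richness/evenness statistics on a vOTU count table:
#' `observed` richness, Shannon entropy (natural log), the Gini-Simpson
#' index `1 - sum(p_i^2)`, bias-corrected Chao1, the abundance-based
#' coverage estimator (ACE, rare-abundance threshold 10), and Fisher's
#' log-series alpha. Shannon and Simpson are computed with
#' [vegan::diversity()], Chao1 and ACE with [vegan::estimateR()];
#' Fisher's alpha is solved directly from `S = alpha * ln(1 + N/alpha)`.
#'
#' @param counts Count matrix, vOTUs as rows, samples as columns.
#'   Chao1, ACE and Fisher require integer counts.
#' @param metric One of `"observed"`, `"shannon"`, `"simpson"`,
#'   `"chao1"`, `"ace"`, `"fisher"`.
#' @return Named numeric vector, one value per sample.
#' @export
#' @examples
#' m <- matrix(c(5, 5, 5, 5), ncol = 1, dimnames = list(NULL, "s1"))
#' alpha_diversity(m, "shannon")  # log(4)
alpha_diversity <- function(counts,
                            metric = c("observed", "shannon", "simpson",
                                       "chao1", "ace", "fisher")) {
  metric <- match.arg(metric)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  comm <- t(counts)  # community matrix: samples as rows
  if (metric %in% c("chao1", "ace", "fisher") &&
      any(counts != round(counts))) {
    stop(sQuote(metric), " requires integer counts", call. = FALSE)
  }
  switch(metric,
    observed = rowSums(comm > 0),
    shannon = vegan::diversity(comm, index = "shannon"),
    simpson = vegan::diversity(comm, index = "simpson"),
    chao1 = {
      est <- vegan::estimateR(comm)
      stats::setNames(est["S.chao1", ], rownames(comm))
    },
    ace = {
      est <- vegan::estimateR(comm)
      stats::setNames(est["S.ACE", ], rownames(comm))
    },
    fisher = {
      vapply(seq_len(nrow(comm)), function(i) {
        x <- comm[i, ]
        .fisher_alpha(sum(x > 0), sum(x))
      }, numeric(1)) |> stats::setNames(rownames(comm))
    })
}

#' Between-sample beta diversity
#'
#' Pairwise sample dissimilarities on a vOTU count table: Bray-Curtis
#' `sum|x_i - y_i| / sum(x_i + y_i)` on abundances, or the classical
#' Jaccard distance `1 - |A n B| / |A u B|` on presence/absence, both
#' computed with [vegan::vegdist()].
#'
#' @param counts Count matrix, vOTUs as rows, samples (at least two) as
#'   columns.
#' @param metric `"bray-curtis"` or `"jaccard"`.
#' @return Symmetric sample-by-sample matrix with zero diagonal and
#'   entries in `[0, 1]`.
#' @export
beta_diversity <- function(counts, metric = c("bray-curtis", "jaccard")) {
  metric <- match.arg(metric)
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least two samples", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  zero <- colSums(counts) == 0
  if (sum(zero) >= 2L) {
    stop("distance undefined between all-zero samples: ",
         paste(sQuote(colnames(counts)[zero]), collapse = ", "),
         call. = FALSE)
  }
  comm <- t(counts)
  d <- if (metric == "bray-curtis") {
    vegan::vegdist(comm, method = "bray")
  } else {
    vegan::vegdist(comm, method = "jaccard", binary = TRUE)
  }
  m <- as.matrix(d)
  diag(m) <- 0
  m
}

#' Per-rank taxonomy summary
#'
#' For each configured rank, the number of distinct taxon names assigned
#' at that rank and the number of vOTUs carrying an assignment there —
#' the "3 families (120 vOTUs)"-style summary of a classification run.
#' Because lineages are truncated by confidence, deeper ranks summarize
#' fewer vOTUs.
#'
#' @param results Output of [classify_all()].
#' @return Data frame with columns `rank`, `n_taxa`, `n_votus`.
#' @export
taxonomy_summary <- function(results) {
  ranks <- attr(results, "ranks")
  if (is.null(ranks)) ranks <- votu_ranks()
  data.frame(
    rank = ranks,
    n_taxa = vapply(ranks, function(r) {
      length(unique(results[[r]][!is.na(results[[r]])]))
    }, integer(1)),
    n_votus = vapply(ranks, function(r) sum(!is.na(results[[r]])),
                     integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
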