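# Natural-log upper tail P(X >= c) for X ~ Hypergeometric(n, b, a):
# shared protein clusters between a profile of size a and one of size b
# drawn from n total PCs. Summed in log space (log-sum-exp over lchoose
# terms) so tiny tails keep full relative precision.
.lhyper_tail <- function(c, a, b, n) {
  if (any(is.na(c(c, a, b, n)))) stop("NA argument", call. = FALSE)
  if (c < 0 || a < 0 || b < 0 || n < 1) {
    stop("counts must be non-negative and n >= 1", call. = FALSE)
  }
  if (a > n || b > n) stop("profile size exceeds total PCs", call. = FALSE)
  if (c > min(a, b)) {
    stop("shared count c = ", c, " exceeds min(a, b) = ", min(a, b),
         call. = FALSE)
  }
  if (c == 0) return(0)
  if (a > b) { tmp <- a; a <- b; b <- tmp }  # symmetric in (a, b): canonicalize
  i <- c:a
  lt <- lchoose(b, i) + lchoose(n - b, a - i) - lchoose(n, a)
  m <- max(lt)
  min(0, m + log(sum(exp(lt - m))))  # clamp rounding above log(1)
}

#' Hypergeometric upper-tail probability of shared protein clusters
#'
#' Probability of observing `c` or more shared protein clusters between
#' two genomes whose PC profiles have sizes `a` and `b`, out of `n`
#' distinct PCs in the data set:
#' \deqn{P(X \ge c) = \sum_{i=c}^{\min(a,b)}
#'   \binom{b}{i}\binom{n-b}{a-i} \big/ \binom{n}{a}.}
#' Computed in log space for numerical stability; this tail is the P
#' value underlying the network's edge weights.
#'
#' @param c Observed shared PC count (`0 <= c <= min(a, b)`).
#' @param a,b Profile sizes (each `<= n`).
#' @param n Total distinct PCs in the data set.
#' @return The tail probability, in `(0, 1]`.
#' @seealso [edge_weight()]
#' @export
#' @examples
#' hypergeom_tail(1, 1, 1, 2) # 0.5
hypergeom_tail <- function(c, a, b, n) {
  exp(.lhyper_tail(c, a, b, n))
}

#' Scoring context for a gene-sharing network
#'
#' @param n_pcs Total distinct protein clusters in the data set.
#' @param n_genomes Total genomes (references plus vOTUs).
#' @return List with `n_pcs`, `n_genomes` and `T`, the total number of
#'   pairwise genome comparisons `M(M-1)/2`.
#' @export
score_context <- function(n_pcs, n_genomes) {
  stopifnot(n_pcs >= 1, n_genomes >= 2)
  list(n_pcs = as.integer(n_pcs), n_genomes = as.integer(n_genomes),
       T = n_genomes * (n_genomes - 1) / 2)
}

#' Gene-sharing significance score (edge weight)
#'
#' The similarity score that weights network edges: the negative base-10
#' logarithm of the hypergeometric tail P value multiplied by the total
#' number of pairwise genome comparisons,
#' \deqn{S = -\log_{10}\!\big(P(X \ge c) \cdot T\big),}
#' floored at 0 when the corrected P value reaches 1. Higher scores mean
#' a larger excess of shared protein clusters than expected by chance.
#'
#' @inheritParams hypergeom_tail
#' @param ctx Scoring context from [score_context()].
#' @return Non-negative score.
#' @export
#' @examples
#' ctx <- score_context(n_pcs = 90, n_genomes = 10)
#' edge_weight(10, 10, 10, ctx)
edge_weight <- function(c, a, b, ctx) {
  stopifnot(is.list(ctx), !is.null(ctx$T), ctx$T >= 1)
  if (ctx$n_pcs < max(a, b)) {
    stop("context n_pcs smaller than a profile", call. = FALSE)
  }
  lp10 <- .lhyper_tail(c, a, b, ctx$n_pcs) / log(10)
  max(0, -(lp10 + log10(ctx$T)))
}

#' Build a gene-sharing network from PC profiles
#'
#' Scores every unordered genome pair sharing at least one protein
#' cluster with [edge_weight()] and keeps pairs at or above `threshold`.
#' The default threshold of 1 keeps pairs whose comparison-corrected P
#' value is at most 0.1.
#'
#' @param profiles Named list mapping genome ids to PC identifier sets
#'   (character vectors; duplicates within a profile collapse).
#' @param threshold Minimum score for an edge (default 1).
#' @return List with `edges` (data frame `source`, `target`, `weight`,
#'   rows sorted by id pair, `source < target`) and `ctx`, the
#'   [score_context()] used.
#' @export
build_network <- function(profiles, threshold = 1) {
  stopifnot(is.list(profiles), length(profiles) >= 2L, threshold >= 0)
  ids <- names(profiles)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("profiles must be a named list", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate genome id(s): ",
         paste(sQuote(unique(ids[duplicated(ids)])), collapse = ", "),
         call. = FALSE)
  }
  ids <- sort(ids, method = "radix")
  profiles <- lapply(profiles[ids], unique)
  pcs <- sort(unique(unlist(profiles, use.names = FALSE)), method = "radix")
  ctx <- score_context(length(pcs), length(profiles))
  # incidence matrix; tcrossprod gives all pairwise shared counts at once
  inc <- matrix(0L, nrow = length(ids), ncol = length(pcs),
                dimnames = list(ids, pcs))
  for (g in seq_along(ids)) inc[g, match(profiles[[g]], pcs)] <- 1L
  shared <- tcrossprod(inc)
  sizes <- lengths(profiles)
  src <- character(0); tgt <- character(0); w <- numeric(0)
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      cc <- shared[i, j]
      if (cc < 1L) next
      s <- edge_weight(cc, sizes[[i]], sizes[[j]], ctx)
      if (s >= threshold) {
        src <- c(src, ids[i]); tgt <- c(tgt, ids[j]); w <- c(w, s)
      }
    }
  }
  list(edges = data.frame(source = src, target = tgt, weight = w,
                          stringsAsFactors = FALSE),
       ctx = ctx)
}
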