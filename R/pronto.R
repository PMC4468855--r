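# GO term-pair association probabilities (PrOnto).
#
# Two hypergeometric measures of how often a pair of BP terms co-occurs:
#   * annotation probability -- co-annotation of single proteins, counted on
#     the DIRECT annotation view restricted to proteins with at least two
#     distinct direct BP terms;
#   * interaction probability -- co-occurrence across the two endpoints of
#     network edges, counted on edges whose endpoints both lie in that same
#     multi-annotated universe.
#
# Dissimilarity uses the lower tail P(X <= k): a small value means the two
# terms co-occur (on proteins, or across interactions) less often than
# expected by chance, i.e. the processes are very rarely performed by a
# single protein or by interacting proteins. The upper tail is exposed for
# similarity queries. Multiple-testing correction is Bonferroni-style:
# e-value = p * number of term pairs evaluated.

check_hyper_counts <- function(N, K, n, k) {
  if (K > N || n > N) stop(sprintf("inconsistent counts: K=%d, n=%d exceed N=%d", K, n, N))
  if (k > min(K, n)) {
    stop(sprintf("inconsistent counts: k=%d exceeds min(K, n)=%d", k, min(K, n)))
  }
  # k below the classical support max(0, K+n-N) is allowed: in the
  # interaction view an edge can contribute to both margins through a
  # single endpoint without forming a cross pair, so the observed k may
  # undershoot the support and the lower tail is then simply 0
  invisible(TRUE)
}

hyper_tails <- function(N, K, n, k) {
  check_hyper_counts(N, K, n, k)
  list(lower = stats::phyper(k, K, N - K, n),
       upper = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

# proteins with >= 2 distinct direct annotations
direct_universe <- function(annotations) {
  names(annotations$direct)[lengths(annotations$direct) >= 2L]
}

#' Annotation co-occurrence probability for a GO term pair
#'
#' Hypergeometric tail probabilities on the protein counts: N = proteins
#' with at least two distinct direct annotations, K = those directly
#' annotated to `go1`, n = those annotated to `go2`, k = those annotated to
#' both. `P(X <= k)` (the `lower` element) is the dissimilarity measure;
#' `upper` gives `P(X >= k)` for similarity.
#'
#' @param go1,go2 Distinct GO term IDs.
#' @param annotations An [annotation_map()].
#' @return List with `lower`, `upper`, `N`, `K`, `n`, `k`.
#' @export
annotation_pvalue <- function(go1, go2, annotations) {
  if (go1 == go2) stop("go1 and go2 must differ")
  u <- annotations$direct[direct_universe(annotations)]
  has1 <- vapply(u, function(t) go1 %in% t, logical(1))
  has2 <- vapply(u, function(t) go2 %in% t, logical(1))
  N <- length(u); K <- sum(has1); n <- sum(has2); k <- sum(has1 & has2)
  c(hyper_tails(N, K, n, k), list(N = N, K = K, n = n, k = k))
}

#' Interaction co-occurrence probability for a GO term pair
#'
#' Hypergeometric tails on edge counts: N = edges between proteins that
#' each have at least two distinct direct annotations; K = such edges with
#' an endpoint directly annotated to `go1`; n = likewise for `go2`; k =
#' edges with one endpoint annotated to `go1` and the other to `go2` (either
#' orientation; an edge whose single endpoint carries both terms does not
#' create a cross pair by itself).
#'
#' @param go1,go2 Distinct GO term IDs.
#' @param network Undirected simple `igraph` graph.
#' @param annotations An [annotation_map()].
#' @return List with `lower`, `upper`, `N`, `K`, `n`, `k`.
#' @export
interaction_pvalue <- function(go1, go2, network, annotations) {
  if (go1 == go2) stop("go1 and go2 must differ")
  u <- direct_universe(annotations)
  el <- igraph::as_edgelist(network)
  el <- el[el[, 1] %in% u & el[, 2] %in% u, , drop = FALSE]
  p1 <- names(annotations$direct)[vapply(annotations$direct, function(t) go1 %in% t, logical(1))]
  p2 <- names(annotations$direct)[vapply(annotations$direct, function(t) go2 %in% t, logical(1))]
  a1 <- el[, 1] %in% p1; b1 <- el[, 2] %in% p1
  a2 <- el[, 1] %in% p2; b2 <- el[, 2] %in% p2
  N <- nrow(el)
  K <- sum(a1 | b1); n <- sum(a2 | b2)
  k <- sum((a1 & b2) | (a2 & b1))
  c(hyper_tails(N, K, n, k), list(N = N, K = K, n = n, k = k))
}

#' Build the PrOnto pair-probability table
#'
#' Evaluates both probabilities for every unordered pair of distinct terms
#' in the universe (by default, all terms assigned to clusters). Pairs for
#' which any margin is zero (K = 0 or n = 0 in either view -- the counts
#' carry no information) are skipped and excluded from the test count.
#' e-values are `p * n_tests`, capped at 1 for reporting; a pair is flagged
#' dissimilar iff both e-values are `<= alpha`.
#'
#' @param annotated An [annotated_clusters()] object supplying the default
#'   term universe, or `NULL` if `terms` is given.
#' @param network Undirected simple `igraph` graph.
#' @param annotations An [annotation_map()].
#' @param terms Optional explicit character vector of terms to pair up.
#' @param alpha e-value significance threshold (default 0.05).
#' @return Data frame of class `pair_table` with columns `go1`, `go2`,
#'   `p_annot`, `e_annot`, `p_inter`, `e_inter`, `dissimilar` plus the
#'   N/K/n/k counts for both views; attributes `n_tests`, `n_skipped`,
#'   `alpha`.
#' @export
build_pair_table <- function(annotated = NULL, network, annotations,
                             terms = NULL, alpha = 0.05) {
  if (is.null(terms)) {
    stopifnot(inherits(annotated, "annotated_clusters"))
    terms <- sort(unique(unlist(annotated$cluster_terms, use.names = FALSE)))
  } else {
    terms <- sort(unique(terms))
  }
  if (length(terms) < 2L) stop("term universe has fewer than 2 terms")

  u <- direct_universe(annotations)
  dset <- annotations$direct[u]
  inc <- vapply(terms, function(t) vapply(dset, function(x) t %in% x, logical(1)),
                logical(length(u)))
  inc <- matrix(inc, nrow = length(u), dimnames = list(u, terms))
  el <- igraph::as_edgelist(network)
  el <- el[el[, 1] %in% u & el[, 2] %in% u, , drop = FALSE]
  ia <- match(el[, 1], u); ib <- match(el[, 2], u)
  N_annot <- length(u)
  N_inter <- nrow(el)

  pairs <- utils::combn(terms, 2)
  rows <- vector("list", ncol(pairs))
  skipped <- 0L
  for (j in seq_len(ncol(pairs))) {
    t1 <- pairs[1, j]; t2 <- pairs[2, j]
    h1 <- inc[, t1]; h2 <- inc[, t2]
    Ka <- sum(h1); na <- sum(h2)
    e1a <- h1[ia]; e1b <- h1[ib]; e2a <- h2[ia]; e2b <- h2[ib]
    Ki <- sum(e1a | e1b); ni <- sum(e2a | e2b)
    if (Ka == 0L || na == 0L || Ki == 0L || ni == 0L) {
      skipped <- skipped + 1L
      next
    }
    ka <- sum(h1 & h2)
    ki <- sum((e1a & e2b) | (e2a & e1b))
    rows[[j]] <- data.frame(
      go1 = t1, go2 = t2,
      p_annot = stats::phyper(ka, Ka, N_annot - Ka, na),
      p_inter = stats::phyper(ki, Ki, N_inter - Ki, ni),
      N_annot = N_annot, K_annot = Ka, n_annot = na, k_annot = ka,
      N_inter = N_inter, K_inter = Ki, n_inter = ni, k_inter = ki,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no evaluable term pairs (all margins zero)")
  pt <- do.call(rbind, rows)
  n_tests <- nrow(pt)
  if (skipped) message(sprintf("build_pair_table: skipped %d pair(s) with a zero margin", skipped))
  pt$e_annot <- pmin(1, pt$p_annot * n_tests)
  pt$e_inter <- pmin(1, pt$p_inter * n_tests)
  pt$dissimilar <- pt$e_annot <= alpha & pt$e_inter <= alpha
  pt <- pt[order(pt$go1, pt$go2), , drop = FALSE]
  rownames(pt) <- NULL
  structure(pt, n_tests = n_tests, n_skipped = skipped, alpha = alpha,
            class = c("pair_table", "data.frame"))
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("<pair_table> %d term pairs tested (%d skipped), %d dissimilar at alpha = %g\n",
              attr(x, "n_tests"), attr(x, "n_skipped"), sum(x$dissimilar),
              attr(x, "alpha")))
  NextMethod()
}
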