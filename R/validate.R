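# Randomization controls, leave-one-out annotation recovery and known-set
# enrichment.
#
# The four null schemes mirror the quality controls of the detection
# pipeline: shuffling annotations across proteins, uniform edge
# resampling, degree-preserving rewiring, and reshuffling the pair
# probabilities across term pairs. Each conserves its stated invariant
# exactly (annotation-set multiset, node/edge counts, degree sequence,
# probability-tuple multiset) and is deterministic given a seed.

#' Shuffle annotations across proteins
#'
#' Permutes the per-protein direct-annotation SETS across proteins (the
#' multiset of sets is conserved, so the per-protein annotation-richness
#' distribution is preserved) and recomputes propagation.
#'
#' @param annotations An [annotation_map()].
#' @param dag The [go_dag()] used for propagation.
#' @param seed Integer seed; the same seed reproduces the permutation.
#' @return A new [annotation_map()].
#' @export
shuffle_annotations <- function(annotations, dag, seed) {
  prots <- names(annotations$direct)
  perm <- with_seed(seed, sample(length(prots)))
  direct <- stats::setNames(annotations$direct[perm], prots)
  propagated <- lapply(direct, function(ts) {
    setdiff(sort(unique(c(ts, unlist(dag$ancestors[ts], use.names = FALSE)))), dag$root)
  })
  structure(list(direct = direct, propagated = propagated, root = dag$root),
            class = "annotation_map")
}

#' Randomize network topology
#'
#' `uniform` draws a fresh Erdos-Renyi G(n, m) graph on the same node set
#' with the same edge count (simple by construction); `degree_preserving`
#' applies double-edge swaps (`swaps_per_edge * m` attempts, rejecting
#' self-loops and multi-edges), conserving the degree sequence exactly.
#'
#' @param network Undirected simple `igraph` graph.
#' @param mode `"uniform"` or `"degree_preserving"`.
#' @param seed Integer seed.
#' @param swaps_per_edge Attempted swaps per edge for degree-preserving
#'   rewiring (default 10, a standard mixing heuristic).
#' @return A randomized `igraph` graph on the same vertex names.
#' @export
randomize_edges <- function(network, mode = c("uniform", "degree_preserving"),
                            seed, swaps_per_edge = 10) {
  mode <- match.arg(mode)
  with_seed(seed, {
    if (mode == "uniform") {
      g <- igraph::sample_gnm(igraph::vcount(network), igraph::ecount(network))
      igraph::V(g)$name <- igraph::V(network)$name
      g
    } else {
      igraph::rewire(network,
                     igraph::keeping_degseq(loops = FALSE,
                                            niter = swaps_per_edge * igraph::ecount(network)))
    }
  })
}

#' Reshuffle pair probabilities across term pairs
#'
#' Permutes the per-pair value tuples (both p-values and their counts)
#' across the term-pair keys and recomputes e-values and the dissimilarity
#' flag under the table's own `n_tests` and `alpha`.
#'
#' @param pair_table A [build_pair_table()] result.
#' @param seed Integer seed.
#' @return A `pair_table` with permuted values.
#' @export
shuffle_pair_probabilities <- function(pair_table, seed) {
  n_tests <- attr(pair_table, "n_tests")
  alpha <- attr(pair_table, "alpha")
  perm <- with_seed(seed, sample(nrow(pair_table)))
  keys <- pair_table[, c("go1", "go2")]
  vals <- pair_table[perm, setdiff(names(pair_table), c("go1", "go2")), drop = FALSE]
  pt <- cbind(keys, vals)
  pt$e_annot <- pmin(1, pt$p_annot * n_tests)
  pt$e_inter <- pmin(1, pt$p_inter * n_tests)
  pt$dissimilar <- pt$e_annot <= alpha & pt$e_inter <= alpha
  rownames(pt) <- NULL
  structure(pt, n_tests = n_tests, n_skipped = attr(pair_table, "n_skipped"),
            alpha = alpha, class = c("pair_table", "data.frame"))
}

#' Leave-one-out annotation recovery
#'
#' For every (cluster, member) case where the member has at least one
#' propagated BP term: drop that protein's annotations, re-annotate the
#' cluster by the majority rule, and count a success iff at least one of
#' the held-out propagated terms appears among the inferred cluster terms
#' or their ancestors (the ancestor closure of an inferred term counts as a
#' match, the root excluded).
#'
#' @param system A [cluster_system()].
#' @param annotations An [annotation_map()].
#' @param dag A [go_dag()].
#' @param threshold Majority threshold (default 0.5).
#' @return Fraction of successful cases in \[0, 1\], with attributes
#'   `cases` and `successes`.
#' @export
leave_one_out_recovery <- function(system, annotations, dag, threshold = 0.5) {
  prop <- annotations$propagated
  cases <- 0L; successes <- 0L
  for (members in system$clusters) {
    held <- intersect(members, names(prop))
    held <- held[lengths(prop[held]) > 0]
    for (p in held) {
      cases <- cases + 1L
      masked <- prop
      masked[[p]] <- character(0)
      inferred <- annotate_one_cluster(members, masked, dag, threshold)
      if (!length(inferred)) next
      closure <- setdiff(unique(c(inferred,
                                  unlist(dag$ancestors[inferred], use.names = FALSE))),
                         dag$root)
      if (length(intersect(prop[[p]], closure))) successes <- successes + 1L
    }
  }
  if (cases == 0L) stop("no evaluable leave-one-out case")
  structure(successes / cases, cases = cases, successes = successes)
}

#' Hypergeometric enrichment of a known gene set among candidates
#'
#' Fold enrichment `k / (|known| * |candidates| / |universe|)`, the
#' one-sided upper-tail hypergeometric probability `P(X >= k)` of drawing
#' at least `k` known genes when sampling `|known|` from the universe with
#' `|candidates|` marked, and the point probability `P(X = k)` of the
#' observed overlap.
#'
#' @param candidates Character vector of candidate IDs (subset of
#'   `universe`).
#' @param known Character vector of known IDs (subset of `universe`).
#' @param universe Character vector, the full ID universe.
#' @return List with `fold`, `p`, `p_point`, `k`, `expected`, `N`, `K`,
#'   `n`.
#' @export
known_set_enrichment <- function(candidates, known, universe) {
  universe <- unique(universe)
  known <- unique(known)
  candidates <- unique(candidates)
  if (!length(universe)) stop("empty universe")
  if (!length(known)) stop("empty known set")
  if (!all(known %in% universe)) stop("known set is not a subset of the universe")
  if (!all(candidates %in% universe)) stop("candidate set is not a subset of the universe")
  N <- length(universe); K <- length(candidates); n <- length(known)
  k <- length(intersect(candidates, known))
  expected <- K * n / N
  fold <- if (k == 0L) 0 else k / expected
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_point <- stats::dhyper(k, K, N - K, n)
  list(fold = fold, p = p, p_point = p_point, k = k, expected = expected,
       N = N, K = K, n = n)
}
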