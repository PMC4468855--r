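# Overlapping cluster generation (OCG re-implementation).
#
# The algorithm covers the network with a system of possibly overlapping
# clusters: an initial class system of centered cliques is greedily merged,
# at each step taking the eligible cluster pair whose union most increases
# an overlap-aware modularity, until no merge gives a strictly positive
# gain. This re-implementation pins the following contract (the package's
# own definition, fully deterministic, no randomness):
#
#   * initial system: one clique grown around each vertex (see
#     build_centered_cliques), deduplicated, subsets removed;
#   * modularity: classical Newman pair-sum restricted to node pairs that
#     share at least one cluster, each pair counted once however many
#     clusters it shares (diagonal terms included, so a single whole-graph
#     cluster scores exactly 0);
#   * eligible merges: cluster pairs sharing >= 1 node or joined by >= 1
#     edge (a merge across components can never have positive gain, so
#     components are effectively clustered independently);
#   * ties broken by the lexicographically smallest pair of cluster
#     fingerprints (the space-joined sorted member list).
#
# Complexity is quadratic in the number of clusters with dense per-node
# bookkeeping; it targets module-scale graphs (up to a few thousand nodes),
# not the full interactome in a tight loop.

#' Initial class system of centered cliques
#'
#' For each vertex `v` (in lexicographic order) a clique seeded at `v` is
#' grown by repeatedly adding the neighbour of `v` adjacent to all current
#' members, preferring highest degree and breaking ties by lexicographic
#' ID. Identical cliques are deduplicated and cliques contained in another
#' are removed. Isolated vertices yield singleton clusters.
#'
#' @param network Undirected simple `igraph` graph with vertex names.
#' @return A [cluster_system()] covering every vertex.
#' @export
build_centered_cliques <- function(network) {
  nodes <- sort(igraph::V(network)$name)
  if (!length(nodes)) stop("empty graph")
  nb <- lapply(igraph::adjacent_vertices(network, nodes), function(v) v$name)
  names(nb) <- nodes
  deg <- stats::setNames(igraph::degree(network)[nodes], nodes)
  cliques <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    members <- v
    cand <- nb[[v]]
    while (length(cand)) {
      ok <- cand[vapply(cand, function(u) all(members %in% c(nb[[u]], u)), logical(1))]
      if (!length(ok)) break
      pick <- ok[order(-deg[ok], ok)][1L]
      members <- c(members, pick)
      cand <- setdiff(cand, pick)
    }
    cliques[[i]] <- sort(members)
  }
  cliques <- drop_subset_clusters(unique(cliques))
  cluster_system(cliques, universe = nodes)
}

#' Overlap-aware modularity of a cluster system
#'
#' Q = (1/2m) * sum over ordered node pairs (u, v) sharing at least one
#' cluster (u = v included) of A_uv - d_u d_v / (2m). Each pair contributes
#' once regardless of how many clusters it shares; for a partition this
#' reduces to classical Newman modularity, and a single cluster holding the
#' whole graph scores exactly 0.
#'
#' @param network Undirected simple `igraph` graph.
#' @param system A [cluster_system()] covering the network.
#' @return Dimensionless modularity score.
#' @export
overlap_modularity <- function(network, system) {
  m <- igraph::ecount(network)
  if (m == 0) stop("modularity undefined: network has no edges")
  nodes <- igraph::V(network)$name
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  deg <- igraph::degree(network)  # igraph vertex order == idx order
  el <- igraph::as_edgelist(network)
  ei <- idx[el[, 1]]; ej <- idx[el[, 2]]
  ekey <- (pmin(ei, ej) - 1) * n + pmax(ei, ej)
  keys <- covered_pair_keys(system, idx, n)
  i <- (keys - 1) %/% n + 1
  j <- keys - (i - 1) * n
  w <- ifelse(i == j, 1, 2)  # ordered-pair weight for unordered storage
  a <- as.numeric(keys %in% ekey)
  sum(w * (a - deg[i] * deg[j] / (2 * m))) / (2 * m)
}

# unique encoded (i <= j) node pairs covered by >= 1 cluster, diagonal included
covered_pair_keys <- function(system, idx, n) {
  keys <- lapply(system$clusters, function(cl) {
    ii <- sort(idx[cl])
    k <- length(ii)
    pr <- cbind(rep(ii, times = k), rep(ii, each = k))
    pr <- pr[pr[, 1] <= pr[, 2], , drop = FALSE]
    (pr[, 1] - 1) * n + pr[, 2]
  })
  unique(unlist(keys, use.names = FALSE))
}

#' Cover a network with overlapping clusters (OCG)
#'
#' Starts from [build_centered_cliques()] and repeatedly merges the
#' eligible cluster pair with the maximal strictly positive modularity
#' gain; stops when no such merge exists (or an optional limit is hit),
#' then enforces the no-subset invariant.
#'
#' @param network Undirected simple `igraph` graph with vertex names.
#' @param max_cluster_size Optional cap: merges producing a larger cluster
#'   are not considered.
#' @param min_final_clusters Optional floor: merging stops once the system
#'   has this many clusters.
#' @return A [cluster_system()]; attribute `merges` records each accepted
#'   merge's modularity gain (non-negative by construction, strictly
#'   positive for every accepted step).
#' @export
ocg_cluster <- function(network, max_cluster_size = NULL, min_final_clusters = NULL) {
  if (igraph::vcount(network) == 0) stop("empty graph")
  system <- build_centered_cliques(network)
  clusters <- system$clusters
  nodes <- system$universe
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  deg <- stats::setNames(igraph::degree(network)[nodes], nodes)
  m <- igraph::ecount(network)
  gains <- numeric(0)

  if (m > 0 && length(clusters) > 1) {
    A <- matrix(FALSE, n, n)
    el <- igraph::as_edgelist(network)
    A[cbind(idx[el[, 1]], idx[el[, 2]])] <- TRUE
    A[cbind(idx[el[, 2]], idx[el[, 1]])] <- TRUE
    # number of clusters covering each node pair
    share <- matrix(0L, n, n)
    for (cl in clusters) {
      ii <- idx[cl]
      share[ii, ii] <- share[ii, ii] + 1L
    }
    null_term <- outer(deg, deg) / (2 * m)  # indexed like A

    merge_gain <- function(ca, cb) {
      ia <- setdiff(idx[ca], idx[cb])
      ib <- setdiff(idx[cb], idx[ca])
      if (!length(ia) || !length(ib)) return(0)  # one contains the other
      new <- share[ia, ib, drop = FALSE] == 0L
      if (!any(new)) return(0)
      sum((A[ia, ib, drop = FALSE][new] - null_term[ia, ib, drop = FALSE][new])) * 2 / (2 * m)
    }
    eligible <- function(ca, cb) {
      if (length(intersect(ca, cb))) return(TRUE)
      any(A[idx[ca], idx[cb], drop = FALSE])
    }

    repeat {
      if (!is.null(min_final_clusters) && length(clusters) <= min_final_clusters) break
      if (length(clusters) < 2) break
      best <- NULL; best_gain <- 0; best_fp <- NULL
      fps <- vapply(clusters, paste, character(1), collapse = " ")
      for (p in seq_len(length(clusters) - 1L)) {
        for (q in (p + 1L):length(clusters)) {
          ca <- clusters[[p]]; cb <- clusters[[q]]
          if (!is.null(max_cluster_size) &&
              length(union(ca, cb)) > max_cluster_size) next
          if (!eligible(ca, cb)) next
          g <- merge_gain(ca, cb)
          if (g <= 0) next
          fp <- sort(c(fps[p], fps[q]))
          if (is.null(best) || g > best_gain + 1e-12 ||
              (abs(g - best_gain) <= 1e-12 &&
               (fp[1] < best_fp[1] || (fp[1] == best_fp[1] && fp[2] < best_fp[2])))) {
            best <- c(p, q); best_gain <- g; best_fp <- fp
          }
        }
      }
      if (is.null(best)) break
      ca <- clusters[[best[1]]]; cb <- clusters[[best[2]]]
      ia <- setdiff(idx[ca], idx[cb]); ib <- setdiff(idx[cb], idx[ca])
      share[ia, ib] <- share[ia, ib] + 1L
      share[ib, ia] <- share[ib, ia] + 1L
      merged <- sort(union(ca, cb))
      clusters <- c(clusters[-best], list(merged))
      gains <- c(gains, best_gain)
    }
  }
  clusters <- drop_subset_clusters(clusters)
  out <- cluster_system(unname(clusters), universe = nodes)
  attr(out, "merges") <- gains
  out
}
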