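# Topological characterization of candidate groups.
#
# Group conventions: Multi / Mono partition the network's proteins by
# cluster-membership count; Cands is a subset of Multi; Multi-NC = Multi
# minus Cands; NC = everything but Cands; Hubs = nodes whose degree reaches
# the hub threshold (twice the mean degree by default). Betweenness follows
# the Brandes contract for undirected graphs: unordered source-target
# pairs, endpoints excluded, shortest-path-count weighted, unnormalized.

#' Assign proteins to comparison groups
#'
#' @param network Undirected simple `igraph` graph.
#' @param system A [cluster_system()] on the same proteins.
#' @param candidates Character vector of candidate IDs (must be network
#'   nodes).
#' @param hub_threshold Absolute degree threshold for hubs; default
#'   `ceiling(2 * mean(degree))`.
#' @return Object of class `protein_groups`: a named list of ID vectors
#'   (`all`, `cands`, `multi`, `mono`, `multi_nc`, `nc`, `hubs`) with
#'   attribute `hub_threshold`.
#' @export
assign_groups <- function(network, system, candidates, hub_threshold = NULL) {
  nodes <- sort(igraph::V(network)$name)
  deg <- stats::setNames(igraph::degree(network)[nodes], nodes)
  if (!all(candidates %in% nodes)) {
    stop("candidates outside the network: ",
         paste(utils::head(setdiff(candidates, nodes), 3), collapse = ", "))
  }
  if (is.null(hub_threshold)) hub_threshold <- ceiling(2 * mean(deg))
  multi <- intersect(nodes, names(find_multiclustered(system)))
  groups <- list(
    all = nodes,
    cands = sort(unique(candidates)),
    multi = multi,
    mono = setdiff(nodes, multi),
    multi_nc = setdiff(multi, candidates),
    nc = setdiff(nodes, candidates),
    hubs = names(deg)[deg >= hub_threshold])
  structure(groups, hub_threshold = hub_threshold, class = "protein_groups")
}

#' Per-protein topology features
#'
#' Degree, unnormalized betweenness and cluster-membership count; when an
#' annotation map is supplied, the number of propagated BP annotations is
#' added. External per-protein columns (disorder, domains, conservation,
#' expression breadth ...) can be merged with [add_feature_columns()]; this
#' package never computes them.
#'
#' @param network Undirected simple `igraph` graph.
#' @param system Optional [cluster_system()] for membership counts.
#' @param annotations Optional [annotation_map()].
#' @return Data frame keyed by `protein` with numeric feature columns.
#' @export
topology_features <- function(network, system = NULL, annotations = NULL) {
  nodes <- sort(igraph::V(network)$name)
  deg <- igraph::degree(network)[nodes]
  btw <- igraph::betweenness(network, directed = FALSE, normalized = FALSE)[nodes]
  out <- data.frame(protein = nodes, degree = as.numeric(deg),
                    betweenness = as.numeric(btw),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(system)) {
    mc <- membership_counts(system)
    out$n_clusters <- as.numeric(mc[match(out$protein, names(mc))])
    out$n_clusters[is.na(out$n_clusters)] <- 0
  }
  if (!is.null(annotations)) {
    out$n_bp_annotations <- vapply(out$protein, function(p)
      length(annotations$propagated[[p]] %||% character(0)), numeric(1))
  }
  out
}

#' Merge user-supplied feature columns
#'
#' @param features A [topology_features()] data frame.
#' @param table A data frame (or TSV path) with a `protein` column and
#'   numeric feature columns to merge; proteins missing from `table` get
#'   `NA`.
#' @return The merged data frame.
#' @export
add_feature_columns <- function(features, table) {
  if (is.character(table)) {
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  }
  if (!"protein" %in% names(table)) stop("feature table needs a 'protein' column")
  merge(features, table, by = "protein", all.x = TRUE, sort = TRUE)
}

#' Mean shortest-path length within or between groups
#'
#' Mean geodesic distance over unordered reachable pairs of distinct
#' proteins; unreachable pairs are excluded from the mean and counted.
#'
#' @param network Undirected simple `igraph` graph.
#' @param group_a Character vector of proteins.
#' @param group_b Optional second group; omitted means within-`group_a`
#'   pairs.
#' @return List with `mean`, `n_pairs`, `n_unreachable`.
#' @export
group_shortest_paths <- function(network, group_a, group_b = NULL) {
  stopifnot(length(group_a) > 0)
  within <- is.null(group_b)
  group_b <- group_b %||% group_a
  stopifnot(length(group_b) > 0)
  d <- igraph::distances(network, v = group_a, to = group_b)
  if (within) {
    vals <- d[upper.tri(d)]
  } else {
    pairs <- expand.grid(a = group_a, b = group_b, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    dup <- duplicated(pair_key(pairs$a, pairs$b))
    pairs <- pairs[!dup, , drop = FALSE]
    vals <- d[cbind(match(pairs$a, group_a), match(pairs$b, group_b))]
  }
  reach <- is.finite(vals)
  if (!any(reach)) stop("all pairs unreachable")
  list(mean = mean(vals[reach]), n_pairs = sum(reach),
       n_unreachable = sum(!reach))
}

#' Compare a feature between two groups (Wilcoxon rank-sum)
#'
#' Two-sided Mann-Whitney/Wilcoxon test (exact for small tie-free samples,
#' normal approximation with tie correction otherwise, as in
#' [stats::wilcox.test()]); raw p-values, no multiplicity correction.
#'
#' @param features A feature data frame with a `protein` column.
#' @param feature Feature column name.
#' @param group_a,group_b Character vectors of proteins.
#' @return List with `mean_a`, `mean_b`, `p`, `statistic`.
#' @export
compare_groups <- function(features, feature, group_a, group_b) {
  stopifnot(feature %in% names(features))
  x <- features[[feature]][match(group_a, features$protein)]
  y <- features[[feature]][match(group_b, features$protein)]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty group after matching features")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(mean_a = mean(x), mean_b = mean(y), p = wt$p.value,
       statistic = unname(wt$statistic))
}

#' Gene-list enrichment per protein group
#'
#' Applies [known_set_enrichment()] to each group against a user-supplied
#' gene list (OMIM, cancer genes, switch-motif proteins, ...). Folds below
#' 1 indicate depletion.
#'
#' @param groups A [assign_groups()] result (or any named list of ID
#'   vectors).
#' @param gene_list Character vector of IDs (subset of `universe`).
#' @param universe Character vector, the protein universe.
#' @return Data frame with columns `group`, `size`, `k`, `fold`, `p`.
#' @export
list_enrichment <- function(groups, gene_list, universe) {
  rows <- lapply(names(groups), function(g) {
    enr <- known_set_enrichment(groups[[g]], gene_list, universe)
    data.frame(group = g, size = enr$K, k = enr$k, fold = enr$fold, p = enr$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
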