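# Shared toy fixtures, all built in code.

graph_from_pairs <- function(...) {
  el <- do.call(rbind, strsplit(c(...), "-", fixed = TRUE))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# two triangles joined at c
bowtie_graph <- function() {
  graph_from_pairs("a-b", "a-c", "b-c", "c-d", "c-e", "d-e")
}

# root T1 <- T2 <- T3
chain_dag <- function() go_dag(list(T2 = "T1", T3 = "T2"))

# diamond: T4 -> {T2, T3} -> T1 (root)
diamond_dag <- function() go_dag(list(T2 = "T1", T3 = "T1", T4 = c("T2", "T3")))

# independent ancestor closure: BFS over the parent lists
bfs_ancestors <- function(parents, term) {
  seen <- character(0)
  frontier <- parents[[term]] %||% character(0)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)), seen)
  }
  sort(seen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random parent-list DAG: term i may have parents among terms 1..(i-1)
random_dag_parents <- function(n_terms, p_edge = 0.4) {
  ids <- sprintf("T%02d", seq_len(n_terms))
  parents <- list()
  for (i in 2:n_terms) {
    cand <- ids[seq_len(i - 1)]
    pick <- cand[stats::runif(length(cand)) < p_edge]
    if (!length(pick)) pick <- ids[1]
    parents[[ids[i]]] <- pick
  }
  parents
}

# independent lower/upper hypergeometric oracle by enumeration of all
# n-subsets of an N-universe with K marked elements
enum_hyper <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  marked <- colSums(subsets <= K)  # elements 1..K are the marked ones
  list(lower = mean(marked <= k), upper = mean(marked >= k))
}

# write lines to a temp file, returning its path
tmpfile_with <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
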