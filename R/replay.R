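# Replay of a deposited analysis: given the published interactome edge
# list, annotated class file and dissimilar GO-pair list as local files,
# recompute the headline counts (node/edge counts, cluster statistics,
# multiclustered proteins, candidates) without re-running clustering or the
# probability calculations. The deposited files themselves are not shipped
# with the package; convert them to the formats below and point `dir` at
# them.

#' Replay headline counts from deposited pipeline artifacts
#'
#' Expects in `dir`:
#' \describe{
#'   \item{`interactome.tsv`}{two-column edge list ([read_network()] TSV
#'     dialect).}
#'   \item{`classes.tsv`}{annotated class file ([read_class_file()]
#'     dialect: membership lines plus GO annotation lines).}
#'   \item{`go_pairs.tsv`}{the dissimilar GO term pairs, two tab-separated
#'     term columns per line (`#` comments allowed).}
#' }
#' Candidates are re-derived by applying the detection rule to the class
#' file and the pair list (listed pairs are taken as significant at any
#' alpha, i.e. their e-values are treated as 0).
#'
#' @param dir Directory holding the three files.
#' @return Named list of counts: `n_nodes`, `n_edges`, `n_clusters`,
#'   `mean_cluster_size`, `n_multiclustered`, `n_annotated_clusters`,
#'   `n_dissimilar_pairs`, `n_candidates`, `candidates`.
#' @export
replay_deposited <- function(dir) {
  paths <- file.path(dir, c("interactome.tsv", "classes.tsv", "go_pairs.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("deposited file(s) not found: ", paste(missing, collapse = ", "))
  }
  g <- read_network(paths[1L])
  annotated <- read_class_file(paths[2L])
  lines <- readLines(paths[3L], warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) stop("malformed GO-pair line ", bad[1L])
  pairs <- data.frame(go1 = vapply(fields, `[[`, character(1), 1L),
                      go2 = vapply(fields, `[[`, character(1), 2L),
                      stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(pair_key(pairs$go1, pairs$go2)), , drop = FALSE]
  pt <- data.frame(go1 = pairs$go1, go2 = pairs$go2,
                   e_annot = 0, e_inter = 0, stringsAsFactors = FALSE)
  ev <- find_emf_candidates(annotated, pt, alpha = 0.05)
  sizes <- lengths(annotated$system$clusters)
  list(n_nodes = igraph::vcount(g),
       n_edges = igraph::ecount(g),
       n_clusters = length(sizes),
       mean_cluster_size = mean(sizes),
       n_multiclustered = length(find_multiclustered(annotated$system)),
       n_annotated_clusters = sum(lengths(annotated$cluster_terms) > 0),
       n_dissimilar_pairs = nrow(pt),
       n_candidates = length(emf_candidates(ev)),
       candidates = emf_candidates(ev))
}
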