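# Network input/output.
#
# The interactome is held as an undirected simple igraph object with protein
# identifiers as vertex names. IDs are opaque, case-sensitive strings: no
# UniProt mapping or isoform collapsing is attempted here (identifier
# resolution is expected to have happened upstream of the edge list).

#' Read a protein-protein interaction network
#'
#' Parses an undirected PPI network from a two-column edge list or a
#' PSI-MITAB 2.5 file. Self-interactions and duplicate edges are dropped
#' (with a reported count), matching the convention that only simple binary
#' interactions are kept. The node set is the union of all edge endpoints,
#' including proteins that only appeared in discarded self-loops.
#'
#' @param path Path to the network file.
#' @param format `"tsv"` for a whitespace/tab separated two-column edge list
#'   (`#` comment lines allowed), or `"mitab"` for PSI-MITAB 2.5, in which
#'   case the primary identifiers in columns 1-2 are used and a leading
#'   `uniprotkb:` prefix is stripped.
#' @return An undirected simple `igraph` graph with vertex names; graph
#'   attributes `dropped_self` and `dropped_dup` record how many lines were
#'   discarded.
#' @examples
#' f <- tempfile()
#' writeLines(c("A B", "B A", "C C"), f)
#' g <- read_network(f)
#' igraph::vcount(g)  # 3 nodes, 1 edge
#' @export
read_network <- function(path, format = c("tsv", "mitab")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty edge list: ", path)
  if (format == "tsv") {
    fields <- strsplit(trimws(lines), "\\s+")
    bad <- which(lengths(fields) != 2L)
    if (length(bad)) {
      stop(sprintf("malformed edge line %d in %s: expected 2 columns, found %d",
                   lineno[bad[1L]], path, length(fields[[bad[1L]]])))
    }
    a <- vapply(fields, `[[`, character(1), 1L)
    b <- vapply(fields, `[[`, character(1), 2L)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 2L)
    if (length(bad)) {
      stop(sprintf("malformed MITAB line %d in %s: fewer than 2 columns",
                   lineno[bad[1L]], path))
    }
    a <- sub("^uniprotkb:", "", vapply(fields, `[[`, character(1), 1L))
    b <- sub("^uniprotkb:", "", vapply(fields, `[[`, character(1), 2L))
  }
  make_network(a, b)
}

# Build a simple undirected graph from endpoint vectors, dropping self-loops
# and duplicate (unordered) edges with a logged count.
make_network <- function(a, b) {
  stopifnot(length(a) == length(b))
  nodes <- sort(unique(c(a, b)))
  self <- a == b
  a2 <- a[!self]
  b2 <- b[!self]
  dup <- duplicated(pair_key(a2, b2))
  if (any(self) || any(dup)) {
    message(sprintf("read_network: dropped %d self-loop(s) and %d duplicate edge(s)",
                    sum(self), sum(dup)))
  }
  edf <- data.frame(from = a2[!dup], to = b2[!dup], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = nodes)
  g$dropped_self <- sum(self)
  g$dropped_dup <- sum(dup)
  g
}

#' Write a network as a two-column edge list
#'
#' Edges are written with the lexicographically smaller endpoint first and
#' sorted, so identical graphs always produce byte-identical files and
#' `read_network(write_network(g))` round-trips node and edge sets exactly.
#' Isolated vertices are written as comment lines so the node set survives
#' the round trip.
#'
#' @param network An undirected `igraph` graph with vertex names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network)
  iso <- setdiff(igraph::V(network)$name, unique(c(el[, 1], el[, 2])))
  lines <- character(0)
  if (nrow(el) > 0) {
    a <- pmin(el[, 1], el[, 2])
    b <- pmax(el[, 1], el[, 2])
    o <- order(a, b)
    lines <- paste(a[o], b[o], sep = "\t")
  }
  if (length(iso)) {
    # self-referential lines would be dropped as self-loops on re-read but
    # still contribute the node, preserving isolated vertices
    lines <- c(lines, paste(sort(iso), sort(iso), sep = "\t"))
  }
  if (!length(lines)) stop("refusing to write an empty edge list")
  write_tsv_lines(lines, path)
}

#' Read a plain-text gene list
#'
#' One identifier per line, `#` comments and blank lines ignored; duplicates
#' are removed keeping first occurrence.
#'
#' @param path File path.
#' @param label Free-text label attached to the list (e.g. "known MPs").
#' @return Character vector of IDs with attribute `label`.
#' @export
read_gene_list <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  ids <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ids <- ids[!duplicated(ids)]
  structure(ids, label = label)
}
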