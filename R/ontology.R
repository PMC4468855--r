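# Gene Ontology DAG and protein annotations (biological_process namespace).
#
# The DAG keeps is_a and part_of edges only (the GO "true-path" relations);
# regulates-type relations are not propagated. Ancestor closures are
# precomputed in topological order at construction time, which also serves
# as the acyclicity check.

#' Construct a GO DAG from a parent list
#'
#' Low-level constructor used both by [read_obo()] and by the synthetic
#' fixture generator. Terms are the union of names and parent references;
#' the root is the unique term without parents.
#'
#' @param parents Named list: term ID -> character vector of parent term IDs
#'   (`is_a`/`part_of`). Terms appearing only as parents are added with no
#'   parents of their own.
#' @param namespace Namespace label stored on the object.
#' @return Object of class `go_dag` with fields `terms`, `parents`,
#'   `ancestors` (transitive closure, self excluded), `root`, `namespace`.
#' @export
go_dag <- function(parents, namespace = "biological_process") {
  if (length(parents) && is.null(names(parents))) stop("`parents` must be a named list")
  terms <- sort(unique(c(names(parents), unlist(parents, use.names = FALSE))))
  full <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) full[[t]] <- unique(as.character(parents[[t]] %||% character(0)))
  # Kahn-style topological pass: process a term once all its parents are done.
  anc <- stats::setNames(vector("list", length(terms)), terms)
  done <- stats::setNames(logical(length(terms)), terms)
  pending <- terms
  while (length(pending)) {
    ready <- pending[vapply(pending, function(t) all(done[full[[t]]]), logical(1))]
    if (!length(ready)) {
      stop("cycle detected in ontology involving term ", pending[1L])
    }
    for (t in ready) {
      anc[[t]] <- sort(unique(c(full[[t]], unlist(anc[full[[t]]], use.names = FALSE))))
      done[t] <- TRUE
    }
    pending <- setdiff(pending, ready)
  }
  roots <- terms[lengths(full) == 0L]
  root <- if (length(roots) == 1L) {
    roots
  } else if ("GO:0008150" %in% roots) {
    warning(sprintf("%d parentless terms; using GO:0008150 as root", length(roots)))
    "GO:0008150"
  } else {
    stop("ontology has ", length(roots), " parentless terms; cannot identify a unique root")
  }
  structure(list(terms = terms, parents = full, ancestors = anc,
                 root = root, namespace = namespace),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d %s terms, root %s\n",
              length(x$terms), x$namespace, x$root))
  invisible(x)
}

#' Ancestors of a term
#'
#' All terms reachable from `term` through is_a/part_of links, the term
#' itself excluded.
#'
#' @param dag A `go_dag`.
#' @param term Term ID.
#' @return Character vector of ancestor IDs.
#' @export
go_ancestors <- function(dag, term) {
  if (!term %in% dag$terms) stop("unknown term: ", term)
  dag$ancestors[[term]]
}

#' Parse an OBO 1.2 ontology, keeping one namespace
#'
#' Reads `[Term]` stanzas (`id`, `namespace`, `is_a`, `relationship:
#' part_of`, `is_obsolete`), drops obsolete terms, restricts to the
#' requested namespace and builds the ancestor closure. Parent references
#' that point to a different namespace or to an obsolete term are dropped
#' silently (cross-namespace part_of links are common in real GO releases);
#' a reference to an ID absent from the file altogether is an error.
#'
#' @param path OBO file path.
#' @param namespace Namespace to keep (default `biological_process`).
#' @return A [go_dag()] object.
#' @export
read_obo <- function(path, namespace = "biological_process") {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  default_ns <- sub("^default-namespace:\\s*", "",
                    grep("^default-namespace:", lines, value = TRUE)[1])
  if (is.na(default_ns)) default_ns <- namespace

  stanza_starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) stop("no [Term] stanzas in ", path)
  ends <- vapply(term_starts, function(s) {
    nxt <- stanza_starts[stanza_starts > s]
    if (length(nxt)) nxt[1L] - 1L else length(lines)
  }, integer(1))

  ids <- character(0); ns <- character(0); obs <- logical(0)
  plist <- list()
  for (i in seq_along(term_starts)) {
    block <- lines[term_starts[i]:ends[i]]
    id <- sub("^id:\\s*", "", grep("^id:", block, value = TRUE)[1])
    if (is.na(id)) next
    this_ns <- sub("^namespace:\\s*", "", grep("^namespace:", block, value = TRUE)[1])
    if (is.na(this_ns)) this_ns <- default_ns
    obsolete <- any(grepl("^is_obsolete:\\s*true", block))
    isa <- sub("\\s*!.*$", "", sub("^is_a:\\s*", "", grep("^is_a:", block, value = TRUE)))
    po <- grep("^relationship:\\s*part_of\\s+", block, value = TRUE)
    po <- sub("\\s*!.*$", "", sub("^relationship:\\s*part_of\\s+", "", po))
    ids <- c(ids, id); ns <- c(ns, this_ns); obs <- c(obs, obsolete)
    plist[[id]] <- trimws(c(isa, po))
  }
  known <- ids
  keep <- !obs & ns == namespace
  kept_ids <- ids[keep]
  if (!length(kept_ids)) stop("no non-obsolete ", namespace, " terms in ", path)
  parents <- stats::setNames(vector("list", length(kept_ids)), kept_ids)
  for (id in kept_ids) {
    p <- plist[[id]]
    missing <- setdiff(p, known)
    if (length(missing)) {
      stop(sprintf("term %s references missing term %s", id, missing[1L]))
    }
    parents[[id]] <- intersect(p, kept_ids)  # drop cross-namespace/obsolete parents
  }
  go_dag(parents, namespace = namespace)
}

#' Build an annotation map (direct + propagated views)
#'
#' @param protein Character vector of protein IDs (repeated per annotation).
#' @param term Character vector of GO term IDs, parallel to `protein`.
#' @param dag A [go_dag()]; rows whose term is absent from the DAG are
#'   skipped with a warning.
#' @return Object of class `annotation_map` with `direct` (protein ->
#'   directly annotated terms) and `propagated` (direct plus all ancestors,
#'   the namespace root excluded). The root never appears in propagated
#'   sets, which grounds the "BP unknown" rule for clusters whose members
#'   share nothing below the root.
#' @export
annotation_map <- function(protein, term, dag) {
  stopifnot(length(protein) == length(term))
  ok <- term %in% dag$terms
  if (any(!ok)) {
    warning(sprintf("%d annotation row(s) reference terms outside the DAG; skipped", sum(!ok)))
  }
  direct <- lapply(split(term[ok], protein[ok]), function(x) sort(unique(x)))
  propagated <- lapply(direct, function(ts) {
    setdiff(sort(unique(c(ts, unlist(dag$ancestors[ts], use.names = FALSE)))), dag$root)
  })
  structure(list(direct = direct, propagated = propagated, root = dag$root),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map> %d proteins, %d direct annotations (root: %s)\n",
              length(x$direct), length(unlist(x$direct)), x$root))
  invisible(x)
}

#' Read protein GO annotations (GAF 2.x or two-column TSV)
#'
#' GAF rows with a `NOT` qualifier are excluded; all evidence codes are
#' retained (including IEA). Terms absent from `dag` -- including terms of
#' other namespaces, since `dag` holds a single namespace -- are skipped
#' with a warning.
#'
#' @param path Annotation file.
#' @param dag A [go_dag()].
#' @param format `"auto"` (default) sniffs GAF (`!gaf-version` header or
#'   >= 15 tab-separated columns) versus a plain `protein<TAB>term` table.
#' @return An [annotation_map()].
#' @export
read_annotations <- function(path, dag, format = c("auto", "gaf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[nzchar(lines) & !startsWith(lines, "!") & !startsWith(lines, "#")]
  if (!length(body)) stop("no annotation rows in ", path)
  if (format == "auto") {
    ncol1 <- length(strsplit(body[1L], "\t", fixed = TRUE)[[1L]])
    format <- if (any(grepl("^!gaf-version", lines)) || ncol1 >= 15L) "gaf" else "tsv"
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (format == "gaf") {
    bad <- which(lengths(fields) < 15L)
    if (length(bad)) stop("malformed GAF row (fewer than 15 columns) at data line ", bad[1L])
    qualifier <- vapply(fields, `[[`, character(1), 4L)
    keep <- !grepl("(^|\\|)NOT(\\||$)", qualifier)
    protein <- vapply(fields, `[[`, character(1), 2L)[keep]
    term <- vapply(fields, `[[`, character(1), 5L)[keep]
  } else {
    bad <- which(lengths(fields) < 2L)
    if (length(bad)) stop("malformed annotation row (need 2 columns) at data line ", bad[1L])
    protein <- vapply(fields, `[[`, character(1), 1L)
    term <- vapply(fields, `[[`, character(1), 2L)
  }
  annotation_map(protein, term, dag)
}

#' Write an ontology as OBO 1.2
#'
#' Emits minimal `[Term]` stanzas (id, namespace, is_a) in sorted term
#' order; `read_obo(write_obo(dag))` round-trips terms, parents and root.
#'
#' @param dag A [go_dag()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  lines <- c("format-version: 1.2",
             paste0("default-namespace: ", dag$namespace), "")
  for (t in sort(dag$terms)) {
    lines <- c(lines, "[Term]", paste0("id: ", t),
               paste0("namespace: ", dag$namespace),
               if (length(dag$parents[[t]])) paste0("is_a: ", sort(dag$parents[[t]])),
               "")
  }
  write_tsv_lines(lines, path)
}
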