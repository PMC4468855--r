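# Cluster systems and the class-file dialect.
#
# A cluster system is an ordered, named list of protein-ID sets covering a
# node universe; clusters may overlap. The on-disk "class file" dialect is
# one record per line, "clusterID<TAB>member1 member2 ...", with optional
# annotation lines "clusterID<TAB>GO:... GO:..." attaching BP terms to a
# cluster declared earlier in the file.

#' Construct a cluster system
#'
#' @param clusters List of character vectors (member IDs); names become
#'   cluster IDs (default `C0001`, `C0002`, ...).
#' @param universe Node universe the clusters live in; defaults to the union
#'   of all members. Used to validate membership downstream.
#' @return Object of class `cluster_system`.
#' @export
cluster_system <- function(clusters, universe = NULL) {
  stopifnot(is.list(clusters))
  clusters <- lapply(clusters, function(x) sort(unique(as.character(x))))
  if (is.null(names(clusters)) || any(!nzchar(names(clusters)))) {
    names(clusters) <- sprintf("C%04d", seq_along(clusters))
  }
  if (anyDuplicated(names(clusters))) stop("duplicate cluster IDs")
  universe <- sort(unique(universe %||% unlist(clusters, use.names = FALSE)))
  structure(list(clusters = clusters, universe = universe), class = "cluster_system")
}

#' @export
print.cluster_system <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("<cluster_system> %d clusters over %d proteins (mean size %.1f, %d multiclustered)\n",
              length(x$clusters), length(x$universe),
              if (length(sizes)) mean(sizes) else 0,
              sum(table(unlist(x$clusters, use.names = FALSE)) >= 2)))
  invisible(x)
}

#' Per-protein cluster membership counts
#'
#' @param system A [cluster_system()].
#' @return Named integer vector, protein -> number of clusters it belongs
#'   to, sorted by protein ID. Proteins of the universe missing from every
#'   cluster get a zero.
#' @export
membership_counts <- function(system) {
  tab <- table(unlist(system$clusters, use.names = FALSE))
  out <- stats::setNames(integer(length(system$universe)), system$universe)
  out[names(tab)] <- as.integer(tab)
  out
}

# drop clusters that are strict or equal subsets of another cluster
drop_subset_clusters <- function(clusters) {
  if (length(clusters) <= 1L) return(clusters)
  keep <- rep(TRUE, length(clusters))
  ord <- order(lengths(clusters))  # small ones can only be subsets of larger
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    for (jj in seq_along(clusters)) {
      if (jj == i || !keep[jj]) next
      if (length(clusters[[i]]) < length(clusters[[jj]]) ||
          (length(clusters[[i]]) == length(clusters[[jj]]) && jj < i)) {
        if (all(clusters[[i]] %in% clusters[[jj]])) { keep[i] <- FALSE; break }
      }
    }
  }
  clusters[keep]
}

#' Read a class file
#'
#' Auto-detects, per line, whether a record is a membership line or an
#' annotation line: a line whose payload tokens all match `^GO:` is taken as
#' an annotation record for an already-declared cluster. The detected
#' dialect (with/without annotation lines) is reported via `message()`.
#'
#' @param path Class file path.
#' @return An [annotated_clusters()] object; clusters without annotation
#'   lines carry an empty term set (the `UNKNOWN` sentinel).
#' @export
read_class_file <- function(path) {
  if (!file.exists(path)) stop("class file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty class file: ", path)
  parts <- regmatches(lines, regexpr("\t", lines), invert = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("malformed class-file line ", bad[1L], ": expected clusterID<TAB>payload")
  ids <- vapply(parts, `[[`, character(1), 1L)
  toks <- strsplit(trimws(vapply(parts, `[[`, character(1), 2L)), "\\s+")
  is_annot <- vapply(toks, function(x) length(x) > 0 && all(grepl("^GO:", x)), logical(1))

  clusters <- list(); annots <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (is_annot[i]) {
      if (is.null(clusters[[id]])) {
        stop("annotation line for undeclared cluster '", id, "' (line ", i, ")")
      }
      annots[[id]] <- sort(unique(c(annots[[id]], toks[[i]])))
    } else {
      if (!is.null(clusters[[id]])) stop("duplicate cluster ID '", id, "'")
      clusters[[id]] <- toks[[i]]
    }
  }
  message(sprintf("read_class_file: %d clusters; dialect: membership lines%s",
                  length(clusters),
                  if (length(annots)) " + GO annotation lines" else " only"))
  sys <- cluster_system(clusters)
  terms <- lapply(names(clusters), function(id) annots[[id]] %||% character(0))
  names(terms) <- names(clusters)
  annotated_clusters(sys, terms)
}

#' Write a class file
#'
#' Clusters are written in lexicographic ID order, members sorted within a
#' line; annotation lines (when the system carries cluster terms) follow the
#' membership block. Re-running on identical input yields byte-identical
#' files.
#'
#' @param x A [cluster_system()] or [annotated_clusters()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classes <- function(x, path) {
  if (inherits(x, "annotated_clusters")) {
    sys <- x$system; terms <- x$cluster_terms
  } else {
    sys <- x; terms <- NULL
  }
  ids <- sort(names(sys$clusters))
  lines <- vapply(ids, function(id) {
    paste0(id, "\t", paste(sort(sys$clusters[[id]]), collapse = " "))
  }, character(1))
  if (!is.null(terms)) {
    ann_ids <- ids[vapply(ids, function(id) length(terms[[id]]) > 0, logical(1))]
    lines <- c(lines, vapply(ann_ids, function(id) {
      paste0(id, "\t", paste(sort(terms[[id]]), collapse = " "))
    }, character(1)))
  }
  write_tsv_lines(lines, path)
}

#' Write the PrOnto pair table
#'
#' Columns: GO1, GO2, p_annot, e_annot, p_inter, e_inter, dissimilar; rows
#' sorted by term pair. Probabilities are fixed-format so reruns are
#' byte-identical.
#'
#' @param pair_table A pair table from [build_pair_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pronto <- function(pair_table, path) {
  pt <- pair_table[order(pair_table$go1, pair_table$go2), , drop = FALSE]
  lines <- c("GO1\tGO2\tp_annot\te_annot\tp_inter\te_inter\tdissimilar",
             sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%d",
                     pt$go1, pt$go2, fmt_num(pt$p_annot), fmt_num(pt$e_annot),
                     fmt_num(pt$p_inter), fmt_num(pt$e_inter), as.integer(pt$dissimilar)))
  write_tsv_lines(lines, path)
}

#' Write EMF candidate evidence
#'
#' One row per evidence triple (protein, cluster pair, GO pair, e-values);
#' an empty candidate set yields a header-only file.
#'
#' @param evidence Evidence data frame from [find_emf_candidates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(evidence, path) {
  header <- "protein\tclusterA\tclusterB\tGO_a\tGO_b\te_annot\te_inter"
  if (nrow(evidence) == 0) return(write_tsv_lines(header, path))
  ev <- evidence[order(evidence$protein, evidence$cluster_a, evidence$cluster_b,
                       evidence$go_a, evidence$go_b), , drop = FALSE]
  lines <- c(header,
             sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s",
                     ev$protein, ev$cluster_a, ev$cluster_b, ev$go_a, ev$go_b,
                     fmt_num(ev$e_annot), fmt_num(ev$e_inter)))
  write_tsv_lines(lines, path)
}

#' Write all pipeline artifacts to a directory
#'
#' Deterministic, sorted TSVs: `candidates.tsv`, `pronto.tsv`, `classes.tsv`.
#'
#' @param candidates Evidence data frame ([find_emf_candidates()]).
#' @param pair_table Pair table ([build_pair_table()]).
#' @param clusters [annotated_clusters()] or [cluster_system()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_outputs <- function(candidates, pair_table, clusters, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(candidates = file.path(out_dir, "candidates.tsv"),
             pronto = file.path(out_dir, "pronto.tsv"),
             classes = file.path(out_dir, "classes.tsv"))
  write_candidates(candidates, paths[["candidates"]])
  write_pronto(pair_table, paths[["pronto"]])
  write_classes(clusters, paths[["classes"]])
  invisible(paths)
}
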