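# Majority-rule annotation of clusters and annotation inheritance.
#
# A cluster becomes a "functional module" when at least `threshold` of its
# annotated members carry a BP term in their propagated annotation sets.
# Qualifying terms are reduced to the most specific ones (an ancestor of
# another qualifying term is dropped: the closure would otherwise always
# co-assign every parent). Clusters with no qualifying term below the root
# -- or no annotated member at all -- get the "BP unknown" sentinel,
# represented as an empty term set.

#' Construct an annotated cluster system
#'
#' @param system A [cluster_system()].
#' @param cluster_terms Named list parallel to `system$clusters`; each
#'   element a character vector of BP term IDs, `character(0)` meaning
#'   "BP unknown".
#' @param threshold The majority threshold the terms were derived with.
#' @return Object of class `annotated_clusters`.
#' @export
annotated_clusters <- function(system, cluster_terms, threshold = NA_real_) {
  stopifnot(inherits(system, "cluster_system"),
            length(cluster_terms) == length(system$clusters))
  if (is.null(names(cluster_terms))) names(cluster_terms) <- names(system$clusters)
  stopifnot(identical(sort(names(cluster_terms)), sort(names(system$clusters))))
  structure(list(system = system,
                 cluster_terms = cluster_terms[names(system$clusters)],
                 threshold = threshold),
            class = "annotated_clusters")
}

#' @export
print.annotated_clusters <- function(x, ...) {
  n_ann <- sum(lengths(x$cluster_terms) > 0)
  cat(sprintf("<annotated_clusters> %d clusters, %d annotated, %d BP unknown\n",
              length(x$cluster_terms), n_ann, length(x$cluster_terms) - n_ann))
  invisible(x)
}

# majority rule for one cluster; propagated = named list protein -> terms
annotate_one_cluster <- function(members, propagated, dag, threshold) {
  prop <- propagated[intersect(members, names(propagated))]
  prop <- prop[lengths(prop) > 0]
  n_ann <- length(prop)
  if (n_ann == 0) return(character(0))
  tab <- table(unlist(prop, use.names = FALSE))
  qual <- names(tab)[tab >= threshold * n_ann]
  qual <- setdiff(qual, dag$root)
  if (!length(qual)) return(character(0))
  # most-specific reduction: drop terms that are ancestors of other
  # qualifying terms
  anc <- unique(unlist(dag$ancestors[qual], use.names = FALSE))
  sort(setdiff(qual, anc))
}

#' Annotate clusters by the majority rule
#'
#' For each cluster, let S be its members with at least one propagated BP
#' term (root excluded). A term qualifies iff it appears in the propagated
#' sets of at least `threshold * |S|` members; assigned terms are the most
#' specific qualifying terms. Clusters where S is empty or only root-level
#' agreement exists are left "BP unknown".
#'
#' @param system A [cluster_system()].
#' @param annotations An [annotation_map()].
#' @param dag The [go_dag()] the annotations were propagated on.
#' @param threshold Majority fraction in (0, 1]; the comparison is `>=`
#'   ("at least"). Default 0.5.
#' @return An [annotated_clusters()] object.
#' @export
annotate_clusters <- function(system, annotations, dag, threshold = 0.5) {
  stopifnot(inherits(system, "cluster_system"),
            inherits(annotations, "annotation_map"),
            inherits(dag, "go_dag"))
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  stray <- setdiff(unlist(system$clusters, use.names = FALSE), system$universe)
  if (length(stray)) stop("cluster references unknown protein: ", stray[1L])
  terms <- lapply(system$clusters, annotate_one_cluster,
                  propagated = annotations$propagated, dag = dag,
                  threshold = threshold)
  annotated_clusters(system, terms, threshold)
}

#' Terms a protein inherits from its modules
#'
#' The union of the protein's own propagated terms and the assigned terms
#' of every cluster it belongs to ("BP unknown" clusters contribute
#' nothing).
#'
#' @param protein Protein ID.
#' @param annotated An [annotated_clusters()] object.
#' @param annotations An [annotation_map()] (for the protein's own terms).
#' @return Sorted character vector of BP term IDs.
#' @export
inherit_annotations <- function(protein, annotated, annotations) {
  stopifnot(inherits(annotated, "annotated_clusters"))
  in_cl <- vapply(annotated$system$clusters, function(cl) protein %in% cl, logical(1))
  if (!any(in_cl)) stop("protein not in any cluster: ", protein)
  own <- annotations$propagated[[protein]] %||% character(0)
  sort(unique(c(own, unlist(annotated$cluster_terms[in_cl], use.names = FALSE))))
}
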