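# EMF candidate detection.
#
# A candidate is a protein found at the intersection of two clusters whose
# assigned BP terms form at least one pair that is significantly dissimilar
# by both e-values. Evidence is exhaustive: every qualifying
# (cluster pair, term pair) combination is retained, which enables the
# provenance classification and function-pair summaries. A term shared by
# both clusters never generates evidence (a term is not dissimilar to
# itself), and "BP unknown" clusters are skipped.

#' Multiclustered proteins
#'
#' @param system A [cluster_system()].
#' @return Sorted named integer vector of cluster-membership counts for the
#'   proteins belonging to two or more clusters.
#' @export
find_multiclustered <- function(system) {
  counts <- membership_counts(system)
  counts[counts >= 2L]
}

#' Detect EMF candidates
#'
#' For every protein in at least two annotated clusters, every unordered
#' pair of its clusters and every cross pair of their assigned terms is
#' checked against the pair table; an evidence row is recorded iff both
#' e-values are `<= alpha`. Term pairs absent from the table are treated as
#' non-significant (their count is reported via `message()`).
#'
#' @param annotated An [annotated_clusters()] object.
#' @param pair_table A data frame with columns `go1`, `go2`, `e_annot`,
#'   `e_inter` (typically from [build_pair_table()]).
#' @param alpha e-value threshold in (0, 1].
#' @return Data frame of class `emf_evidence`, one row per evidence triple,
#'   sorted by protein; attributes `candidates` (sorted unique protein IDs),
#'   `alpha` and `n_missing_pairs`.
#' @export
find_emf_candidates <- function(annotated, pair_table, alpha = 0.05) {
  stopifnot(inherits(annotated, "annotated_clusters"))
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  key <- pair_key(pair_table$go1, pair_table$go2)
  counts <- find_multiclustered(annotated$system)
  terms <- annotated$cluster_terms
  cl_names <- names(annotated$system$clusters)
  rows <- list()
  n_missing <- 0L
  for (p in names(counts)) {
    in_cl <- which(vapply(annotated$system$clusters, function(cl) p %in% cl, logical(1)))
    in_cl <- in_cl[lengths(terms[in_cl]) > 0]  # skip BP-unknown clusters
    if (length(in_cl) < 2L) next
    for (a_i in seq_len(length(in_cl) - 1L)) {
      for (b_i in (a_i + 1L):length(in_cl)) {
        ca <- in_cl[a_i]; cb <- in_cl[b_i]
        cross <- expand.grid(go_a = terms[[ca]], go_b = terms[[cb]],
                             stringsAsFactors = FALSE)
        cross <- cross[cross$go_a != cross$go_b, , drop = FALSE]
        if (!nrow(cross)) next
        m <- match(pair_key(cross$go_a, cross$go_b), key)
        n_missing <- n_missing + sum(is.na(m))
        sig <- !is.na(m) & pair_table$e_annot[m] <= alpha & pair_table$e_inter[m] <= alpha
        if (!any(sig)) next
        rows[[length(rows) + 1L]] <- data.frame(
          protein = p,
          cluster_a = cl_names[ca], cluster_b = cl_names[cb],
          go_a = cross$go_a[sig], go_b = cross$go_b[sig],
          e_annot = pair_table$e_annot[m[sig]],
          e_inter = pair_table$e_inter[m[sig]],
          stringsAsFactors = FALSE)
      }
    }
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein = character(0), cluster_a = character(0),
               cluster_b = character(0), go_a = character(0),
               go_b = character(0), e_annot = numeric(0), e_inter = numeric(0),
               stringsAsFactors = FALSE)
  ev <- ev[order(ev$protein, ev$cluster_a, ev$cluster_b, ev$go_a, ev$go_b), ,
           drop = FALSE]
  rownames(ev) <- NULL
  if (n_missing) {
    message(sprintf("find_emf_candidates: %d cross term pair(s) absent from the pair table (treated as non-significant)",
                    n_missing))
  }
  structure(ev, candidates = sort(unique(ev$protein)), alpha = alpha,
            n_missing_pairs = n_missing,
            class = c("emf_evidence", "data.frame"))
}

#' Candidate IDs from an evidence table
#'
#' @param evidence An `emf_evidence` data frame.
#' @return Sorted character vector of candidate protein IDs.
#' @export
emf_candidates <- function(evidence) {
  attr(evidence, "candidates") %||% sort(unique(evidence$protein))
}

#' Provenance of the terms that flagged each candidate
#'
#' Classifies every candidate against its own propagated annotations using
#' its best-supported evidence entry: `both_known` if some evidence pair has
#' both terms already in the protein's propagated set, `one_inherited` if at
#' best one term was known, `both_inherited` if no evidence term was.
#'
#' @param evidence An `emf_evidence` data frame with at least one row.
#' @param annotations An [annotation_map()].
#' @return Data frame with columns `protein` and `provenance` (factor with
#'   levels `both_known`, `one_inherited`, `both_inherited`).
#' @export
candidate_provenance <- function(evidence, annotations) {
  if (nrow(evidence) == 0) {
    return(data.frame(protein = character(0),
                      provenance = factor(character(0),
                                          levels = c("both_known", "one_inherited",
                                                     "both_inherited"))))
  }
  own <- annotations$propagated
  per <- split(evidence[, c("go_a", "go_b")], evidence$protein)
  prov <- vapply(names(per), function(p) {
    mine <- own[[p]] %||% character(0)
    best <- max((per[[p]]$go_a %in% mine) + (per[[p]]$go_b %in% mine))
    c("both_inherited", "one_inherited", "both_known")[best + 1L]
  }, character(1))
  data.frame(protein = names(per),
             provenance = factor(prov, levels = c("both_known", "one_inherited",
                                                  "both_inherited")),
             row.names = NULL, stringsAsFactors = FALSE)
}
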