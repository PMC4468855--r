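# The end-to-end detection pipeline as a single classed object.
#
# moongo() chains cluster -> annotate -> pair probabilities -> detect and
# returns everything a downstream analysis needs: the cluster system, the
# annotated modules, the pair table, the evidence rows and the candidate
# set, plus headline counts. simulate() re-runs the pipeline under the
# four randomization null schemes.

#' Run the EMF detection pipeline
#'
#' @param network Undirected simple `igraph` graph with vertex names.
#' @param annotations An [annotation_map()].
#' @param dag A [go_dag()].
#' @param alpha e-value significance threshold in (0, 1] (default 0.05).
#' @param annot_threshold Majority-rule fraction in (0, 1] (default 0.5).
#' @param system Optional precomputed [cluster_system()]; by default
#'   clusters are generated with [ocg_cluster()].
#' @param pair_terms Optional explicit term universe for the pair table;
#'   default is all cluster-assigned terms.
#' @return Object of class `moongo` with elements `network`, `annotations`,
#'   `dag`, `system`, `annotated`, `pair_table`, `evidence`, `candidates`,
#'   `multiclustered`, `provenance`, `alpha`, `annot_threshold` and
#'   `summary` (named list of headline counts).
#' @examples
#' scn <- generate_scenario(seed = 7)
#' fit <- moongo(scn$network, scn$annotations, scn$dag)
#' fit$candidates  # the planted shared nodes
#' @export
moongo <- function(network, annotations, dag, alpha = 0.05,
                   annot_threshold = 0.5, system = NULL, pair_terms = NULL) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  if (!(annot_threshold > 0 && annot_threshold <= 1)) {
    stop("annot_threshold must be in (0, 1]")
  }
  if (is.null(system)) system <- ocg_cluster(network)
  annotated <- annotate_clusters(system, annotations, dag, annot_threshold)
  pair_table <- build_pair_table(annotated, network, annotations,
                                 terms = pair_terms, alpha = alpha)
  evidence <- find_emf_candidates(annotated, pair_table, alpha)
  candidates <- emf_candidates(evidence)
  multicl <- find_multiclustered(system)
  sizes <- lengths(system$clusters)
  smry <- list(
    n_nodes = igraph::vcount(network),
    n_edges = igraph::ecount(network),
    n_clusters = length(system$clusters),
    mean_cluster_size = mean(sizes),
    n_annotated_clusters = sum(lengths(annotated$cluster_terms) > 0),
    n_multiclustered = length(multicl),
    n_tests = attr(pair_table, "n_tests"),
    n_dissimilar_pairs = sum(pair_table$dissimilar),
    n_candidates = length(candidates))
  structure(list(network = network, annotations = annotations, dag = dag,
                 system = system, annotated = annotated,
                 pair_table = pair_table, evidence = evidence,
                 candidates = candidates, multiclustered = multicl,
                 provenance = candidate_provenance(evidence, annotations),
                 alpha = alpha, annot_threshold = annot_threshold,
                 summary = smry),
            class = "moongo")
}

#' @export
print.moongo <- function(x, ...) {
  s <- x$summary
  cat("Extreme-multifunctionality detection (MoonGO-style pipeline)\n")
  cat(sprintf("  network: %d proteins, %d interactions\n", s$n_nodes, s$n_edges))
  cat(sprintf("  clusters: %d (mean size %.1f), %d annotated, %d proteins multiclustered\n",
              s$n_clusters, s$mean_cluster_size, s$n_annotated_clusters,
              s$n_multiclustered))
  cat(sprintf("  term pairs tested: %d, dissimilar: %d (alpha = %g)\n",
              s$n_tests, s$n_dissimilar_pairs, x$alpha))
  cat(sprintf("  EMF candidates: %d\n", s$n_candidates))
  invisible(x)
}

#' @export
summary.moongo <- function(object, hub_threshold = NULL, ...) {
  groups <- assign_groups(object$network, object$system, object$candidates,
                          hub_threshold = hub_threshold)
  feats <- topology_features(object$network, object$system,
                             object$annotations)
  group_means <- vapply(groups, function(g) {
    mean(feats$degree[match(g, feats$protein)], na.rm = TRUE)
  }, numeric(1))
  out <- list(fit = object, groups = groups,
              hub_threshold = attr(groups, "hub_threshold"),
              mean_degree_by_group = group_means,
              provenance = table(object$provenance$provenance))
  class(out) <- "summary.moongo"
  out
}

#' @export
print.summary.moongo <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  hub threshold: degree >= %d\n", x$hub_threshold))
  cat("  group sizes: ",
      paste(sprintf("%s=%d", names(x$groups), lengths(x$groups)), collapse = ", "),
      "\n", sep = "")
  cat("  mean degree by group: ",
      paste(sprintf("%s=%.1f", names(x$mean_degree_by_group),
                    x$mean_degree_by_group), collapse = ", "),
      "\n", sep = "")
  if (sum(x$provenance) > 0) {
    cat("  candidate provenance: ",
        paste(sprintf("%s=%d", names(x$provenance), x$provenance),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.moongo <- function(x, ...) {
  groups <- assign_groups(x$network, x$system, x$candidates)
  feats <- topology_features(x$network, x$system)
  sel <- c("cands", "multi_nc", "mono", "hubs")
  vals <- lapply(groups[sel], function(g) {
    v <- feats$degree[match(g, feats$protein)]
    v[!is.na(v)]
  })
  keep <- lengths(vals) > 0
  graphics::boxplot(vals[keep],
                    names = c(Cands = "Cands", multi_nc = "Multi-NC",
                              mono = "Mono", hubs = "Hubs")[sel][keep],
                    ylab = "degree", main = "Degree by protein group", ...)
  invisible(x)
}

#' Randomization controls for a fitted pipeline
#'
#' Re-runs the detection under one of the four null schemes, `nsim` times:
#' `annotation_shuffle` permutes annotation sets across proteins and
#' re-annotates the observed clusters; `edge_uniform` and
#' `edge_degree_preserving` randomize the topology and re-run the full
#' pipeline (re-clustering included); `probability_shuffle` permutes the
#' pair-probability tuples across term pairs and re-detects. Replicate `i`
#' uses seed `seed + i - 1`.
#'
#' @param object A `moongo` fit.
#' @param nsim Number of replicates (default 10).
#' @param seed Base integer seed (default 1).
#' @param scheme Null scheme.
#' @param ... Unused.
#' @return Data frame of class `moongo_null` with one row per replicate
#'   (`rep`, `scheme`, `n_annotated_clusters`, `n_candidates`) and
#'   attributes `mean_candidates`, `mean_annotated_clusters`,
#'   `observed_candidates`.
#' @export
simulate.moongo <- function(object, nsim = 10, seed = 1,
                            scheme = c("annotation_shuffle", "edge_uniform",
                                       "edge_degree_preserving",
                                       "probability_shuffle"), ...) {
  scheme <- match.arg(scheme)
  seed <- seed %||% 1
  rows <- lapply(seq_len(nsim), function(i) {
    si <- seed + i - 1L
    res <- switch(scheme,
      annotation_shuffle = {
        ann2 <- shuffle_annotations(object$annotations, object$dag, si)
        null_detect(object$system, object$network, ann2, object$dag,
                    object$alpha, object$annot_threshold)
      },
      edge_uniform = ,
      edge_degree_preserving = {
        mode <- if (scheme == "edge_uniform") "uniform" else "degree_preserving"
        g2 <- randomize_edges(object$network, mode, si)
        sys2 <- ocg_cluster(g2)
        null_detect(sys2, g2, object$annotations, object$dag,
                    object$alpha, object$annot_threshold)
      },
      probability_shuffle = {
        pt2 <- shuffle_pair_probabilities(object$pair_table, si)
        ev2 <- find_emf_candidates(object$annotated, pt2, object$alpha)
        list(n_annotated = object$summary$n_annotated_clusters,
             n_candidates = length(emf_candidates(ev2)))
      })
    data.frame(rep = i, scheme = scheme,
               n_annotated_clusters = res$n_annotated,
               n_candidates = res$n_candidates,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out,
            mean_candidates = mean(out$n_candidates),
            mean_annotated_clusters = mean(out$n_annotated_clusters),
            observed_candidates = object$summary$n_candidates,
            class = c("moongo_null", "data.frame"))
}

# annotate + pair table + detect on (possibly randomized) inputs; a term
# universe collapsing below 2 terms simply means zero candidates
null_detect <- function(system, network, annotations, dag, alpha, threshold) {
  annotated <- suppressMessages(annotate_clusters(system, annotations, dag, threshold))
  terms <- unique(unlist(annotated$cluster_terms, use.names = FALSE))
  n_ann <- sum(lengths(annotated$cluster_terms) > 0)
  if (length(terms) < 2L) {
    return(list(n_annotated = n_ann, n_candidates = 0L))
  }
  pt <- tryCatch(
    suppressMessages(build_pair_table(annotated, network, annotations, alpha = alpha)),
    error = function(e) NULL)
  if (is.null(pt)) return(list(n_annotated = n_ann, n_candidates = 0L))
  ev <- suppressMessages(find_emf_candidates(annotated, pt, alpha))
  list(n_annotated = n_ann, n_candidates = length(emf_candidates(ev)))
}

#' @export
print.moongo_null <- function(x, ...) {
  cat(sprintf("<moongo_null> scheme %s, %d replicate(s): mean %.2f candidates (observed %d), mean %.1f annotated clusters\n",
              x$scheme[1L], nrow(x), attr(x, "mean_candidates"),
              attr(x, "observed_candidates"),
              attr(x, "mean_annotated_clusters")))
  invisible(x)
}

#' Run the pipeline from files and write all artifacts
#'
#' Reads the network, ontology and annotations, runs [moongo()], and writes
#' `classes.tsv`, `pronto.tsv`, `candidates.tsv` and `summary.json` to
#' `out_dir`. Reruns on identical inputs produce byte-identical outputs.
#'
#' @param network Path to the network file (or an `igraph` graph).
#' @param obo Path to the OBO ontology (or a `go_dag`).
#' @param gaf Path to the annotation file (or an `annotation_map`).
#' @param out_dir Output directory.
#' @param alpha,annot_threshold Pipeline thresholds.
#' @param network_format Passed to [read_network()].
#' @return The `moongo` fit, invisibly.
#' @export
run_pipeline <- function(network, obo, gaf, out_dir, alpha = 0.05,
                         annot_threshold = 0.5, network_format = "tsv") {
  dag <- if (inherits(obo, "go_dag")) obo else read_obo(obo)
  g <- if (inherits(network, "igraph")) network else read_network(network, network_format)
  ann <- if (inherits(gaf, "annotation_map")) gaf else read_annotations(gaf, dag)
  message(sprintf("stage network: %d nodes, %d edges", igraph::vcount(g), igraph::ecount(g)))
  fit <- moongo(g, ann, dag, alpha = alpha, annot_threshold = annot_threshold)
  message(sprintf("stage cluster: %d clusters", fit$summary$n_clusters))
  message(sprintf("stage annotate: %d annotated clusters", fit$summary$n_annotated_clusters))
  message(sprintf("stage pronto: %d pairs tested", fit$summary$n_tests))
  message(sprintf("stage detect: %d candidates", fit$summary$n_candidates))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_outputs(fit$evidence, fit$pair_table, fit$annotated, out_dir)
  jsonlite::write_json(fit$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}
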