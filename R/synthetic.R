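# Seeded synthetic scenarios with planted overlapping modules and planted
# EMF nodes.
#
# The generator emulates the modular structure the detection principle
# assumes: dense blocks of proteins engaged in the same process, connected
# by sparse noise edges, with a few nodes shared between two modules. The
# toy ontology gives every module term its own branch under the root, so
# distinct processes share no ancestry below the root; terms of different
# modules are rarely co-annotated and rarely bridge interactions, which
# makes cross-module term pairs dissimilar under the pair probabilities
# computed on this corpus, and randomly assembled protein groups share no
# majority term (the "BP unknown" outcome, as on real ontologies).
# Besides its specific (module-level) term, every protein carries one
# private rare term under the same branch, mimicking the long tail of GO
# term frequencies in real corpora. This guarantees the two distinct
# direct annotations the pair-probability universe requires, and it is
# what makes the randomization controls behave as on real data: clusters
# found in randomized topologies are annotated mostly with rare terms,
# which blows up the number of term pairs under test and Bonferroni-kills
# chance associations, while genuine module clusters assign only module
# terms (a rare term never reaches the majority threshold in a real
# module).

#' Generate a planted-EMF scenario
#'
#' Modules are dense blocks (each intra-module edge present with `p_in`),
#' with inter-module noise edges drawn with `p_out`. `n_shared_nodes` extra
#' nodes are each placed in two modules (consecutive pairs, round-robin) and
#' form the planted EMF set: they are directly annotated to the term of
#' their first module only, inheriting the second module's term through
#' module membership. Exclusive members are annotated to their module's
#' term with probability `annotation_purity`, otherwise to a uniformly
#' drawn other module's term; every protein also carries a private rare
#' term under the branch of its specific term. Fully deterministic given
#' `seed`.
#'
#' @param n_modules Number of planted modules (>= 2 when nodes are shared).
#' @param sizes Exclusive module sizes (recycled to `n_modules`; each >= 3).
#' @param p_in Intra-module edge probability.
#' @param p_out Inter-module edge probability.
#' @param n_shared_nodes Number of planted EMF nodes.
#' @param annotation_purity Probability an exclusive member is annotated to
#'   its own module's term.
#' @param rare_coverage Fraction of the focal modules' exclusive members
#'   that carry a private rare term in addition to their specific term
#'   (and hence enter the two-annotation universe of the pair
#'   probabilities). Members of non-focal modules carry their specific
#'   term only, emulating study-biased annotation density.
#' @param seed Integer seed.
#' @return Object of class `planted_scenario`: `network`, `true_modules`,
#'   `dag`, `annotations`, `planted_emfs`, `params`, and `recoverable`
#'   (`p_in > p_out`).
#' @export
generate_scenario <- function(n_modules = 8,
                              sizes = c(20, 20, rep(10, 6)), p_in = 1.0,
                              p_out = 0.01, n_shared_nodes = 2,
                              annotation_purity = 0.9, rare_coverage = 1.0,
                              seed = 1) {
  sizes <- rep_len(sizes, n_modules)
  stopifnot(n_modules >= 1, all(sizes >= 3),
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            annotation_purity >= 0, annotation_purity <= 1,
            rare_coverage >= 0, rare_coverage <= 1,
            n_shared_nodes >= 0)
  if (n_shared_nodes > min(sizes)) {
    stop("n_shared_nodes exceeds the smallest module size")
  }
  if (n_shared_nodes > 0 && n_modules < 2) {
    stop("shared nodes require at least 2 modules")
  }

  # ontology: every module term sits in its own branch under the root, so
  # distinct processes share no ancestry below the root
  root <- "GO:0000001"
  br <- sprintf("GO:00001%02d", seq_len(n_modules))
  branch_of <- stats::setNames(br, sprintf("GO:00002%02d", seq_len(n_modules)))
  mod_terms <- names(branch_of)

  core <- split(sprintf("P%03d", seq_len(sum(sizes))),
                rep(seq_len(n_modules), sizes))
  shared <- if (n_shared_nodes > 0) sprintf("S%02d", seq_len(n_shared_nodes)) else character(0)
  all_prots <- c(unlist(core, use.names = FALSE), shared)
  rare_of <- stats::setNames(sprintf("GO:0000%03d", 500 + seq_along(all_prots)),
                             all_prots)
  parents <- c(stats::setNames(rep(list(root), length(br)), br),
               lapply(branch_of, identity))
  modules <- lapply(seq_len(n_modules), function(i) core[[i]])
  first_module <- integer(0)
  for (j in seq_len(n_shared_nodes)) {
    # planted EMFs bridge the two focal (richly annotated) modules,
    # alternating which side supplies their direct annotation
    m1 <- if (n_modules == 1L) 1L else (j - 1L) %% 2L + 1L
    m2 <- if (n_modules == 1L) 1L else 3L - m1
    modules[[m1]] <- c(modules[[m1]], shared[j])
    modules[[m2]] <- c(modules[[m2]], shared[j])
    first_module[j] <- m1
  }
  modules <- lapply(modules, sort)
  nodes <- sort(unique(unlist(modules)))

  scenario <- with_seed(seed, {
    # annotations
    prot <- character(0); term <- character(0)
    rare_parent <- character(0)
    for (i in seq_len(n_modules)) {
      focal <- i <= 2L
      for (p in core[[i]]) {
        own <- stats::runif(1) <= annotation_purity || n_modules == 1L
        t <- if (own) mod_terms[i] else sample(mod_terms[-i], 1L)
        if (focal && stats::runif(1) <= rare_coverage) {
          prot <- c(prot, p, p); term <- c(term, t, rare_of[[p]])
          rare_parent[rare_of[[p]]] <- branch_of[[t]]
        } else {
          prot <- c(prot, p); term <- c(term, t)
        }
      }
    }
    for (j in seq_len(n_shared_nodes)) {
      # planted EMFs are sparsely annotated: their second function is the
      # one the module inheritance reveals
      prot <- c(prot, shared[j]); term <- c(term, mod_terms[first_module[j]])
    }
    dag <- go_dag(c(parents, lapply(rare_parent, identity)))
    ann <- annotation_map(prot, term, dag)

    # edges: enumerate unordered pairs once, in fixed order
    pairs <- utils::combn(nodes, 2)
    same <- vapply(seq_len(ncol(pairs)), function(c1) {
      any(vapply(modules, function(m) all(pairs[, c1] %in% m), logical(1)))
    }, logical(1))
    pe <- ifelse(same, p_in, p_out)
    keep <- stats::runif(ncol(pairs)) <= pe
    edf <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                      stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = nodes)
    list(network = g, annotations = ann, dag = dag)
  })

  structure(list(network = scenario$network,
                 true_modules = modules,
                 dag = scenario$dag,
                 annotations = scenario$annotations,
                 planted_emfs = shared,
                 params = list(n_modules = n_modules, sizes = sizes,
                               p_in = p_in, p_out = p_out,
                               n_shared_nodes = n_shared_nodes,
                               annotation_purity = annotation_purity,
                               rare_coverage = rare_coverage,
                               seed = seed),
                 recoverable = p_in > p_out),
            class = "planted_scenario")
}

#' @export
print.planted_scenario <- function(x, ...) {
  cat(sprintf("<planted_scenario> %d modules, %d nodes, %d edges, %d planted EMF(s), seed %d\n",
              length(x$true_modules), igraph::vcount(x$network),
              igraph::ecount(x$network), length(x$planted_emfs),
              x$params$seed))
  invisible(x)
}

#' Best-match Jaccard recovery of planted modules
#'
#' Mean over true modules of the maximum Jaccard index against any found
#' cluster.
#'
#' @param found A [cluster_system()] or list of member vectors.
#' @param true_modules List of true member vectors.
#' @return Fraction in \[0, 1\].
#' @export
recovery_score <- function(found, true_modules) {
  fl <- if (inherits(found, "cluster_system")) found$clusters else found
  stopifnot(length(fl) > 0, length(true_modules) > 0)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  mean(vapply(true_modules, function(t) {
    max(vapply(fl, function(f) jac(f, t), numeric(1)))
  }, numeric(1)))
}
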