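# Randomization invariants, leave-one-out recovery and set enrichment.

test_that("annotation shuffling conserves the multiset of annotation sets", {
  scn <- generate_scenario(seed = 4)
  ann <- scn$annotations
  sh <- shuffle_annotations(ann, scn$dag, seed = 99)
  canon <- function(a) sort(unname(vapply(a$direct, paste, character(1), collapse = "|")))
  expect_identical(canon(sh), canon(ann))
  expect_identical(sort(names(sh$direct)), sort(names(ann$direct)))
  # same seed, same permutation; different seed, (here) different one
  sh2 <- shuffle_annotations(ann, scn$dag, seed = 99)
  expect_identical(sh$direct, sh2$direct)
  sh3 <- shuffle_annotations(ann, scn$dag, seed = 100)
  expect_false(identical(sh$direct, sh3$direct))
  # propagation is recomputed for the permuted sets
  p <- names(sh$direct)[1]
  expect_identical(sh$propagated[[p]],
                   setdiff(sort(unique(c(sh$direct[[p]],
                                         unlist(scn$dag$ancestors[sh$direct[[p]]])))),
                           scn$dag$root))
})

test_that("degree-preserving rewiring conserves the degree sequence exactly", {
  scn <- generate_scenario(seed = 5)
  g <- scn$network
  r <- randomize_edges(g, "degree_preserving", seed = 1)
  expect_identical(sort(igraph::degree(r)), sort(igraph::degree(g)))
  expect_identical(stats::setNames(igraph::degree(r)[igraph::V(g)$name], igraph::V(g)$name),
                   stats::setNames(igraph::degree(g)[igraph::V(g)$name], igraph::V(g)$name))
  expect_true(igraph::is_simple(r))
  # same seed reproduces the graph
  r2 <- randomize_edges(g, "degree_preserving", seed = 1)
  expect_true(igraph::identical_graphs(r, r2))
})

test_that("uniform rewiring conserves node and edge counts on a simple graph", {
  scn <- generate_scenario(seed = 6)
  g <- scn$network
  r <- randomize_edges(g, "uniform", seed = 2)
  expect_equal(igraph::vcount(r), igraph::vcount(g))
  expect_equal(igraph::ecount(r), igraph::ecount(g))
  expect_true(igraph::is_simple(r))
  expect_setequal(igraph::V(r)$name, igraph::V(g)$name)
})

test_that("probability reshuffling conserves the tuple multiset", {
  scn <- generate_scenario(seed = 8)
  fit <- suppressMessages(moongo(scn$network, scn$annotations, scn$dag))
  pt <- fit$pair_table
  sh <- shuffle_pair_probabilities(pt, seed = 3)
  expect_identical(sort(sh$p_annot), sort(pt$p_annot))
  expect_identical(sort(paste(sh$p_annot, sh$p_inter)),
                   sort(paste(pt$p_annot, pt$p_inter)))
  expect_identical(sh[, c("go1", "go2")], pt[, c("go1", "go2")])
  expect_equal(sh$e_annot, pmin(1, sh$p_annot * attr(sh, "n_tests")))
  expect_identical(shuffle_pair_probabilities(pt, seed = 3)$p_annot, sh$p_annot)
})

test_that("leave-one-out recovers shared terms and fails unique-term members", {
  dag <- go_dag(list(T = "R", U = "R"))
  sys <- cluster_system(list(c("p1", "p2", "p3")))
  # p1, p2 share T; p3 carries a unique term U
  ann <- annotation_map(c("p1", "p2", "p3"), c("T", "T", "U"), dag)
  frac <- leave_one_out_recovery(sys, ann, dag)
  # holding out p1 or p2: the other + p3 still qualify T (and U) at 1/2 -> recovered;
  # holding out p3: remaining members share only T -> U never recovered
  expect_equal(as.numeric(frac), 2 / 3)
  expect_equal(attr(frac, "cases"), 3L)

  # every member shares T: perfect recovery
  ann2 <- annotation_map(c("p1", "p2", "p3"), rep("T", 3), dag)
  expect_equal(as.numeric(leave_one_out_recovery(sys, ann2, dag)), 1)

  # no annotated member anywhere -> no evaluable case
  ann3 <- annotation_map("zz", "T", dag)
  expect_error(leave_one_out_recovery(sys, ann3, dag), "no evaluable")
})

test_that("an ancestor of an inferred term counts as a recovered annotation", {
  dag <- chain_dag()  # T1 root <- T2 <- T3
  sys <- cluster_system(list(c("p1", "p2", "p3")))
  # p3 directly annotated to T2; others to T3 (whose closure contains T2).
  # Held out, p3's T2 is matched by the ancestor closure of inferred T3.
  ann <- annotation_map(c("p1", "p2", "p3"), c("T3", "T3", "T2"), dag)
  expect_equal(as.numeric(leave_one_out_recovery(sys, ann, dag)), 1)
})

test_that("leave-one-out recovery increases with annotation purity", {
  fracs <- vapply(c(0.3, 0.7, 1.0), function(purity) {
    scn <- generate_scenario(annotation_purity = purity, p_out = 0, seed = 21)
    sys <- ocg_cluster(scn$network)
    as.numeric(leave_one_out_recovery(sys, scn$annotations, scn$dag))
  }, numeric(1))
  expect_true(all(fracs >= 0 & fracs <= 1))
  expect_true(all(diff(fracs) >= 0))
  expect_gt(fracs[3], fracs[1])
})

test_that("known-set enrichment matches closed forms and the paper-style counts", {
  # printed-count check: N=12865, K=430, n=39, k=6 -> 4.6-fold, p ~ 1.4e-3
  uni <- sprintf("u%05d", 1:12865)
  cands <- uni[1:430]
  known <- c(uni[1:6], uni[12001:12033])
  enr <- known_set_enrichment(cands, known, uni)
  expect_equal(enr$k, 6)
  expect_equal(round(enr$fold, 1), 4.6)
  # the upper tail and the point probability bracket the printed 1.4e-3
  expect_lt(abs(enr$p_point - 1.4e-3), 1.5e-4)
  expect_lt(abs(enr$p - 1.4e-3), 5e-4)

  # degenerate identities
  expect_equal(known_set_enrichment(letters, letters, letters)$fold, 1)
  expect_equal(known_set_enrichment(letters, letters, letters)$p, 1)
  e0 <- known_set_enrichment(letters[1:3], letters[4:6], letters)
  expect_equal(e0$fold, 0)
  expect_equal(e0$p, 1)
  expect_error(known_set_enrichment(letters[1:3], character(0), letters), "empty known")
  expect_error(known_set_enrichment(letters[1:3], "zzz", letters), "subset")
})

test_that("enrichment p matches exhaustive enumeration for small universes", {
  set.seed(13)
  for (rep in 1:8) {
    N <- sample(5:12, 1)
    uni <- sprintf("g%02d", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    cands <- uni[seq_len(K)]
    known <- sample(uni, n)
    enr <- known_set_enrichment(cands, known, uni)
    o <- enum_hyper(N, K, n, enr$k)
    expect_equal(enr$p, o$upper)
  }
})
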