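# Hypergeometric term-pair probabilities and the corrected pair table.

# annotations engineered to give exact (N, K, n, k) on the direct view:
# every protein gets two private filler terms so all N proteins have >= 2
# distinct direct annotations
counts_annotation_map <- function(N, K, n, k) {
  prots <- sprintf("p%02d", seq_len(N))
  prot <- character(0); term <- character(0)
  for (i in seq_len(N)) {
    ts <- sprintf("F%02d%s", i, c("a", "b"))  # fillers, absent from pair queries
    if (i <= K) ts <- c(ts, "G1")
    if (i > K - k && i <= K - k + n) ts <- c(ts, "G2")
    prot <- c(prot, rep(prots[i], length(ts))); term <- c(term, ts)
  }
  fillers <- unique(grep("^F", term, value = TRUE))
  dag2 <- go_dag(c(list(G1 = "R", G2 = "R"),
                   stats::setNames(rep(list("R"), length(fillers)), fillers)))
  annotation_map(prot, term, dag2)
}

test_that("annotation probabilities match closed forms", {
  # N=6, K=3, n=2, k=0 -> P(X<=0) = C(3,2)/C(6,2) = 0.2
  ann <- counts_annotation_map(6, 3, 2, 0)
  r <- annotation_pvalue("G1", "G2", ann)
  expect_equal(c(r$N, r$K, r$n, r$k), c(6, 3, 2, 0))
  expect_equal(r$lower, 0.2)
  # K = N forces k = n and P(X<=k) = 1
  r2 <- annotation_pvalue("G1", "G2", counts_annotation_map(5, 5, 3, 3))
  expect_equal(r2$k, r2$n)
  expect_equal(r2$lower, 1)
  # N=10, K=5, n=5, k=5: lower tail 1, upper tail 1/C(10,5)
  r3 <- annotation_pvalue("G1", "G2", counts_annotation_map(10, 5, 5, 5))
  expect_equal(r3$lower, 1)
  expect_equal(r3$upper, 1 / 252)
  expect_error(annotation_pvalue("G1", "G1", ann), "must differ")
})

test_that("both tails equal exhaustive enumeration for N <= 12", {
  set.seed(7)
  for (rep in 1:12) {
    N <- sample(4:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    ks <- max(0, K + n - N):min(K, n)
    k <- ks[sample.int(length(ks), 1)]
    r <- annotation_pvalue("G1", "G2", counts_annotation_map(N, K, n, k))
    o <- enum_hyper(N, K, n, k)
    expect_equal(r$lower, o$lower)
    expect_equal(r$upper, o$upper)
    # complementarity P(X<=k) + P(X>=k+1) = 1
    expect_equal(r$lower + stats::phyper(k, K, N - K, n, lower.tail = FALSE), 1)
  }
})

test_that("lower tail is monotone non-decreasing in k with fixed margins", {
  expect_true(all(diff(stats::phyper(0:4, 5, 7, 4)) >= 0))
  expect_error(moonnet:::check_hyper_counts(10, 12, 3, 1), "inconsistent")
  expect_error(moonnet:::check_hyper_counts(10, 4, 3, 4), "inconsistent")
})

test_that("interaction probabilities count edges, not proteins", {
  dag <- go_dag(list(G1 = "R", G2 = "R", Fa = "R", Fb = "R", Fc = "R",
                     Fd = "R", Fe = "R"))
  # path p1-p2-p3-p4-p5; GO1 on p1,p2; GO2 on p4,p5; p3 neither
  g <- graph_from_pairs("p1-p2", "p2-p3", "p3-p4", "p4-p5")
  ann <- annotation_map(
    c("p1", "p1", "p2", "p2", "p3", "p3", "p4", "p4", "p5", "p5"),
    c("G1", "Fa", "G1", "Fb", "Fa", "Fb", "G2", "Fc", "G2", "Fd"), dag)
  r <- interaction_pvalue("G1", "G2", g, ann)
  expect_equal(c(r$N, r$K, r$n, r$k), c(4, 2, 2, 0))
  expect_equal(r$lower, 1 / 6)  # C(2,2)/C(4,2), confirmed by enumeration
  expect_equal(r$lower, enum_hyper(4, 2, 2, 0)$lower)
  # symmetry under term swap
  r2 <- interaction_pvalue("G2", "G1", g, ann)
  expect_equal(r2$lower, r$lower)

  # single-edge universe: both endpoints annotated to both-of-a-kind
  g1 <- graph_from_pairs("A-B")
  ann1 <- annotation_map(c("A", "A", "B", "B"), c("G1", "Fa", "G2", "Fb"), dag)
  r1 <- interaction_pvalue("G1", "G2", g1, ann1)
  expect_equal(c(r1$N, r1$K, r1$n, r1$k), c(1, 1, 1, 1))
  expect_equal(r1$lower, 1)
})

test_that("an edge whose single endpoint carries both terms is no cross pair", {
  dag <- go_dag(list(G1 = "R", G2 = "R", Fa = "R", Fb = "R"))
  g <- graph_from_pairs("A-B")
  ann <- annotation_map(c("A", "A", "B", "B"), c("G1", "G2", "Fa", "Fb"), dag)
  r <- interaction_pvalue("G1", "G2", g, ann)
  expect_equal(r$k, 0)
})

test_that("pair table corrects by the number of evaluated pairs", {
  scn <- generate_scenario(seed = 2)
  sys <- ocg_cluster(scn$network)
  ac <- annotate_clusters(sys, scn$annotations, scn$dag)
  pt <- suppressMessages(build_pair_table(ac, scn$network, scn$annotations))
  n_tests <- attr(pt, "n_tests")
  expect_equal(nrow(pt), n_tests)
  expect_equal(pt$e_annot, pmin(1, pt$p_annot * n_tests))
  expect_equal(pt$e_inter, pmin(1, pt$p_inter * n_tests))
  expect_identical(pt$dissimilar, pt$e_annot <= 0.05 & pt$e_inter <= 0.05)
  # symmetric storage: each unordered pair appears exactly once
  expect_false(any(duplicated(paste(pmin(pt$go1, pt$go2), pmax(pt$go1, pt$go2)))))

  # a single tested pair has e = p
  dag <- go_dag(list(G1 = "R", G2 = "R", Fa = "R", Fb = "R"))
  g <- graph_from_pairs("A-B")
  ann <- annotation_map(c("A", "A", "B", "B"), c("G1", "Fa", "G2", "Fb"), dag)
  pt1 <- build_pair_table(NULL, g, ann, terms = c("G1", "G2"))
  expect_equal(nrow(pt1), 1L)
  expect_equal(pt1$e_annot, pt1$p_annot)
})

test_that("zero-margin pairs are skipped and excluded from n_tests", {
  dag <- go_dag(list(G1 = "R", G2 = "R", G3 = "R", Fa = "R", Fb = "R"))
  g <- graph_from_pairs("A-B")
  ann <- annotation_map(c("A", "A", "B", "B"), c("G1", "Fa", "G2", "Fb"), dag)
  # G3 annotates nobody: its pairs are dropped, only (G1,G2) counted
  expect_message(pt <- build_pair_table(NULL, g, ann, terms = c("G1", "G2", "G3")),
                 "skipped 2")
  expect_equal(attr(pt, "n_tests"), 1L)
  expect_error(build_pair_table(NULL, g, ann, terms = "G1"), "fewer than 2")
})
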