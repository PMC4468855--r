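# Group assignment, topology features and group comparisons.

# independent betweenness oracle: enumerate all shortest paths explicitly
betweenness_oracle <- function(g) {
  nodes <- igraph::V(g)$name
  btw <- stats::setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, nodes[i], nodes[j])$vpaths)
      if (!length(paths)) next
      inner <- unlist(lapply(paths, function(p) setdiff(names(p), c(nodes[i], nodes[j]))))
      if (length(inner)) {
        tab <- table(inner) / length(paths)
        btw[names(tab)] <- btw[names(tab)] + tab
      }
    }
  }
  btw
}

test_that("hub threshold defaults to twice the mean degree, rounded up", {
  star <- igraph::make_star(11, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", sprintf("leaf%02d", 1:10))
  sys <- cluster_system(list(igraph::V(star)$name))
  g <- assign_groups(star, sys, candidates = character(0))
  # mean degree 20/11, threshold ceil(3.64) = 4: only the center qualifies
  expect_equal(attr(g, "hub_threshold"), 4)
  expect_identical(g$hubs, "hub")
  g25 <- assign_groups(star, sys, character(0), hub_threshold = 25)
  expect_length(g25$hubs, 0L)
})

test_that("group invariants hold and candidates must be network nodes", {
  sys <- ocg_cluster(bowtie_graph())
  g <- assign_groups(bowtie_graph(), sys, candidates = "c")
  expect_setequal(g$mono, c("a", "b", "d", "e"))
  expect_identical(g$multi, "c")
  expect_setequal(c(g$multi, g$mono), g$all)
  expect_length(intersect(g$multi, g$mono), 0L)
  expect_true(all(g$cands %in% g$multi))
  expect_setequal(g$multi_nc, setdiff(g$multi, g$cands))
  expect_setequal(g$nc, setdiff(g$all, g$cands))
  expect_error(assign_groups(bowtie_graph(), sys, "zz"), "outside the network")
})

test_that("betweenness follows the unordered endpoint-excluded convention", {
  path3 <- graph_from_pairs("a-b", "b-c")
  ft <- topology_features(path3)
  expect_equal(ft$betweenness[ft$protein == "b"], 1)
  expect_equal(ft$betweenness[ft$protein != "b"], c(0, 0))
  c4 <- graph_from_pairs("a-b", "b-c", "c-d", "d-a")
  ft4 <- topology_features(c4)
  expect_equal(ft4$betweenness, rep(0.5, 4))  # two tied geodesics split
})

test_that("betweenness and degree match the brute-force oracle on small graphs", {
  set.seed(71)
  for (rep in 1:5) {
    g <- igraph::sample_gnp(sample(5:8, 1), 0.5)
    igraph::V(g)$name <- sprintf("v%02d", seq_len(igraph::vcount(g)))
    ft <- topology_features(g)
    oracle <- betweenness_oracle(g)
    expect_equal(stats::setNames(ft$betweenness, ft$protein),
                 oracle[ft$protein], tolerance = 1e-10)
    expect_equal(stats::setNames(ft$degree, ft$protein),
                 stats::setNames(as.numeric(igraph::degree(g)[ft$protein]), ft$protein))
  }
})

test_that("feature table carries cluster counts and annotation counts", {
  scn <- generate_scenario(n_modules = 2, sizes = c(4, 4), p_out = 0,
                           n_shared_nodes = 1, seed = 2)
  sys <- ocg_cluster(scn$network)
  ft <- topology_features(scn$network, sys, scn$annotations)
  mc <- membership_counts(sys)
  expect_equal(stats::setNames(ft$n_clusters, ft$protein), mc[ft$protein] + 0)
  expect_true(all(ft$n_bp_annotations >= 1))
  merged <- add_feature_columns(ft, data.frame(protein = ft$protein[1],
                                               disorder = 0.5))
  expect_equal(merged$disorder[merged$protein == ft$protein[1]], 0.5)
  expect_true(all(is.na(merged$disorder[-match(ft$protein[1], merged$protein)])))
})

test_that("group shortest paths average over reachable unordered pairs", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(group_shortest_paths(k4, letters[1:4])$mean, 1)
  path3 <- graph_from_pairs("a-b", "b-c")
  expect_equal(group_shortest_paths(path3, c("a", "c"))$mean, 2)
  two <- graph_from_pairs("a-b", "x-y")
  r <- group_shortest_paths(two, c("a", "x"), c("b", "y"))
  expect_equal(r$mean, 1)
  expect_equal(r$n_unreachable, 2L)  # a-y and x-b cross components
  expect_error(group_shortest_paths(two, "a", "y"), "unreachable")
})

test_that("rank-sum comparison is exact for small samples and detects shifts", {
  ft <- data.frame(protein = sprintf("p%d", 1:6), v = 1:6)
  r <- compare_groups(ft, "v", sprintf("p%d", 1:3), sprintf("p%d", 4:6))
  expect_equal(r$p, 0.1)  # enumeration over C(6,3) = 20 rank assignments
  expect_equal(r$mean_a, 2)
  expect_equal(r$mean_b, 5)
  same <- compare_groups(ft, "v", sprintf("p%d", 1:3), sprintf("p%d", 1:3))
  expect_equal(same$p, 1)
  # p decreases with effect size on larger simulated samples
  set.seed(9)
  base <- data.frame(protein = sprintf("q%03d", 1:80),
                     v = c(stats::rnorm(40), stats::rnorm(40, 1)))
  shifted <- base
  shifted$v[41:80] <- shifted$v[41:80] + 2
  p1 <- compare_groups(base, "v", base$protein[1:40], base$protein[41:80])$p
  p2 <- compare_groups(shifted, "v", base$protein[1:40], base$protein[41:80])$p
  expect_lt(p2, p1)
  expect_error(compare_groups(ft, "v", character(0), "p1"), "empty group")
})

test_that("list enrichment reports fold per group including depletion", {
  uni <- sprintf("g%02d", 1:10)
  groups <- list(top = uni[1:5], rest = uni[6:10])
  gl <- uni[1:2]
  tab <- list_enrichment(groups, gl, uni)
  # list fully inside "top": fold = (2/ (5*2/10)) = 2 = |universe|/|group|
  expect_equal(tab$fold[tab$group == "top"], 2)
  expect_equal(tab$fold[tab$group == "rest"], 0)  # empty intersection
  expect_equal(tab$p[tab$group == "rest"], 1)
  # depletion direction: fold < 1 when underrepresented
  tab2 <- list_enrichment(list(big = uni[1:8]), uni[8:10], uni)
  expect_lt(tab2$fold, 1)
})
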