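# Centralities and network-level measures against closed forms and
# brute-force oracles.

star5 <- function() igraph::make_star(5, mode = "undirected", center = 1)
path3 <- function() igraph::make_graph(~ A - B - C)
cycle4 <- function() igraph::make_ring(4)
complete4 <- function() igraph::make_full_graph(4)

test_that("degree centrality matches closed forms", {
  d <- degree_centrality(star5())
  expect_equal(unname(sort(d, decreasing = TRUE)), c(4L, 1L, 1L, 1L, 1L))
  empty <- igraph::make_empty_graph(3, directed = FALSE)
  expect_equal(unname(degree_centrality(empty)), c(0L, 0L, 0L))
})

test_that("betweenness matches closed forms on path, star and cycle", {
  b <- betweenness_centrality(path3())
  expect_equal(unname(b), c(0, 1, 0))
  bs <- betweenness_centrality(star5())
  expect_equal(unname(sort(bs, decreasing = TRUE)), c(6, 0, 0, 0, 0))
  bc <- betweenness_centrality(cycle4())
  expect_equal(unname(bc), rep(0.5, 4))
})

test_that("eigenvector centrality matches analytic values", {
  ev <- eigenvector_centrality(complete4())
  expect_equal(unname(ev), rep(1, 4), tolerance = 1e-8)
  es <- eigenvector_centrality(star5())
  expect_equal(unname(sort(es, decreasing = TRUE)), c(1, rep(0.5, 4)),
               tolerance = 1e-8)
})

test_that("eigenvector output satisfies the eigen equation", {
  g <- rand_named_graph(12, 0.3)
  ev <- eigenvector_centrality(g)
  adj <- bf_adjacency(g)
  pos <- ev > 0
  if (any(pos)) {
    a <- adj[pos, pos, drop = FALSE]
    x <- ev[pos]
    lambda <- as.numeric(x %*% a %*% x / sum(x^2))
    expect_lt(max(abs(a %*% x - lambda * x)), 1e-6)
  }
})

test_that("eigenvector centrality is permutation equivariant", {
  set.seed(99)
  g <- rand_named_graph(10, 0.35)
  ev <- eigenvector_centrality(g)
  perm <- sample(10)
  g2 <- igraph::permute(g, perm)
  ev2 <- eigenvector_centrality(g2)
  expect_equal(ev2[names(ev)], ev, tolerance = 1e-8)
})

test_that("density and mean distance match hand enumeration", {
  expect_equal(net_density(complete4()), 1)
  expect_equal(net_mean_distance(complete4()), 1)
  expect_equal(net_density(path3()), 2 / 3)
  expect_equal(net_mean_distance(path3()), 4 / 3)
  # two disjoint edges: connected pairs only
  g <- igraph::graph_from_literal(A - B, C - D)
  expect_equal(net_density(g), 1 / 3)
  expect_equal(net_mean_distance(g), 1)
  expect_error(net_density(igraph::make_empty_graph(1, directed = FALSE)),
               "undefined")
})

test_that("degrees sum to twice the edge count", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- rand_named_graph(15, 0.25)
    expect_equal(sum(degree_centrality(g)), 2 * igraph::ecount(g))
  }
})

test_that("all measures agree with brute force on random small graphs", {
  set.seed(1234)
  for (i in 1:40) {
    n <- sample(2:7, 1)
    g <- rand_named_graph(n, runif(1, 0.2, 0.9))
    adj <- bf_adjacency(g)
    expect_equal(unname(degree_centrality(g)), unname(bf_degree(adj)))
    expect_equal(unname(betweenness_centrality(g)), bf_betweenness(adj),
                 tolerance = 1e-8)
    expect_equal(suppressWarnings(unname(suppressMessages(
      eigenvector_centrality(g)))), bf_eigenvector(adj), tolerance = 1e-6)
    expect_equal(net_density(g), bf_density(adj))
    md <- suppressWarnings(net_mean_distance(g))
    expect_equal(md, bf_mean_distance(adj))
  }
})

test_that("adding an edge raises density and never raises mean distance", {
  set.seed(7)
  g <- rand_named_graph(8, 0.4)
  non_edges <- which(bf_adjacency(g) == 0, arr.ind = TRUE)
  non_edges <- non_edges[non_edges[, 1] < non_edges[, 2], , drop = FALSE]
  comp <- igraph::components(g)
  for (k in seq_len(min(5, nrow(non_edges)))) {
    i <- non_edges[k, 1]; j <- non_edges[k, 2]
    # restrict to pairs inside one component so the connected-pair set is
    # unchanged by the addition
    if (comp$membership[i] != comp$membership[j]) next
    g2 <- igraph::add_edges(g, c(i, j))
    expect_gt(net_density(g2), net_density(g))
    expect_lte(net_mean_distance(g2), net_mean_distance(g))
  }
})

test_that("the random-graph baseline is seeded, feasible and exact when forced", {
  base <- random_graph_baseline(4, 6, reps = 10, seed = 1)
  expect_equal(base$mean, 1)
  expect_equal(base$sd, 0)
  b1 <- random_graph_baseline(10, 15, reps = 30, seed = 9)
  b2 <- random_graph_baseline(10, 15, reps = 30, seed = 9)
  expect_identical(b1$values, b2$values)
  expect_error(random_graph_baseline(4, 7), "infeasible")
})

test_that("the G(n,m) baseline converges to the exhaustive enumeration value", {
  # all C(6,3) = 20 labelled graphs on 4 nodes with 3 edges
  pairs <- t(combn(4, 2))
  combos <- combn(6, 3)
  vals <- apply(combos, 2, function(idx) {
    adj <- matrix(0, 4, 4)
    for (e in idx) {
      adj[pairs[e, 1], pairs[e, 2]] <- 1
      adj[pairs[e, 2], pairs[e, 1]] <- 1
    }
    bf_mean_distance(adj)
  })
  exact <- mean(vals)
  base <- random_graph_baseline(4, 3, reps = 2000, seed = 3)
  mc_se <- base$sd / sqrt(2000)
  expect_lt(abs(base$mean - exact), 3 * mc_se + 1e-9)
})

test_that("specialty tie statistics match hand counts", {
  ds <- toy_claims(
    list(P1 = c("A", "B"), P2 = c("A", "B"), P3 = c("B", "C"),
         P4 = c("B", "C"), P5 = c("C", "D"), P6 = c("C", "D"),
         P7 = c("A", "D"), P8 = c("A", "D"), P9 = c("A", "C"),
         P10 = c("A", "C")),
    specialties = c(A = "general_practice", B = "general_practice",
                    C = "cardiology", D = "cardiology"))
  net <- build_practice_network(ds, threshold = 2)
  # edges: A-B (same, pcp), B-C, C-D (same, specialist), A-D, A-C -> 5 ties
  st <- specialty_tie_stats(net)
  expect_equal(st$pct_same_specialty, 100 * 2 / 5)
  expect_equal(st$pct_same_specialty_pcp, 50)
  # all nodes sharing one specialty gives 100%
  ds2 <- toy_claims(list(P1 = c("A", "B"), P2 = c("A", "B")),
                    specialties = c(A = "cardiology", B = "cardiology"))
  st2 <- specialty_tie_stats(build_practice_network(ds2, threshold = 1))
  expect_equal(st2$pct_same_specialty, 100)
  # no same-specialty edge: 0% and the second statistic is missing
  ds3 <- toy_claims(list(P1 = c("A", "B"), P2 = c("A", "B")),
                    specialties = c(A = "cardiology", B = "urology"))
  st3 <- specialty_tie_stats(build_practice_network(ds3, threshold = 1))
  expect_equal(st3$pct_same_specialty, 0)
  expect_true(is.na(st3$pct_same_specialty_pcp))
})
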