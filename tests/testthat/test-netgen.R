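test_that("ER generator hits edge-count limits and the target mean degree", {
  expect_equal(igraph::ecount(generate_er(10, 0, seed = 1)), 0)
  expect_equal(igraph::ecount(generate_er(10, 9, seed = 1)), 45)
  ks <- vapply(1:100, function(s) {
    mean(igraph::degree(generate_er(1000, 20, seed = s)))
  }, 0)
  # binomial expectation: mean degree 20, s.e. of the ensemble mean ~ 0.02
  expect_equal(mean(ks), 20, tolerance = 0.01)
  expect_error(generate_er(10, 12), "k_avg")
})

test_that("BA growth gives m*(n-m) edges, connectivity and heavy tails", {
  expect_equal(igraph::ecount(generate_ba(100, 2, seed = 1)), 99)
  expect_equal(igraph::ecount(generate_ba(4, 2, seed = 1)), 3)
  g <- generate_ba(500, 10, seed = 7)
  expect_equal(igraph::ecount(g), 5 * (500 - 5))
  expect_true(igraph::is_connected(g))
  expect_true(igraph::is_simple(g))
  maxdeg <- vapply(1:50, function(s) {
    c(ba = max(igraph::degree(generate_ba(300, 10, seed = s))),
      er = max(igraph::degree(generate_er(300, 10, seed = s))))
  }, c(ba = 0, er = 0))
  expect_gt(mean(maxdeg["ba", ]), 2 * mean(maxdeg["er", ]))
  expect_error(generate_ba(100, 3), "even")
})

test_that("WS lattice keeps M = n*k/2 and its closed-form transitivity", {
  g0 <- generate_ws(20, 4, 0, seed = 1)
  expect_equal(igraph::ecount(g0), 40)
  # ring lattice transitivity 3(k-2)/(4(k-1)) = 1/2 at k = 4
  expect_equal(graph_transitivity(g0), 0.5)
  g1 <- generate_ws(20, 4, 0.1, seed = 1)
  expect_equal(igraph::ecount(g1), 40)
  trans <- vapply(1:100, function(s) {
    graph_transitivity(generate_ws(200, 6, 1, seed = s))
  }, 0)
  # full rewiring: ER-level clustering ~ k/N
  expect_equal(mean(trans), 6 / 200, tolerance = 0.3)
  expect_error(generate_ws(20, 3, 0.1), "even")
})

test_that("dichotomous graphs realize the exact two-degree histogram", {
  g <- generate_dichotomous(100, 8, 24, seed = 1)
  expect_equal(sort(unique(igraph::degree(g))), c(8, 24))
  expect_equal(as.integer(table(igraph::degree(g))), c(50L, 50L))
  expect_true(igraph::is_connected(g))
  expect_true(igraph::is_simple(g))
  greg <- generate_dichotomous(100, 16, 16, seed = 2)
  expect_true(all(igraph::degree(greg) == 16))
  # population degree variance is exactly (k1-k2)^2/4 for any realization
  for (kp in list(c(16, 16), c(12, 20), c(4, 28))) {
    gi <- generate_dichotomous(200, kp[1], kp[2], seed = 3)
    d <- igraph::degree(gi)
    expect_equal(mean((d - mean(d))^2), (kp[1] - kp[2])^2 / 4)
  }
  expect_error(generate_dichotomous(101, 8, 24), "even")
})

test_that("SBM respects block structure and binomial edge counts", {
  sb <- generate_sbm(100, 1, 0, seed = 1)
  comp <- igraph::components(sb$graph)
  expect_equal(comp$no, 2)
  expect_equal(igraph::ecount(sb$graph), 2 * choose(50, 2))
  within_counts <- vapply(1:100, function(s) {
    x <- generate_sbm(100, 0.5, 0.15, seed = s)
    el <- igraph::as_edgelist(x$graph, names = FALSE)
    sum(x$blocks[el[, 1]] == x$blocks[el[, 2]])
  }, 0)
  mu <- 2 * 0.5 * choose(50, 2) # binomial expectation over both blocks
  sdm <- sqrt(2 * choose(50, 2) * 0.5 * 0.5) / sqrt(100)
  expect_lt(abs(mean(within_counts) - mu), 3 * sdm)
})

test_that("x-swap preserves degrees, simplicity and connectivity", {
  g <- generate_ws(200, 6, 0, seed = 5)
  expect_identical(igraph::as_edgelist(xswap_randomize(g, 0)),
                   igraph::as_edgelist(g))
  # K5: no admissible swap exists
  k5 <- igraph::make_full_graph(5)
  gx <- xswap_randomize(k5, 100, seed = 1)
  expect_equal(igraph::ecount(gx), 10)
  expect_true(igraph::is_simple(gx))
  expect_true(all(igraph::degree(gx) == 4))
  lower <- vapply(1:20, function(s) {
    ws <- generate_ws(200, 6, 0, seed = s)
    gr <- xswap_randomize(ws, 10 * igraph::ecount(ws), seed = 100 + s)
    expect_identical(sort(igraph::degree(gr)), sort(igraph::degree(ws)))
    expect_equal(igraph::ecount(gr), igraph::ecount(ws))
    expect_true(igraph::is_simple(gr))
    expect_true(igraph::is_connected(gr))
    graph_transitivity(gr) < graph_transitivity(ws)
  }, TRUE)
  expect_true(all(lower))
  expect_error(xswap_randomize(igraph::make_empty_graph(4, directed = FALSE), 10),
               "connected")
})

test_that("transitivity and modularity match brute-force enumeration (N <= 12)", {
  expect_equal(graph_transitivity(igraph::make_full_graph(3)), 1)
  expect_equal(graph_transitivity(igraph::make_star(5, mode = "undirected")), 0)
  # K4 minus one edge: 2 triangles, 8 triads
  k4m <- igraph::delete_edges(igraph::make_full_graph(4), 1)
  expect_equal(graph_transitivity(k4m), 0.75)
  set.seed(11)
  for (rep in 1:100) {
    g <- random_small_graph(sample(4:12, 1))
    expect_equal(graph_transitivity(g), brute_transitivity(g))
    blocks <- sample(c("A", "B"), igraph::vcount(g), replace = TRUE)
    expect_equal(newman_modularity(g, blocks), brute_modularity(g, blocks))
  }
})

test_that("modularity closed cases: disjoint cliques, one block, C4 split", {
  two_k50 <- igraph::disjoint_union(igraph::make_full_graph(50),
                                    igraph::make_full_graph(50))
  expect_equal(newman_modularity(two_k50, rep(c("A", "B"), each = 50)), 0.5)
  expect_equal(newman_modularity(two_k50, rep("A", 100)), 0)
  c4 <- igraph::make_ring(4)
  expect_equal(newman_modularity(c4, c("A", "A", "B", "B")), 0)
  expect_error(newman_modularity(igraph::make_empty_graph(3, directed = FALSE),
                                 rep("A", 3)), "empty")
})

test_that("expected SBM modularity: limits and Monte-Carlo agreement", {
  expect_equal(expected_sbm_modularity(100, 0.7, 0), 0.5)
  expect_equal(expected_sbm_modularity(2000, 0.3, 0.3), 0, tolerance = 1e-3)
  expect_error(expected_sbm_modularity(100, 0, 0), "undefined")
  for (pp in list(c(0.5, 0.15), c(0.2, 0.2), c(0.15, 0.5), c(0.7, 0.05))) {
    qs <- vapply(1:200, function(s) {
      x <- generate_sbm(100, pp[1], pp[2], seed = s)
      newman_modularity(x$graph, x$blocks)
    }, 0)
    se <- sd(qs) / sqrt(length(qs))
    expect_lt(abs(mean(qs) - expected_sbm_modularity(100, pp[1], pp[2])), 2 * se + 1e-3)
  }
})

test_that("summary metrics: complete graph and the two density conventions", {
  m <- summary_metrics(igraph::make_full_graph(10))
  expect_equal(m$transitivity, 1)
  expect_equal(m$aspl, 1)
  expect_equal(m$density_pairs, 1)
  expect_equal(m$density_mn2, 45 / 100)
  expect_equal(m$mean_degree, 9)
  g <- generate_er(40, 3, seed = 3) # typically disconnected
  expect_error(summary_metrics(g), "disconnected")
  m2 <- summary_metrics(g, on_disconnected = "largest-component")
  expect_true(is.finite(m2$aspl))
})
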