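make_net <- function(W) {
  # wrap a weight matrix as a minimal pcor_network for pathway functions
  structure(list(node_names = colnames(W), W = W, p = ncol(W),
                 n_edges = sum(abs(W[upper.tri(W)]) > 1e-8),
                 group_label = "", n = 100L),
            class = "pcor_network")
}

test_that("distance transform is the reciprocal absolute weight", {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- W["b", "a"] <- 0.25
  W["b", "c"] <- W["c", "b"] <- -0.5
  dg <- to_distance_graph(W)
  expect_equal(dg$D["a", "b"], 4)
  expect_equal(dg$D["b", "c"], 2)
  expect_identical(dg$D["a", "c"], Inf)
  expect_true(is.na(dg$D["a", "a"]))

  # stronger |w| => strictly shorter edge
  w <- seq(0.05, 0.95, by = 0.05)
  d <- 1 / w
  expect_true(all(diff(d) < 0))

  dg_u <- to_distance_graph(W, unweighted = TRUE)
  expect_equal(dg_u$D["a", "b"], 1)
  expect_equal(dg_u$D["b", "c"], 1)
})

test_that("dijkstra handles the textbook cases", {
  # triangle: indirect route wins
  D <- matrix(Inf, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  D["A", "B"] <- D["B", "A"] <- 1
  D["B", "C"] <- D["C", "B"] <- 1
  D["A", "C"] <- D["C", "A"] <- 3
  diag(D) <- NA
  sp <- dijkstra(D, "A")
  expect_equal(unname(sp$dist["C"]), 2)
  expect_equal(sp$pred[["C"]], 2) # through B

  # disconnected node
  D2 <- matrix(Inf, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  D2["A", "B"] <- D2["B", "A"] <- 5
  diag(D2) <- NA
  expect_identical(unname(dijkstra(D2, "A")$dist["C"]), Inf)

  # square with two co-optimal routes A-B-D and A-C-D
  D3 <- matrix(Inf, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  for (e in list(c("A", "B"), c("B", "D"), c("A", "C"), c("C", "D"))) {
    D3[e[1], e[2]] <- D3[e[2], e[1]] <- 1
  }
  diag(D3) <- NA
  sp3 <- dijkstra(D3, "A")
  expect_equal(unname(sp3$dist["D"]), 2)
  expect_equal(sort(sp3$pred[["D"]]), c(2, 3)) # both B and C

  expect_error(dijkstra(D3, "Z"), "valid nodes")
})

test_that("dijkstra agrees with exhaustive simple-path enumeration", {
  set.seed(99)
  for (rep in 1:40) {
    p <- sample(4:7, 1)
    W <- random_connected_weights(p)
    dg <- to_distance_graph(W)
    pw <- shortest_pathways(make_net(W), sources = "n1",
                            targets = paste0("n", p))
    r <- pw$pairs[[1]]
    oracle <- brute_force_shortest(dg$D, 1, p)
    expect_equal(r$distance, oracle$dist, tolerance = 1e-12)
    got <- lapply(r$paths, function(nm) match(nm, colnames(W)))
    expect_identical(got, oracle$paths)
  }
})

test_that("co-optimal paths are all reported with equal total distance", {
  W <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  for (e in list(c("A", "B"), c("B", "D"), c("A", "C"), c("C", "D"))) {
    W[e[1], e[2]] <- W[e[2], e[1]] <- 0.5
  }
  pw <- shortest_pathways(make_net(W), sources = "A", targets = "D")
  r <- pw$pairs[["A->D"]]
  expect_length(r$paths, 2)
  dists <- vapply(r$edges, function(e) sum(e$distance), 0)
  expect_lt(diff(range(dists)), 1e-9)
  # deterministic ordering by node-index sequence: A-B-D before A-C-D
  expect_equal(r$paths[[1]], c("A", "B", "D"))
  # consecutive nodes share a present edge; distance equals sum of 1/|w|
  expect_equal(r$distance, 4)
})

test_that("pathway results are equivariant under node relabeling", {
  set.seed(17)
  W <- random_connected_weights(6)
  pw1 <- shortest_pathways(make_net(W), sources = "n1", targets = "n6")
  perm <- sample(6)
  Wp <- W[perm, perm]
  pw2 <- shortest_pathways(make_net(Wp), sources = "n1", targets = "n6")
  r1 <- pw1$pairs[["n1->n6"]]
  r2 <- pw2$pairs[["n1->n6"]]
  expect_equal(r1$distance, r2$distance)
  expect_setequal(vapply(r1$paths, paste, "", collapse = "-"),
                  vapply(r2$paths, paste, "", collapse = "-"))
})

test_that("dijkstra agrees with igraph on weighted networks", {
  set.seed(4)
  for (rep in 1:10) {
    W <- random_connected_weights(7)
    dg <- to_distance_graph(W)
    g <- igraph::graph_from_adjacency_matrix(abs(W) > 1e-8, mode = "undirected")
    el <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$weight <- 1 / abs(W[el])
    ref <- igraph::distances(g, v = 1)[1, ]
    got <- dijkstra(dg, 1)$dist
    expect_equal(unname(got), unname(ref), tolerance = 1e-10)
  }
})

test_that("unreachable pairs are flagged, not errors", {
  W <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  pw <- shortest_pathways(make_net(W), sources = "A", targets = c("B", "C"))
  expect_false(pw$pairs[["A->B"]]$reachable)
  expect_identical(pw$pairs[["A->B"]]$distance, Inf)
  expect_equal(nrow(pw$union_edges), 0)
})

test_that("planted BN pathways are recovered from data at n = 2000", {
  spec <- planted_topology_spec("BN", n_subjects = 2000, seed = 5)
  net <- estimate_network(generate_dataset(spec))
  pw <- shortest_pathways(net)
  for (src in cm_nodes()) {
    expect_true(path_traverses(pw, src, "body_dissatisfaction",
                               c("emotional_abuse", "ineffectiveness")))
    expect_true(path_traverses(pw, src, "bulimia",
                               c("emotional_abuse", "ineffectiveness",
                                 "interoceptive_awareness")))
  }
})

test_that("planted BED pathways run through impulsivity", {
  spec <- planted_topology_spec("BED", n_subjects = 2000, seed = 5)
  net <- estimate_network(generate_dataset(spec))
  pw <- shortest_pathways(net)
  expect_true(path_traverses(pw, "emotional_abuse", "bulimia",
                             c("impulsivity", "interoceptive_awareness")))
  expect_true(path_traverses(pw, "emotional_abuse", "body_dissatisfaction",
                             c("impulsivity", "ineffectiveness")))
})

test_that("pathway input validation", {
  W <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  W["A", "B"] <- W["B", "A"] <- 0.3
  expect_error(shortest_pathways(make_net(W), sources = "A", targets = "A"),
               "disjoint")
  expect_error(shortest_pathways(make_net(W), sources = "Q", targets = "A"),
               "unknown node")
})
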