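test_that("pcor_to_precision matches the hand-computed relation", {
  # identity: no conditional dependence
  expect_equal(pcor_to_precision(diag(3)), diag(3))

  # 2 nodes, P12 = 0.5, conditional precisions 2: K_12 = -0.5 * sqrt(4) = -1
  P <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(pcor_to_precision(P, diag_scale = c(2, 2)),
               matrix(c(2, -1, -1, 2), 2))

  # infeasible: equal-weight 3-cycle at 0.999 has eigenvalue 1 - 2*0.999 < 0
  P3 <- matrix(0.999, 3, 3); diag(P3) <- 1
  expect_error(pcor_to_precision(P3), "infeasible partial correlation")

  # malformed inputs
  expect_error(pcor_to_precision(matrix(c(1, 0.2, 0.3, 1), 2)), "symmetric")
  expect_error(pcor_to_precision(diag(2) * 2), "unit diagonal")
})

test_that("precision -> pcor -> precision round-trips for feasible structures", {
  set.seed(42)
  for (rep in 1:20) {
    p <- sample(4:10, 1)
    spec <- random_topology_spec(p, min(p, 2 * p - 4), n_subjects = 10,
                                 seed = rep)
    P <- spec$true_partial_corr
    K <- pcor_to_precision(P, diag_scale = runif(p, 0.5, 3))
    expect_lt(max(abs(precision_to_pcor(K) - P)), 1e-10)
  }
})

test_that("generate_dataset is a pure function of the spec", {
  spec <- planted_topology_spec("BN", n_subjects = 60, seed = 9)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$scores, d2$scores)
  d3 <- generate_dataset(planted_topology_spec("BN", n_subjects = 60, seed = 10))
  expect_false(identical(d1$scores, d3$scores))

  # the global RNG stream is untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_dataset(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("generate_dataset respects bounds, integrality and sample-size contract", {
  spec <- planted_topology_spec("BED", n_subjects = 200, seed = 4)
  d <- generate_dataset(spec)
  expect_true(all(d$scores == round(d$scores)))
  expect_true(all(t(d$scores) >= spec$score_bounds[, 1]))
  expect_true(all(t(d$scores) <= spec$score_bounds[, 2]))
  expect_equal(d$group_label, "BED")
  bad <- spec; bad$n_subjects <- 1L
  expect_error(generate_dataset(bad), "degenerate sample")
})

test_that("identity truth yields near-zero pairwise correlations at large n", {
  d <- generate_dataset(null_spec(p = 8, n = 5000, seed = 77))
  S <- correlation_matrix(d)$S
  expect_lt(max(abs(S[upper.tri(S)])), 0.05)
})

test_that("marginal means and SDs track the spec at large n with wide bounds", {
  p <- 6
  spec <- synthetic_spec(paste0("V", 1:p), diag(p),
                         means = c(10, 12, 8, 15, 9, 11),
                         sds = c(4, 5, 3, 6, 4, 5),
                         score_bounds = cbind(rep(-500L, p), rep(500L, p)),
                         n_subjects = 20000, seed = 31)
  d <- generate_dataset(spec)
  expect_lt(max(abs(colMeans(d$scores) - spec$means) / spec$means), 0.02)
  expect_lt(max(abs(apply(d$scores, 2, sd) - spec$sds) / spec$sds), 0.02)
})

test_that("a planted edge is recovered by direct inversion at large n", {
  nodes <- subscale_nodes()
  P <- diag(16); dimnames(P) <- list(nodes$name, nodes$name)
  P["emotional_abuse", "ineffectiveness"] <-
    P["ineffectiveness", "emotional_abuse"] <- 0.4
  spec <- synthetic_spec(nodes$name, P, means = 50, sds = 10,
                         score_bounds = cbind(rep(-500L, 16), rep(500L, 16)),
                         n_subjects = 5000, seed = 13)
  S <- correlation_matrix(generate_dataset(spec))$S
  pc <- precision_to_pcor(solve(S))
  expect_gt(pc["emotional_abuse", "ineffectiveness"], 0.3)
  expect_lt(pc["emotional_abuse", "ineffectiveness"], 0.5)
})

test_that("planted BN/BED topologies contain the expected ground-truth edges", {
  bn <- planted_topology_spec("BN")
  P <- bn$true_partial_corr
  expect_gt(P["emotional_abuse", "ineffectiveness"], 0)
  expect_gt(P["ineffectiveness", "body_dissatisfaction"], 0)
  expect_gt(P["interoceptive_awareness", "bulimia"], 0)
  expect_equal(P["emotional_abuse", "impulsivity"], 0)
  expect_equal(bn$n_subjects, 181L)

  bed <- planted_topology_spec("BED")
  Q <- bed$true_partial_corr
  expect_gt(Q["emotional_abuse", "impulsivity"], 0)
  expect_gt(Q["impulsivity", "ineffectiveness"], 0)
  expect_equal(Q["emotional_abuse", "ineffectiveness"], 0)
  expect_equal(bed$n_subjects, 144L)

  # marginal defaults carry the group values
  expect_equal(unname(bn$means["ineffectiveness"]), 12.85)
  expect_equal(unname(bn$sds["ineffectiveness"]), 7.89)
  expect_equal(unname(bed$means["body_dissatisfaction"]), 18.88)

  expect_error(planted_topology_spec("AN"), "valid labels")
})

test_that("score bounds must be ordered and sds positive", {
  expect_error(
    synthetic_spec("a", matrix(1), means = 0, sds = 1,
                   score_bounds = cbind(5L, 5L), n_subjects = 10),
    "min < max")
  expect_error(
    synthetic_spec(c("a", "b"), diag(2), means = 0, sds = c(1, 0),
                   score_bounds = cbind(c(0L, 0L), c(9L, 9L)), n_subjects = 10),
    "positive")
})
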