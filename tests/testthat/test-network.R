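test_that("correlation_matrix validates input and flags perfect correlation", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 1, 3, 2))
  S <- suppressWarnings(correlation_matrix(X))
  expect_equal(S$S["a", "b"], 1)
  expect_error(correlation_matrix(cbind(a = rep(2, 5), b = 1:5)),
               "zero-variance.*a")
  expect_error(correlation_matrix(X[1:2, ]), "insufficient sample")
})

test_that("spearman correlations are rank-based", {
  set.seed(5)
  x <- rnorm(50); y <- exp(x) + rnorm(50, sd = 0.01) # monotone, nonlinear
  S <- correlation_matrix(cbind(a = x, b = y), method = "spearman")
  expect_gt(S$S["a", "b"], 0.99)
})

test_that("lambda_grid is log-spaced between lambda_max and its min_ratio multiple", {
  S <- diag(3); S[1, 2] <- S[2, 1] <- 0.6
  g <- lambda_grid(S, n_lambda = 100, min_ratio = 0.01)
  expect_equal(g$lambdas[1], 0.6)
  expect_equal(g$lambdas[100], 0.006)
  ratios <- g$lambdas[-1] / g$lambdas[-100]
  expect_lt(diff(range(ratios)), 1e-12)
  expect_true(all(diff(g$lambdas) < 0))

  g2 <- lambda_grid(matrix(c(1, 0.4, 0.4, 1), 2), n_lambda = 2, min_ratio = 0.5)
  expect_equal(g2$lambdas, c(0.4, 0.2))

  expect_error(lambda_grid(diag(4)), "empty model")
})

test_that("precision_to_pcor implements the standardized negation", {
  K <- matrix(c(2, -1, 0, -1, 2, -1, 0, -1, 2), 3)
  P <- precision_to_pcor(K)
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[1, 3], 0)
  expect_equal(P[2, 3], 0.5)
  expect_equal(precision_to_pcor(diag(4)), diag(4))
  expect_equal(precision_to_pcor(matrix(c(4, 2, 2, 4), 2))[1, 2], -0.5)
  expect_error(precision_to_pcor(matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("glasso is diagonal at lambda_max and matches inversion when unpenalized", {
  set.seed(2)
  spec <- random_topology_spec(6, 5, n_subjects = 400, seed = 21)
  cm <- correlation_matrix(generate_dataset(spec))
  lmax <- max(abs(cm$S[upper.tri(cm$S)]))

  fit <- glasso_path(cm, c(lmax, 1e-6))
  expect_equal(fit$edges[1], 0)
  expect_true(all(abs(fit$K[[1]][upper.tri(fit$K[[1]])]) < 1e-8))
  # stationarity of the diagonal: K_ii = 1 / S_ii for the empty model
  expect_equal(diag(fit$K[[1]]), 1 / diag(cm$S), tolerance = 1e-6,
               ignore_attr = TRUE)

  oracle <- precision_to_pcor(solve(cm$S))
  expect_lt(max(abs(fit$P[[2]] - oracle)), 1e-4)
})

test_that("glasso on an identity matrix returns the identity at any penalty", {
  fit <- glasso_path(diag(5), c(0.5, 0.1, 0.01), n = 100)
  for (K in fit$K) expect_equal(K, diag(5), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$edges, c(0L, 0L, 0L))
})

test_that("edge counts are non-increasing in lambda on fixtures", {
  # asserted on well-conditioned fixtures; not a theorem for glasso paths,
  # and near-threshold flips can occur at the dense end for small n
  for (s in 1:5) {
    spec <- random_topology_spec(10, 10, n_subjects = 800, seed = s)
    cm <- correlation_matrix(generate_dataset(spec))
    fit <- glasso_path(cm, lambda_grid(cm, n_lambda = 40))
    expect_true(all(diff(fit$edges) >= 0)) # lambdas decrease along the path
  }
})

test_that("ebic implements -2L + E log n + 4 E gamma log p", {
  expect_equal(ebic(-150, 0, 100, 16, 0.5), 300)
  expect_equal(ebic(-150, 0, 100, 16, 2), 300)
  # gamma = 0 is plain BIC
  expect_equal(ebic(-10, 4, 50, 8, 0), 20 + 4 * log(50))
  expect_equal(ebic(-150, 3, 100, 16, 0.5),
               300 + 3 * log(100) + 6 * log(16))
  expect_equal(ebic(-150, 3, 100, 16, 0.5), 330.4528, tolerance = 1e-4)
  expect_error(ebic(-10, -1, 50, 8, 0.5), "nonnegative")
})

test_that("select_network takes the EBIC argmin with ties to the sparser model", {
  spec <- random_topology_spec(8, 6, n_subjects = 400, seed = 3)
  cm <- correlation_matrix(generate_dataset(spec))
  fit <- glasso_path(cm, lambda_grid(cm))
  net <- select_network(fit)
  scores <- ebic(fit$loglik, fit$edges, fit$n, fit$p, fit$gamma)
  expect_equal(net$lambda_index, which.min(scores))
  expect_equal(net$lambda_selected, fit$lambdas[which.min(scores)])

  # synthetic tie: duplicate the path entry; the larger lambda must win
  tied <- fit
  tied$lambdas <- c(0.5, 0.25)
  tied$loglik <- c(-100, -100)
  tied$edges <- c(2L, 2L)
  tied$P <- fit$P[c(1, 1)]
  tied$K <- fit$K[c(1, 1)]
  expect_equal(select_network(tied)$lambda_selected, 0.5)
})

test_that("estimate_network recovers a planted edge and is deterministic", {
  spec <- planted_topology_spec("BN", n_subjects = 2000, seed = 11)
  d <- generate_dataset(spec)
  net1 <- estimate_network(d)
  net2 <- estimate_network(d)
  expect_identical(net1$W, net2$W)
  expect_gt(net1$W["emotional_abuse", "ineffectiveness"], 0)

  # type invariants
  expect_lt(max(abs(net1$W - t(net1$W))), 1e-10)
  expect_true(all(diag(net1$W) == 0))
  expect_true(all(abs(net1$W) < 1))
})

test_that("estimation succeeds when p exceeds n", {
  spec <- random_topology_spec(16, 10, n_subjects = 5, seed = 8)
  d <- generate_dataset(spec)
  net <- estimate_network(d)
  expect_s3_class(net, "pcor_network")
  expect_lte(net$n_edges, 16 * 15 / 2)
})

test_that("gamma = 0.5 never selects more edges than gamma = 0 on sparse truth", {
  worse <- 0
  for (s in 1:20) {
    spec <- random_topology_spec(10, 8, n_subjects = 300, seed = 100 + s)
    cm <- correlation_matrix(generate_dataset(spec))
    fit <- glasso_path(cm, lambda_grid(cm))
    e05 <- select_network(fit, gamma = 0.5)$n_edges
    e00 <- select_network(fit, gamma = 0)$n_edges
    expect_lte(e05, e00)
    worse <- worse + (e05 > e00)
  }
  expect_equal(worse, 0)
})

test_that("network accessors and refit behave", {
  spec <- planted_topology_spec("BED", n_subjects = 800, seed = 6)
  d <- generate_dataset(spec)
  net <- estimate_network(d)
  el <- coef(net)
  expect_equal(nrow(el), net$n_edges)
  expect_true(all(abs(el$weight) > 1e-8))

  refit <- estimate_network(d, refit = TRUE)
  # same support, weights no closer to zero on average (penalty removed)
  expect_equal(abs(refit$W) > 1e-8, abs(net$W) > 1e-8)
  expect_gte(mean(abs(refit$W[abs(net$W) > 1e-8])),
             mean(abs(net$W[abs(net$W) > 1e-8])))

  g <- as_igraph(net)
  expect_equal(igraph::gsize(g), net$n_edges)

  sims <- simulate(net, nsim = 2, seed = 1, n = 50)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), c(50, 16))
})
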