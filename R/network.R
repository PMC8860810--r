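#' Pairwise correlation matrix with PSD guarantee
#'
#' Computes the Pearson or Spearman correlation matrix of a subscale dataset.
#' If numerical noise leaves the smallest eigenvalue below -1e-8 the matrix is
#' repaired by eigenvalue clipping at zero followed by re-standardization to
#' unit diagonal; a repair is reported with a warning and recorded in the
#' result, never applied silently.
#'
#' @param data a [subscale_dataset()] or numeric matrix with column names.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `cor_matrix`: list with `S` (p x p), `method`,
#'   `n`, `repaired`.
#' @export
correlation_matrix <- function(data, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- if (inherits(data, "subscale_data")) data$scores else as.matrix(data)
  n <- nrow(X)
  if (n < 3) stop("insufficient sample: need at least 3 rows")
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(X)[v == 0], collapse = ", "))
  }
  S <- stats::cor(X, method = method)
  S <- (S + t(S)) / 2
  repaired <- FALSE
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    lam <- pmax(ev$values, 0)
    S <- ev$vectors %*% (lam * t(ev$vectors))
    S <- stats::cov2cor(S)
    S <- (S + t(S)) / 2
    dimnames(S) <- list(colnames(X), colnames(X))
    repaired <- TRUE
    warning("correlation matrix was not PSD; repaired by eigenvalue clipping")
  }
  structure(list(S = S, method = method, n = n, repaired = repaired),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat(sprintf("%s correlation matrix, p = %d, n = %d%s\n", x$method,
              ncol(x$S), x$n, if (x$repaired) " (PSD-repaired)" else ""))
  invisible(x)
}

#' Logarithmic penalty grid for the graphical lasso
#'
#' `n_lambda` penalties logarithmically spaced from
#' `lambda_max = max_{i != j} |S_ij|` (at which the glasso solution is exactly
#' diagonal) down to `lambda_max * min_ratio`, in decreasing order.
#'
#' @param S a [correlation_matrix()] result or plain symmetric matrix.
#' @param n_lambda grid size (default 100).
#' @param min_ratio `lambda_min / lambda_max` (default 0.01).
#' @return Object of class `lambda_path`: list with `lambdas`, `n_lambda`,
#'   `min_ratio`.
#' @export
lambda_grid <- function(S, n_lambda = 100L, min_ratio = 0.01) {
  if (inherits(S, "cor_matrix")) S <- S$S
  stopifnot(n_lambda >= 2, min_ratio > 0, min_ratio < 1)
  off <- abs(S[upper.tri(S)])
  lmax <- max(off)
  if (lmax == 0) stop("empty model at all penalties: all off-diagonals are zero")
  lambdas <- exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
  structure(list(lambdas = lambdas, n_lambda = as.integer(n_lambda),
                 min_ratio = min_ratio),
            class = "lambda_path")
}

#' Partial correlations from a precision matrix
#'
#' `P_ij = -K_ij / sqrt(K_ii K_jj)` off the diagonal, `P_ii = 1`: the
#' correlation between two variables after conditioning on all the others in
#' the Gaussian graphical model encoded by K.
#'
#' @param K symmetric positive definite precision matrix.
#' @return Symmetric partial-correlation matrix with unit diagonal.
#' @export
precision_to_pcor <- function(K) {
  K <- as.matrix(K)
  if (max(abs(K - t(K))) > 1e-8 * max(abs(K))) stop("`K` must be symmetric")
  if (any(diag(K) <= 0) ||
      min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("`K` must be positive definite")
  }
  d <- 1 / sqrt(diag(K))
  P <- -K * tcrossprod(d)
  diag(P) <- 1
  (P + t(P)) / 2
}

edge_count <- function(P, tol = 1e-8) sum(abs(P[upper.tri(P)]) > tol)

#' Graphical lasso solution path
#'
#' For each penalty in the grid, solves the l1-penalized Gaussian
#' maximum-likelihood problem
#' `max log det K - tr(S K) - lambda * sum_{i != j} |K_ij|`
#' (block coordinate descent on the covariance with a coordinate-descent
#' lasso inner solver, warm starts along the path), and records the precision
#' estimate, the partial-correlation matrix, the edge count (off-diagonals
#' with `|P_ij| > 1e-8`), the Gaussian log-likelihood
#' `L = (n/2)(log det K - tr(S K))`, and the EBIC for the chosen `gamma`.
#'
#' @param S a [correlation_matrix()] (supplies `n`), or a plain matrix (then
#'   pass `n`).
#' @param grid a [lambda_grid()], or a numeric vector of decreasing penalties.
#' @param n sample size if `S` is a plain matrix.
#' @param gamma EBIC hyperparameter used for the scores stored on the path.
#' @param tol relative convergence tolerance of the outer loop.
#' @param maxit maximum outer sweeps per penalty.
#' @return Object of class `glasso_path`: lists `K` and `P` (one matrix per
#'   penalty), vectors `lambdas`, `edges`, `loglik`, `ebic`, `iterations`,
#'   plus `n`, `p`, `gamma`.
#' @export
glasso_path <- function(S, grid, n = NULL, gamma = 0.5, tol = 1e-4,
                        maxit = 200L) {
  if (inherits(S, "cor_matrix")) {
    if (is.null(n)) n <- S$n
    S <- S$S
  }
  if (is.null(n)) stop("supply `n` when `S` is a plain matrix")
  lambdas <- if (inherits(grid, "lambda_path")) grid$lambdas else as.numeric(grid)
  stopifnot(all(lambdas > 0), !is.unsorted(rev(lambdas)))
  p <- ncol(S)
  fit <- .glasso_path_cpp(S, lambdas, tol, as.integer(maxit))
  if (!all(fit$converged)) {
    bad <- which(!fit$converged)[1]
    stop(sprintf("glasso did not converge at lambda = %.6g after %d iterations",
                 lambdas[bad], fit$iterations[bad]))
  }
  nm <- colnames(S)
  Ks <- vector("list", length(lambdas))
  Ps <- vector("list", length(lambdas))
  E <- integer(length(lambdas))
  L <- numeric(length(lambdas))
  for (l in seq_along(lambdas)) {
    K <- fit$K[, , l]
    dimnames(K) <- list(nm, nm)
    ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) {
      stop(sprintf("glasso returned a non-PD precision at lambda = %.6g",
                   lambdas[l]))
    }
    P <- precision_to_pcor(K)
    Ks[[l]] <- K
    Ps[[l]] <- P
    E[l] <- edge_count(P)
    L[l] <- (n / 2) * (determinant(K, logarithm = TRUE)$modulus[1] -
                         sum(S * K))
  }
  structure(
    list(lambdas = lambdas, K = Ks, P = Ps, edges = E, loglik = L,
         ebic = ebic(L, E, n, p, gamma), iterations = fit$iterations,
         n = n, p = p, gamma = gamma, node_names = nm),
    class = "glasso_path"
  )
}

#' @export
print.glasso_path <- function(x, ...) {
  cat(sprintf("glasso path: %d penalties, p = %d, n = %d; edges %d..%d\n",
              length(x$lambdas), x$p, x$n, min(x$edges), max(x$edges)))
  invisible(x)
}

#' Extended Bayesian Information Criterion
#'
#' `EBIC = -2 L + E log(n) + 4 E gamma log(p)`, where E is the number of
#' edges (free off-diagonal parameters). `gamma = 0` recovers the ordinary
#' BIC; `gamma = 0.5`, the conventional default in regularized network
#' estimation, penalizes dense graphs more heavily.
#'
#' @param L Gaussian log-likelihood(s).
#' @param E edge count(s), nonnegative.
#' @param n sample size.
#' @param p number of nodes.
#' @param gamma nonnegative hyperparameter.
#' @return Numeric score(s); smaller is better.
#' @export
ebic <- function(L, E, n, p, gamma = 0.5) {
  stopifnot(n >= 2, p >= 2, gamma >= 0)
  if (any(E < 0)) stop("`E` must be nonnegative")
  -2 * L + E * log(n) + 4 * E * gamma * log(p)
}

#' Select the network minimizing EBIC along a glasso path
#'
#' Picks the penalty minimizing `EBIC(lambda; gamma)`; ties are broken toward
#' the larger penalty (the sparser model). The returned edge-weight matrix W
#' is the selected partial-correlation matrix with zeroed diagonal.
#'
#' @param fit a [glasso_path()].
#' @param gamma EBIC hyperparameter; defaults to the one stored on the path.
#' @param group_label carried into the result.
#' @return Object of class `pcor_network`; see [estimate_network()].
#' @export
select_network <- function(fit, gamma = NULL, group_label = "") {
  stopifnot(inherits(fit, "glasso_path"), length(fit$lambdas) >= 1)
  if (is.null(gamma)) gamma <- fit$gamma
  scores <- ebic(fit$loglik, fit$edges, fit$n, fit$p, gamma)
  best <- which.min(scores) # lambdas decreasing, which.min takes the first
                            # minimum = the largest lambda on ties
  W <- fit$P[[best]]
  diag(W) <- 0
  structure(
    list(node_names = fit$node_names, W = W, K = fit$K[[best]],
         lambda_selected = fit$lambdas[best], lambda_index = best,
         gamma = gamma, n = fit$n, p = fit$p,
         n_edges = fit$edges[best], ebic = scores[best],
         loglik = fit$loglik[best], group_label = group_label,
         path = list(lambdas = fit$lambdas, edges = fit$edges,
                     ebic = scores)),
    class = "pcor_network"
  )
}

#' Estimate a regularized partial-correlation network
#'
#' The full estimation chain for one group: correlation matrix, logarithmic
#' penalty grid, graphical-lasso solution path, EBIC model selection. This is
#' the package's central fitting function; the result is the network whose
#' edge weights are regularized partial correlations.
#'
#' @param data a [subscale_dataset()] or numeric matrix with column names.
#' @param method correlation type, `"pearson"` or `"spearman"`.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda,min_ratio penalty grid controls, see [lambda_grid()].
#' @param refit if TRUE, the selected sparsity pattern is refit without
#'   penalty (maximum likelihood restricted to the selected graph).
#' @return Object of class `pcor_network`: `W` (symmetric p x p edge-weight
#'   matrix, zero diagonal), `lambda_selected`, `gamma`, `n`, `n_edges`,
#'   metadata and the EBIC path. Methods: `print`, `summary`, `coef`
#'   (edge list), `plot`, `simulate`, [as_igraph()].
#' @export
#' @examples
#' spec <- planted_topology_spec("BN", n_subjects = 300, seed = 11)
#' net <- estimate_network(generate_dataset(spec))
#' net
#' head(coef(net))
estimate_network <- function(data, method = c("pearson", "spearman"),
                             gamma = 0.5, n_lambda = 100L, min_ratio = 0.01,
                             refit = FALSE) {
  method <- match.arg(method)
  cm <- correlation_matrix(data, method = method)
  grid <- lambda_grid(cm, n_lambda = n_lambda, min_ratio = min_ratio)
  fit <- glasso_path(cm, grid, gamma = gamma)
  group <- if (inherits(data, "subscale_data")) data$group_label else ""
  net <- select_network(fit, gamma = gamma, group_label = group)
  if (refit) net <- refit_unpenalized(net, cm)
  net$method <- method
  net$n_lambda <- as.integer(n_lambda)
  net$min_ratio <- min_ratio
  net$psd_repaired <- cm$repaired
  net$refit <- refit
  if (inherits(data, "subscale_data")) net$variable_role <- data$variable_role
  net
}

# ML refit restricted to the selected graph: iterative proportional scaling
# via glasso at a vanishing penalty on the selected submodel is overkill for
# these sizes; a simple constrained Newton through the covariance works.
refit_unpenalized <- function(net, cm) {
  S <- cm$S
  A <- abs(net$W) > 1e-8
  # coordinate updates of K over free entries (selected edges + diagonal)
  K <- net$K
  for (it in 1:200) {
    Kold <- K
    Sigma <- solve(K)
    for (j in seq_len(ncol(S))) {
      free <- which(A[, j])
      idx <- setdiff(seq_len(ncol(S)), j)
      # regression form: fit column j of Sigma to match S on free entries
      if (length(free)) {
        W11 <- Sigma[idx, idx, drop = FALSE]
        # solve for beta supported on `free` rows
        fi <- match(free, idx)
        b <- solve(W11[fi, fi, drop = FALSE], S[free, j])
        w12 <- W11[, fi, drop = FALSE] %*% b
        Sigma[idx, j] <- w12
        Sigma[j, idx] <- w12
      } else {
        Sigma[idx, j] <- 0
        Sigma[j, idx] <- 0
      }
    }
    K <- solve(Sigma)
    K[!A & !diag(ncol(S))] <- 0
    K <- (K + t(K)) / 2
    if (max(abs(K - Kold)) < 1e-8) break
  }
  P <- precision_to_pcor(K)
  diag(P) <- 0
  net$W <- P
  net$K <- K
  net
}

#' @export
print.pcor_network <- function(x, ...) {
  cat(sprintf("Regularized partial-correlation network%s\n",
              if (nzchar(x$group_label)) paste0(" (", x$group_label, ")") else ""))
  cat(sprintf("  nodes: %d, edges: %d of %d possible\n", x$p, x$n_edges,
              x$p * (x$p - 1) / 2))
  cat(sprintf("  n = %d, gamma = %g, lambda* = %.4g (grid index %d)\n",
              x$n, x$gamma, x$lambda_selected, x$lambda_index))
  invisible(x)
}

#' @export
summary.pcor_network <- function(object, ...) {
  el <- coef(object)
  cat(sprintf("Network '%s': %d nodes, %d edges, n = %d\n",
              object$group_label, object$p, object$n_edges, object$n))
  cat(sprintf("  EBIC(gamma = %g) = %.2f at lambda = %.4g\n", object$gamma,
              object$ebic, object$lambda_selected))
  if (nrow(el)) {
    cat("  strongest edges:\n")
    el <- el[order(-abs(el$weight)), , drop = FALSE]
    print(utils::head(el, 8), row.names = FALSE)
  } else {
    cat("  (empty network)\n")
  }
  invisible(object)
}

#' @export
coef.pcor_network <- function(object, ...) {
  W <- object$W
  ut <- which(upper.tri(W) & abs(W) > 1e-8, arr.ind = TRUE)
  data.frame(node_i = object$node_names[ut[, 1]],
             node_j = object$node_names[ut[, 2]],
             weight = W[ut], stringsAsFactors = FALSE)
}

#' Convert a fitted network to an igraph object
#'
#' @param net a `pcor_network`.
#' @return An undirected weighted igraph graph; edge attribute `weight` keeps
#'   the signed partial correlation.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "pcor_network"))
  g <- igraph::graph_from_adjacency_matrix(abs(net$W) > 1e-8, mode = "undirected")
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$weight <- net$W[cbind(el[, 1], el[, 2])]
  igraph::V(g)$name <- net$node_names
  g
}

#' @export
plot.pcor_network <- function(x, highlight = NULL, ...) {
  g <- as_igraph(x)
  w <- igraph::E(g)$weight
  role <- if (!is.null(x$variable_role)) x$variable_role[x$node_names] else rep("ED", x$p)
  set.seed(1)
  igraph::plot.igraph(
    g,
    layout = igraph::layout_with_fr(g, weights = abs(w) * 5 + 0.1),
    edge.width = abs(w) * 10,
    edge.color = ifelse(w > 0, "#2c7fb8", "#d95f02"),
    vertex.color = ifelse(role == "CM", "#fee08b", "#c7e9c0"),
    vertex.label.cex = 0.7, ...)
  invisible(x)
}

#' Simulate integer score datasets from a fitted network
#'
#' Draws new datasets from the Gaussian graphical model defined by the fitted
#' precision matrix, on the marginal scale of the data used for fitting
#' (column means/SDs are taken from the fit when available, otherwise
#' standard normal margins), rounded to integers.
#'
#' @param object a `pcor_network`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param n rows per dataset (defaults to the fitting n).
#' @param ... unused.
#' @return A list of `nsim` integer matrices.
#' @export
simulate.pcor_network <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- object$n
  Sigma <- stats::cov2cor(solve(object$K))
  R <- chol(Sigma)
  lapply(seq_len(nsim), function(i) {
    X <- matrix(stats::rnorm(n * object$p), n, object$p) %*% R
    colnames(X) <- object$node_names
    round_half_away(X * 10)
  })
}
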