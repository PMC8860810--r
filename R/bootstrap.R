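#' Nonparametric bootstrap of edge weights
#'
#' Case-resampling bootstrap of the full estimation chain: for each of `B`
#' replicates, subjects are resampled with replacement, the complete
#' correlation -> penalty grid -> graphical lasso -> EBIC selection pipeline
#' is re-run on the resample (the penalty is re-selected inside every
#' replicate unless `fix_lambda = TRUE`), and every edge weight is recorded.
#' Percentile confidence intervals summarize the replicate distribution.
#'
#' Replicate seeds are derived from the master seed by a counter-based scheme
#' so each replicate is reproducible independently of execution order.
#' Resamples containing a zero-variance column are redrawn (with a fresh
#' counter value); more than `10 * B` total redraws aborts.
#'
#' @param data a [subscale_dataset()] or numeric matrix.
#' @param B number of bootstrap replicates (the conventional accuracy
#'   analysis uses 2500).
#' @param seed master integer seed.
#' @param ci confidence level for the percentile interval (default 0.95).
#' @param fix_lambda if TRUE, reuse the full-data selected penalty in every
#'   replicate instead of re-selecting (faster, slightly anticonservative).
#' @param method,gamma,n_lambda,min_ratio passed to [estimate_network()].
#' @return Object of class `edge_boot`: a data.frame with one row per
#'   unordered node pair (`node_i`, `node_j`, `estimate`, `boot_mean`,
#'   `ci_low`, `ci_high`, `prop_nonzero`) and attributes `B`, `seed`, `ci`,
#'   `n_redraws`, `network` (the full-data fit).
#' @export
#' @examples
#' spec <- planted_topology_spec("BN", n_subjects = 200, seed = 3)
#' bt <- bootstrap_edges(generate_dataset(spec), B = 25, seed = 42)
#' summary(bt)
bootstrap_edges <- function(data, B = 2500L, seed = 1L, ci = 0.95,
                            fix_lambda = FALSE,
                            method = c("pearson", "spearman"), gamma = 0.5,
                            n_lambda = 100L, min_ratio = 0.01) {
  method <- match.arg(method)
  if (B < 1) stop("`B` must be >= 1")
  stopifnot(ci > 0, ci < 1)
  X <- if (inherits(data, "subscale_data")) data$scores else as.matrix(data)
  n <- nrow(X)
  p <- ncol(X)

  net <- estimate_network(data, method = method, gamma = gamma,
                          n_lambda = n_lambda, min_ratio = min_ratio)
  ut <- which(upper.tri(net$W), arr.ind = TRUE)
  n_pairs <- nrow(ut)
  boots <- matrix(NA_real_, n_pairs, B)

  fixed_lambdas <- if (fix_lambda) net$lambda_selected else NULL
  n_redraws <- 0L
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  for (b in seq_len(B)) {
    counter <- 0L
    repeat {
      set.seed(replicate_seed(seed, b, counter))
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      if (all(matrixStats_colVars(Xb) > 0)) break
      counter <- counter + 1L
      n_redraws <- n_redraws + 1L
      if (n_redraws > 10L * B) {
        stop("degenerate resampling: more than 10*B resamples had a zero-variance column")
      }
    }
    Wb <- boot_replicate_network(Xb, method, gamma, n_lambda, min_ratio,
                                 fixed_lambdas)
    boots[, b] <- Wb[ut]
  }

  alpha <- (1 - ci) / 2
  qs <- t(apply(boots, 1, stats::quantile, probs = c(alpha, 1 - alpha),
                type = 6, names = FALSE))
  out <- data.frame(
    node_i = net$node_names[ut[, 1]],
    node_j = net$node_names[ut[, 2]],
    estimate = net$W[ut],
    boot_mean = rowMeans(boots),
    ci_low = qs[, 1],
    ci_high = qs[, 2],
    prop_nonzero = rowMeans(abs(boots) > 1e-8),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("edge_boot", "data.frame"),
            B = as.integer(B), seed = as.integer(seed), ci = ci,
            n_redraws = n_redraws, network = net)
}

# deterministic per-replicate seed, kept within 32-bit integer range
replicate_seed <- function(master, b, counter = 0L) {
  s <- (as.double(master) * 2654435761 + as.double(b) * 40503 +
          as.double(counter) * 69427 + 11) %% 2147483629
  as.integer(s) + 1L
}

boot_replicate_network <- function(Xb, method, gamma, n_lambda, min_ratio,
                                   fixed_lambdas) {
  cm <- suppressWarnings(correlation_matrix(Xb, method = method))
  if (is.null(fixed_lambdas)) {
    grid <- lambda_grid(cm, n_lambda = n_lambda, min_ratio = min_ratio)
    fit <- glasso_path(cm, grid, gamma = gamma)
    net <- select_network(fit, gamma = gamma)
  } else {
    fit <- glasso_path(cm, fixed_lambdas, gamma = gamma)
    net <- select_network(fit, gamma = gamma)
  }
  net$W
}

matrixStats_colVars <- function(X) {
  mu <- colMeans(X)
  colMeans(X^2) - mu^2
}

#' @export
print.edge_boot <- function(x, ...) {
  cat(sprintf("Edge-weight bootstrap: %d pairs, B = %d, %g%% percentile CIs (seed %d)\n",
              nrow(x), attr(x, "B"), 100 * attr(x, "ci"), attr(x, "seed")))
  if (attr(x, "n_redraws") > 0) {
    cat(sprintf("  %d degenerate resamples redrawn\n", attr(x, "n_redraws")))
  }
  NextMethod()
}

#' @export
summary.edge_boot <- function(object, ...) {
  nz <- object[abs(object$estimate) > 1e-8, , drop = FALSE]
  cat(sprintf("Bootstrap of %d edges present in the full-data network (B = %d):\n",
              nrow(nz), attr(object, "B")))
  if (nrow(nz)) {
    nz <- nz[order(-abs(nz$estimate)), ]
    print(utils::head(nz, 10), row.names = FALSE, digits = 3)
    cat(sprintf("  median CI width (present edges): %.3f\n",
                stats::median(nz$ci_high - nz$ci_low)))
  }
  invisible(object)
}

#' @export
plot.edge_boot <- function(x, ...) {
  ord <- order(x$estimate)
  k <- nrow(x)
  graphics::plot(x$estimate[ord], seq_len(k), xlim = range(x$ci_low, x$ci_high),
                 pch = 19, cex = 0.5, xlab = "edge weight", ylab = "",
                 yaxt = "n", main = "Bootstrapped edge weights", ...)
  graphics::segments(x$ci_low[ord], seq_len(k), x$ci_high[ord], seq_len(k),
                     col = "grey60")
  graphics::points(x$boot_mean[ord], seq_len(k), pch = 4, cex = 0.5, col = "red")
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
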