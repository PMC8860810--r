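# shared fixtures and independent oracles

# brute force shortest paths by exhaustive enumeration of all simple paths;
# independent of the package's Dijkstra (used only as an oracle)
brute_force_shortest <- function(D, s, t) {
  p <- ncol(D)
  best <- list(dist = Inf, paths = list())
  walk <- function(path, d) {
    path <- as.integer(path)
    u <- path[length(path)]
    if (u == t) {
      if (d < best$dist - 1e-12) {
        best$dist <<- d
        best$paths <<- list(path)
      } else if (abs(d - best$dist) <= 1e-12) {
        best$paths <<- c(best$paths, list(path))
      }
      return()
    }
    for (v in seq_len(p)) {
      if (v %in% path) next
      if (!is.finite(D[u, v])) next
      walk(c(path, v), d + D[u, v])
    }
  }
  walk(s, 0)
  key <- vapply(best$paths, function(v) paste(sprintf("%04d", v), collapse = "."), "")
  best$paths <- best$paths[order(key)]
  best
}

# random symmetric weight matrix whose support is a connected graph
random_connected_weights <- function(p, extra_prob = 0.35) {
  W <- matrix(0, p, p)
  perm <- sample(p)
  for (k in 2:p) { # random spanning tree
    i <- perm[k]; j <- perm[sample(k - 1, 1)]
    W[i, j] <- W[j, i] <- stats::runif(1, 0.05, 0.6) * sample(c(-1, 1), 1)
  }
  ut <- which(upper.tri(W), arr.ind = TRUE)
  for (r in seq_len(nrow(ut))) {
    i <- ut[r, 1]; j <- ut[r, 2]
    if (W[i, j] == 0 && stats::runif(1) < extra_prob) {
      W[i, j] <- W[j, i] <- stats::runif(1, 0.05, 0.6) * sample(c(-1, 1), 1)
    }
  }
  colnames(W) <- rownames(W) <- paste0("n", seq_len(p))
  W
}

# identity-truth spec on p nodes at a continuous-like scale
null_spec <- function(p = 16, n = 500, seed = 1) {
  synthetic_spec(paste0("V", seq_len(p)), diag(p), means = 0, sds = 10,
                 score_bounds = cbind(rep(-1000L, p), rep(1000L, p)),
                 n_subjects = n, seed = seed)
}

# U statistic by direct enumeration of all n1*n2 pairs (oracle)
u_by_enumeration <- function(x, y) {
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  sum(cmp)
}
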