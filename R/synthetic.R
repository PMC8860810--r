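#' Build a precision matrix from a partial-correlation target
#'
#' Inverts the standard relation between a precision matrix K and the partial
#' correlations P (see [precision_to_pcor()]): given the target off-diagonal
#' partial correlations and per-variable conditional precisions `diag_scale`,
#' returns K with `K_ii = diag_scale_i` and
#' `K_ij = -P_ij * sqrt(K_ii * K_jj)` for `i != j`.
#'
#' Not every partial-correlation pattern is feasible: the resulting K must be
#' positive definite. Infeasible targets raise an error reporting the most
#' negative eigenvalue.
#'
#' @param P symmetric matrix, unit diagonal, off-diagonals in (-1, 1).
#' @param diag_scale positive per-variable conditional precisions (recycled);
#'   default 1 picks the canonical unit-conditional-variance representative.
#' @return Symmetric positive definite precision matrix.
#' @export
#' @examples
#' P <- diag(3); P[1, 2] <- P[2, 1] <- 0.5
#' K <- pcor_to_precision(P)
#' precision_to_pcor(K)[1, 2] # 0.5 back
pcor_to_precision <- function(P, diag_scale = 1) {
  P <- as.matrix(P)
  p <- nrow(P)
  stopifnot(p == ncol(P))
  if (max(abs(P - t(P))) > 1e-12) stop("`P` must be symmetric")
  if (max(abs(diag(P) - 1)) > 1e-12) stop("`P` must have unit diagonal")
  off <- P[upper.tri(P)]
  if (any(abs(off) >= 1)) stop("off-diagonal partial correlations must lie in (-1, 1)")
  diag_scale <- rep_len(diag_scale, p)
  if (any(diag_scale <= 0)) stop("`diag_scale` must be positive")
  d <- sqrt(diag_scale)
  K <- -P * tcrossprod(d)
  diag(K) <- diag_scale
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(abs(ev))) {
    stop(sprintf(
      "infeasible partial correlation structure: implied precision is not positive definite (most negative eigenvalue %.3e)",
      min(ev)))
  }
  K
}

#' Specify a synthetic questionnaire-data generator
#'
#' Bundles everything [generate_dataset()] needs: the planted sparse
#' partial-correlation graph (the ground truth for recovery testing), the
#' per-variable marginal locations/scales on the questionnaire score scale,
#' integer score bounds for clipping, the sample size, a group label and the
#' RNG seed.
#'
#' @param node_names character vector of variable names.
#' @param true_partial_corr symmetric matrix, unit diagonal, sparse
#'   off-diagonals in (-1, 1); the implied precision (unit conditional
#'   variances) must be positive definite.
#' @param means,sds per-variable marginal location and scale in score points
#'   (recycled).
#' @param score_bounds two-column matrix (min, max) per variable, or NULL for
#'   the canonical bounds of recognized names.
#' @param n_subjects number of participants to draw.
#' @param group_label free text (`"BN"`, `"BED"`, ...).
#' @param seed integer seed; the generator is a pure function of the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(node_names, true_partial_corr, means, sds,
                           score_bounds = NULL, n_subjects, group_label = "",
                           seed = 1L) {
  p <- length(node_names)
  P <- as.matrix(true_partial_corr)
  stopifnot(nrow(P) == p, ncol(P) == p)
  means <- rep_len(means, p)
  sds <- rep_len(sds, p)
  if (any(sds <= 0)) stop("`sds` must be positive")
  if (is.null(score_bounds)) {
    canon <- subscale_nodes()
    m <- match(node_names, canon$name)
    if (anyNA(m)) {
      score_bounds <- cbind(min = rep(-.Machine$integer.max / 2, p),
                            max = rep(.Machine$integer.max / 2, p))
    } else {
      score_bounds <- cbind(min = canon$min[m], max = canon$max[m])
    }
  } else {
    score_bounds <- as.matrix(score_bounds)
    stopifnot(nrow(score_bounds) == p, ncol(score_bounds) == 2)
  }
  if (any(score_bounds[, 1] >= score_bounds[, 2])) {
    stop("score_bounds must satisfy min < max for every variable")
  }
  # validates symmetry/diagonal/feasibility as a side effect
  pcor_to_precision(P)
  structure(
    list(node_names = node_names, true_partial_corr = P,
         means = stats::setNames(means, node_names),
         sds = stats::setNames(sds, node_names),
         score_bounds = score_bounds,
         n_subjects = as.integer(n_subjects),
         group_label = group_label, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  P <- x$true_partial_corr
  ne <- sum(abs(P[upper.tri(P)]) > 0)
  cat(sprintf(
    "Synthetic spec '%s': %d nodes, %d planted edges, n = %d, seed = %d\n",
    x$group_label, length(x$node_names), ne, x$n_subjects, x$seed))
  invisible(x)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Draw an integer subscale dataset from a planted graphical model
#'
#' Samples `n_subjects` latent vectors from the zero-mean multivariate normal
#' whose correlation structure is implied by the spec's partial-correlation
#' target (precision built with unit conditional variances, then standardized
#' to unit marginal variances), rescales by `sds`, shifts by `means`, rounds
#' half-away-from-zero to integer score points, and clips to the score
#' bounds. Identical specs (including seed) give bitwise-identical tables;
#' the global RNG state is left untouched.
#'
#' @param spec a [synthetic_spec()].
#' @return A [subscale_dataset()] with provenance `"synthetic"`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_subjects < 2) stop("degenerate sample: n_subjects must be >= 2")
  K <- pcor_to_precision(spec$true_partial_corr)
  Sigma <- stats::cov2cor(solve(K))
  R <- chol(Sigma)
  p <- length(spec$node_names)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  Z <- matrix(stats::rnorm(spec$n_subjects * p), spec$n_subjects, p)
  X <- Z %*% R
  X <- sweep(X, 2, spec$sds, `*`)
  X <- sweep(X, 2, spec$means, `+`)
  X <- round_half_away(X)
  X <- pmin(pmax(X, rep(spec$score_bounds[, 1], each = nrow(X))),
            rep(spec$score_bounds[, 2], each = nrow(X)))
  colnames(X) <- spec$node_names

  canon <- subscale_nodes()
  role <- canon$role[match(spec$node_names, canon$name)]
  if (anyNA(role)) role[is.na(role)] <- "ED"
  subscale_dataset(X, variable_role = role, group_label = spec$group_label,
                   provenance = "synthetic",
                   provenance_detail = sprintf("seed=%d", spec$seed))
}

# Group marginal targets (means, SDs) for the two clinical samples the
# generator emulates; score points on the EDI-2 / CTQ subscale scales.
reference_margins <- function(group = c("BN", "BED")) {
  group <- match.arg(group)
  bn <- c(
    ineffectiveness = 12.85, social_insecurity = 7.71, drive_for_thinness = 15.55,
    interoceptive_awareness = 14.02, maturity_fear = 8.75,
    body_dissatisfaction = 16.02, perfectionism = 7.23,
    interpersonal_distrust = 6.77, impulsivity = 9.86, bulimia = 10.58,
    asceticism = 9.23, emotional_neglect = 13.30, emotional_abuse = 10.21,
    sexual_abuse = 6.69, physical_neglect = 7.28, physical_abuse = 6.89)
  bn_sd <- c(7.89, 4.30, 5.27, 6.89, 5.72, 7.25, 4.60, 4.81, 7.22, 5.64, 4.46,
             4.83, 4.71, 3.61, 2.51, 3.08)
  bed <- c(
    ineffectiveness = 9.58, social_insecurity = 5.24, drive_for_thinness = 12.81,
    interoceptive_awareness = 8.54, maturity_fear = 6.68,
    body_dissatisfaction = 18.88, perfectionism = 6.03,
    interpersonal_distrust = 4.97, impulsivity = 5.43, bulimia = 8.13,
    asceticism = 6.61, emotional_neglect = 11.76, emotional_abuse = 9.96,
    sexual_abuse = 6.55, physical_neglect = 6.97, physical_abuse = 6.25)
  bed_sd <- c(7.32, 3.31, 5.63, 6.12, 5.02, 6.13, 4.43, 4.33, 5.17, 5.18, 3.68,
              4.90, 4.47, 3.34, 2.21, 2.51)
  if (group == "BN") list(means = bn, sds = stats::setNames(bn_sd, names(bn)), n = 181L)
  else list(means = bed, sds = stats::setNames(bed_sd, names(bed)), n = 144L)
}

planted_edge_list <- function(group) {
  cm_to_ea <- cbind(c("emotional_neglect", "sexual_abuse", "physical_neglect",
                      "physical_abuse"), "emotional_abuse")
  if (group == "BN") {
    chain <- rbind(
      c("emotional_abuse", "ineffectiveness"),
      c("ineffectiveness", "body_dissatisfaction"),
      c("ineffectiveness", "interoceptive_awareness"),
      c("interoceptive_awareness", "bulimia"))
  } else {
    chain <- rbind(
      c("emotional_abuse", "impulsivity"),
      c("impulsivity", "ineffectiveness"),
      c("ineffectiveness", "body_dissatisfaction"),
      c("impulsivity", "interoceptive_awareness"),
      c("interoceptive_awareness", "bulimia"))
  }
  # peripheral ED-ED associations at a fixed small weight: realistic density
  # that cannot shortcut the planted chains (see the methods vignette)
  background <- rbind(
    c("drive_for_thinness", "body_dissatisfaction"),
    c("drive_for_thinness", "asceticism"),
    c("perfectionism", "asceticism"),
    c("social_insecurity", "interpersonal_distrust"),
    c("social_insecurity", "ineffectiveness"),
    c("maturity_fear", "interpersonal_distrust"),
    if (group == "BN") c("impulsivity", "interoceptive_awareness") else NULL)
  rbind(
    data.frame(from = cm_to_ea[, 1], to = cm_to_ea[, 2], weight = 0.30),
    data.frame(from = chain[, 1], to = chain[, 2], weight = 0.40),
    data.frame(from = background[, 1], to = background[, 2], weight = 0.20))
}

#' Ready-made generator spec with the planted BN / BED network topology
#'
#' Returns a [synthetic_spec()] whose ground-truth graph reproduces the
#' qualitative pathway structure of the two clinical groups: all
#' maltreatment (CTQ) nodes converge on emotional abuse, and emotional abuse
#' reaches the ED-specific symptoms through ineffectiveness (BN) or through
#' impulsivity (BED), with interoceptive awareness on the route to bulimia in
#' both. Planted weights are strong enough to be detectable by EBIC-glasso at
#' the default clinical sample sizes. Peripheral ED-ED edges at a fixed small
#' weight (|w| = 0.20) add
#' realistic density without shortcutting the planted pathways. Marginal
#' means/SDs default to the clinical group values; sample sizes default to
#' 181 (BN) and 144 (BED).
#'
#' @param group `"BN"` or `"BED"`.
#' @param n_subjects sample size override.
#' @param seed integer seed.
#' @return A `synthetic_spec`.
#' @export
#' @examples
#' spec <- planted_topology_spec("BN", seed = 7)
#' spec$true_partial_corr["emotional_abuse", "ineffectiveness"]
planted_topology_spec <- function(group = c("BN", "BED"), n_subjects = NULL,
                                  seed = 1L) {
  if (length(group) == 1 && !group[1] %in% c("BN", "BED")) {
    stop(sprintf("unknown group label '%s'; valid labels: BN, BED", group[1]))
  }
  group <- match.arg(group)
  marg <- reference_margins(group)
  nodes <- subscale_nodes()
  p <- nrow(nodes)
  P <- diag(p)
  dimnames(P) <- list(nodes$name, nodes$name)
  ed <- planted_edge_list(group)
  for (i in seq_len(nrow(ed))) {
    P[ed$from[i], ed$to[i]] <- P[ed$to[i], ed$from[i]] <- ed$weight[i]
  }
  synthetic_spec(
    node_names = nodes$name, true_partial_corr = P,
    means = marg$means[nodes$name], sds = marg$sds[nodes$name],
    score_bounds = cbind(nodes$min, nodes$max),
    n_subjects = if (is.null(n_subjects)) marg$n else n_subjects,
    group_label = group, seed = seed)
}

#' Random sparse ground-truth spec for recovery experiments
#'
#' Plants `n_edges` edges uniformly at random among the `p(p-1)/2` pairs with
#' weights drawn from `weight_range` (random sign when `signed`), redrawing
#' until the implied precision is positive definite. Marginals default to a
#' wide continuous-like scale so that integer rounding attenuates the planted
#' structure negligibly.
#'
#' @param p number of nodes.
#' @param n_edges number of planted edges.
#' @param weight_range absolute partial-correlation magnitude range.
#' @param n_subjects sample size for [generate_dataset()].
#' @param seed integer seed (controls both topology and, via the spec, data).
#' @param signed draw negative weights with probability 1/2.
#' @param max_tries redraw budget before giving up.
#' @return A `synthetic_spec` with generic node names `V1..Vp`.
#' @export
random_topology_spec <- function(p, n_edges, weight_range = c(0.25, 0.35),
                                 n_subjects = 500L, seed = 1L, signed = TRUE,
                                 max_tries = 200L) {
  stopifnot(p >= 2, n_edges <= p * (p - 1) / 2)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  for (try in seq_len(max_tries)) {
    sel <- sample(nrow(pairs), n_edges)
    w <- stats::runif(n_edges, weight_range[1], weight_range[2])
    if (signed) w <- w * sample(c(-1, 1), n_edges, replace = TRUE)
    P <- diag(p)
    for (k in seq_len(n_edges)) {
      i <- pairs[sel[k], 1]; j <- pairs[sel[k], 2]
      P[i, j] <- P[j, i] <- w[k]
    }
    ok <- tryCatch({ pcor_to_precision(P); TRUE }, error = function(e) FALSE)
    if (ok) {
      nm <- paste0("V", seq_len(p))
      dimnames(P) <- list(nm, nm)
      return(synthetic_spec(
        node_names = nm, true_partial_corr = P, means = 0, sds = 10,
        score_bounds = cbind(rep(-1000L, p), rep(1000L, p)),
        n_subjects = n_subjects, group_label = "sim", seed = seed))
    }
  }
  stop("could not draw a positive definite sparse truth in `max_tries` tries")
}
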