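#' Mann-Whitney U test (group-1 convention)
#'
#' U is the number of pairs `(x_i, y_j)` with `x_i > y_j` plus half the tied
#' pairs — the group-1 statistic, so `U + U' = n1 * n2`. The two-sided
#' p-value uses the exact null distribution when there are no ties and
#' `n1 * n2 <= 400`, and otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y numeric score vectors for the two groups.
#' @return List with `U`, `p`, `method` (`"exact"` or `"normal"`), `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # U = 0
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (!has_ties && n1 * n2 <= 400) {
    # exact: P(|U - n1 n2 / 2| >= |u - n1 n2 / 2|) under the null
    lo <- min(U, n1 * n2 - U)
    p <- min(1, 2 * stats::pwilcox(lo, n1, n2))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    }
    method <- "normal"
  }
  list(U = U, p = min(p, 1), method = method, n1 = n1, n2 = n2)
}

#' CTQ occurrence cut-offs
#'
#' The conventional subscale cut-offs marking the occurrence of each
#' maltreatment type: emotional neglect >= 15, emotional abuse >= 10, sexual
#' abuse, physical neglect and physical abuse >= 8 (inclusive).
#'
#' @return Named integer vector of cut-off scores.
#' @export
cm_cutoffs <- function() {
  c(emotional_neglect = 15L, emotional_abuse = 10L, sexual_abuse = 8L,
    physical_neglect = 8L, physical_abuse = 8L)
}

#' Dichotomize maltreatment scores at occurrence cut-offs
#'
#' Flags, per subject and CM type, whether the subscale score meets or
#' exceeds the cut-off (inclusive `>=`).
#'
#' @param data a [subscale_dataset()] containing the CM columns.
#' @param cutoffs named vector of cut-off scores; default [cm_cutoffs()].
#' @return Logical matrix, subjects x CM types.
#' @export
dichotomize_cm <- function(data, cutoffs = cm_cutoffs()) {
  X <- if (inherits(data, "subscale_data")) data$scores else as.matrix(data)
  missing_cols <- setdiff(names(cutoffs), colnames(X))
  if (length(missing_cols)) {
    stop("missing CM column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- sapply(names(cutoffs), function(v) X[, v] >= cutoffs[[v]])
  matrix(out, nrow = nrow(X), dimnames = list(NULL, names(cutoffs)))
}

#' Pearson chi-squared test for a 2 x 2 table
#'
#' `X^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on one degree of freedom,
#' without continuity correction by default; `yates = TRUE` applies the Yates
#' correction `(|ad - bc| - n/2)` clipped at zero.
#'
#' @param a,b,c,d nonnegative cell counts, rows = condition, columns = group.
#' @param yates apply the continuity correction.
#' @return List with `statistic`, `p`, `df = 1`.
#' @export
#' @examples
#' chi_squared_2x2(76, 105, 43, 101)$statistic # ~5.08
chi_squared_2x2 <- function(a, b, c, d, yates = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be nonnegative")
  n <- sum(counts)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("zero margin in the 2x2 table")
  delta <- abs(a * d - b * c)
  if (yates) delta <- max(0, delta - n / 2)
  stat <- n * delta^2 / prod(margins)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Two-group descriptive comparison table
#'
#' The descriptive layout of a clinical characteristics table: per variable,
#' group means +/- SDs and the Mann-Whitney U with its two-sided p; and per
#' CM type, counts and percentages above the occurrence cut-off in each group
#' with the (uncorrected) chi-squared statistic and p.
#'
#' @param data1,data2 [subscale_dataset()] objects for the two groups (same
#'   variables).
#' @param cutoffs CM occurrence cut-offs, default [cm_cutoffs()].
#' @param yates continuity-correct the chi-squared tests.
#' @return Object of class `group_comparison`: list with `scores`
#'   (data.frame: variable, mean1, sd1, mean2, sd2, U, p) and `occurrence`
#'   (data.frame: cm_type, cutoff, count1, pct1, count2, pct2, chisq, p),
#'   plus the group labels and sizes.
#' @export
group_comparison <- function(data1, data2, cutoffs = cm_cutoffs(),
                             yates = FALSE) {
  stopifnot(inherits(data1, "subscale_data"), inherits(data2, "subscale_data"))
  if (!identical(data1$variable_names, data2$variable_names)) {
    stop("the two datasets must share the same variables in the same order")
  }
  X1 <- data1$scores; X2 <- data2$scores
  vars <- data1$variable_names
  sc <- do.call(rbind, lapply(vars, function(v) {
    mw <- mann_whitney(X1[, v], X2[, v])
    data.frame(variable = v,
               mean1 = mean(X1[, v]), sd1 = stats::sd(X1[, v]),
               mean2 = mean(X2[, v]), sd2 = stats::sd(X2[, v]),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  }))
  f1 <- dichotomize_cm(data1, cutoffs)
  f2 <- dichotomize_cm(data2, cutoffs)
  n1 <- nrow(X1); n2 <- nrow(X2)
  occ <- do.call(rbind, lapply(names(cutoffs), function(v) {
    c1 <- sum(f1[, v]); c2 <- sum(f2[, v])
    cs <- tryCatch(chi_squared_2x2(c1, n1 - c1, c2, n2 - c2, yates = yates),
                   error = function(e) list(statistic = NA_real_, p = NA_real_))
    data.frame(cm_type = v, cutoff = cutoffs[[v]],
               count1 = c1, pct1 = 100 * c1 / n1,
               count2 = c2, pct2 = 100 * c2 / n2,
               chisq = cs$statistic, p = cs$p, stringsAsFactors = FALSE)
  }))
  structure(list(scores = sc, occurrence = occ,
                 group1 = data1$group_label, group2 = data2$group_label,
                 n1 = n1, n2 = n2, cutoffs = cutoffs, yates = yates),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 2, ...) {
  cat(sprintf("Group comparison: %s (n = %d) vs %s (n = %d)\n",
              x$group1, x$n1, x$group2, x$n2))
  sc <- x$scores
  sc$mean1 <- sprintf("%.2f ± %.2f", sc$mean1, sc$sd1)
  sc$mean2 <- sprintf("%.2f ± %.2f", sc$mean2, sc$sd2)
  print(sc[, c("variable", "mean1", "mean2", "U", "p")], row.names = FALSE,
        digits = digits)
  cat("\nMaltreatment occurrence (score >= cut-off):\n")
  print(x$occurrence, row.names = FALSE, digits = digits)
  invisible(x)
}
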