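#' @title Shared statistical primitives
#' @description Small, deterministic statistical building blocks used across
#'   the pipeline: two-sided Fisher's exact test on 2x2 tables, Wilcoxon
#'   rank-sum with exact small-sample handling (including ties), Kruskal-Wallis,
#'   Spearman correlation, Benjamini-Hochberg adjustment, area under the ROC
#'   curve with the standard tie convention, and the adjusted Rand index.
#'   Each returns a plain value or a `test_result` list so callers can record
#'   whether the p-value came from enumeration or an approximation.
#' @name stats_util
NULL

test_result <- function(statistic, p_value, method, exact) {
  stopifnot(p_value > 0, p_value <= 1)
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, exact = exact),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, p = %g (%s)\n", x$method, x$statistic,
              x$p_value, if (x$exact) "exact" else "approximate"))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass convention: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' whose probability does not exceed the observed table's.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A `test_result` with the sample odds ratio as statistic.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  ft <- stats::fisher.test(table, alternative = "two.sided")
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  test_result(statistic = or, p_value = min(1, ft$p.value),
              method = "fisher_exact_2x2", exact = TRUE)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact for combined n <= 25 when there are no ties; exact by full
#' enumeration of group assignments for combined n <= 10 when ties are
#' present; otherwise the normal approximation with continuity and tie
#' correction. The two-sided exact p is `min(1, 2 * min(P(W <= w), P(W >= w)))`
#' on the rank-sum statistic.
#'
#' @param x,y numeric vectors for the two groups.
#' @return A `test_result`; the statistic is the Mann-Whitney U of `x`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n <- length(x) + length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n <= 25) {
    wt <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    return(test_result(wt$statistic, wt$p.value, "wilcoxon_rank_sum", TRUE))
  }
  if (ties && n <= 10) {
    r <- rank(c(x, y))
    nx <- length(x)
    combos <- utils::combn(n, nx)
    sums <- colSums(matrix(r[combos], nrow = nx))
    w.obs <- sum(r[seq_len(nx)])
    eps <- 1e-9
    p.le <- mean(sums <= w.obs + eps)
    p.ge <- mean(sums >= w.obs - eps)
    p <- min(1, 2 * min(p.le, p.ge))
    u <- w.obs - nx * (nx + 1) / 2
    return(test_result(u, p, "wilcoxon_rank_sum", TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  test_result(wt$statistic, wt$p.value, "wilcoxon_rank_sum", FALSE)
}

#' Kruskal-Wallis rank-sum test
#'
#' @param values numeric vector of observations.
#' @param groups grouping vector of the same length.
#' @return A `test_result` (chi-squared approximation).
#' @export
kruskal_wallis <- function(values, groups) {
  kt <- stats::kruskal.test(values, as.factor(groups))
  test_result(kt$statistic, kt$p.value, "kruskal_wallis", FALSE)
}

#' Spearman rank correlation with test
#'
#' @param x,y numeric vectors.
#' @return A `test_result` whose statistic is Spearman's rho.
#' @export
spearman_cor <- function(x, y) {
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  test_result(ct$estimate, ct$p.value, "spearman", FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with enforced monotonicity, capped at 1.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator: the probability that a random
#' positive outscores a random negative, ties counted one half.
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param labels logical or 0/1 vector; `TRUE`/1 is the positive class.
#' @return auROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n.pos <- sum(labels); n.neg <- sum(!labels)
  if (n.pos == 0L || n.neg == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n.pos * (n.pos + 1) / 2) / (n.pos * n.neg)
}

#' Label-permutation test for an auROC
#'
#' Permutes the class labels against a fixed score vector and reports
#' `p = (1 + #\{auROC_perm >= auROC_obs\}) / (n_perm + 1)`.
#'
#' @param scores numeric scores.
#' @param labels logical or 0/1 labels.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return List with `auroc`, `p_value`, `n_perm`.
#' @export
auroc_perm_test <- function(scores, labels, n_perm = 1000L, seed = 1L) {
  labels <- as.logical(labels)
  obs <- auroc(scores, labels)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    auroc(scores, sample(labels))
  }, numeric(1)))
  p <- (1 + sum(null >= obs - 1e-12)) / (n_perm + 1)
  list(auroc = obs, p_value = p, n_perm = n_perm)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b cluster label vectors of equal length.
#' @return ARI; 1 for identical partitions, about 0 for independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum.ij <- sum(comb2(tab))
  sum.a <- sum(comb2(rowSums(tab)))
  sum.b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum.a * sum.b / comb2(n)
  max.index <- (sum.a + sum.b) / 2
  if (max.index == expected) return(1)
  (sum.ij - expected) / (max.index - expected)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
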