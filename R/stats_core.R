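#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum null distribution when
#' `length(x) + length(y) <= exact_max` and there are no ties; otherwise
#' the normal approximation with tie correction and a continuity
#' correction.  The exact two-sided p is `2 * min(P(W <= w), P(W >= w))`
#' capped at 1, which for the tie-free (symmetric) null equals the
#' symmetric-tail permutation probability.
#'
#' @param x,y numeric vectors (each length >= 1).
#' @param exact_max largest pooled sample size for exact enumeration
#'   (default 12).
#' @return list with `statistic` (rank sum of `x`), `p_value`, `method`,
#'   `n` (per-group sizes).  Identical constant samples give `p = 1`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value  # 1/3
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12L) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  m <- length(x)
  n <- length(y)
  N <- m + n
  pooled <- c(x, y)
  rk <- rank(pooled)
  w <- sum(rk[seq_len(m)])
  ties <- any(duplicated(pooled))
  if (!ties && N <= exact_max) {
    sets <- utils::combn(N, m)
    wdist <- colSums(matrix(seq_len(N)[sets], nrow = m))
    p <- 2 * min(mean(wdist <= w), mean(wdist >= w))
    return(list(statistic = w, p_value = min(1, p),
                method = "wilcoxon_rank_sum_exact", n = c(m, n)))
  }
  e <- m * (N + 1) / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  v <- m * n / 12 * ((N + 1) - tie_term)
  if (v <= 0) {
    return(list(statistic = w, p_value = 1,
                method = "wilcoxon_rank_sum_normal", n = c(m, n)))
  }
  z <- (abs(w - e) - 0.5) / sqrt(v)
  z <- max(z, 0)
  p <- 2 * stats::pnorm(-z)
  list(statistic = w, p_value = min(1, p),
       method = "wilcoxon_rank_sum_normal", n = c(m, n))
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction; p from the chi-square distribution
#' with `k - 1` degrees of freedom.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 1).
#' @return list with `statistic` (H), `p_value`, `method`, `n`.
#'   All-equal observations give `H = 0`, `p = 1`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  pooled <- unlist(groups)
  N <- length(pooled)
  rk <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  rsum <- tapply(rk, idx, sum)
  h <- 12 / (N * (N + 1)) * sum(rsum^2 / lengths(groups)) - 3 * (N + 1)
  tie_tab <- table(pooled)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (corr <= 0) {
    return(list(statistic = 0, p_value = 1, method = "kruskal_wallis",
                n = lengths(groups)))
  }
  h <- h / corr
  list(statistic = h,
       p_value = stats::pchisq(h, df = length(groups) - 1,
                               lower.tail = FALSE),
       method = "kruskal_wallis", n = lengths(groups))
}

#' Pearson correlation with t-test p-value
#'
#' @param x,y numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return list with `statistic` (r), `p_value` (two-sided t test on
#'   `n - 2` df), `method`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input to pearson_cor")
  }
  n <- length(x)
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(statistic = r, p_value = p, method = "pearson", n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Optional multiple-testing correction for batches of pairwise tests
#' (no correction is applied by default anywhere in the package).
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
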