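# Nonparametric group comparisons, implemented from the rank definitions up.
# Exact small-sample Mann-Whitney inference is the point here: the (3,6)
# comparison in the glioma cohort needs the enumerated null (the normal
# approximation misses p = 0.048).

.group_test_result <- function(statistic_name, statistic, df, p_value,
                               method, group_sizes) {
  structure(
    list(statistic_name = statistic_name, statistic = statistic, df = df,
         p_value = p_value, method = method, group_sizes = group_sizes),
    class = "group_test_result"
  )
}

#' @export
print.group_test_result <- function(x, ...) {
  dfs <- if (is.na(x$df)) "" else sprintf("(%g)", x$df)
  cat(sprintf("%s%s = %.4g, p = %.4g  [%s; n = %s]\n",
              x$statistic_name, dfs, x$statistic, x$p_value, x$method,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

# Counts of the null distribution of U (number of (x,y) pairs with x > y)
# for sample sizes m, n without ties, by the standard recurrence
# N(u; i, j) = N(u - j; i - 1, j) + N(u; i, j - 1); totals are C(m + n, m).
.u_null_counts <- function(m, n) {
  maxu <- m * n
  mat <- matrix(0, nrow = n + 1, ncol = maxu + 1) # rows j = 0..n
  mat[, 1] <- 1 # i = 0: all mass at u = 0
  for (i in seq_len(m)) {
    new <- matrix(0, nrow = n + 1, ncol = maxu + 1)
    new[1, 1] <- 1 # j = 0
    for (j in seq_len(n)) {
      shifted <- c(rep(0, j), mat[j + 1, seq_len(maxu + 1 - j)])
      new[j + 1, ] <- shifted + new[j, ]
    }
    mat <- new
  }
  mat[n + 1, ]
}

#' Mann-Whitney U test
#'
#' Two-sample rank test. The statistic is reported as `min(U1, U2)` with
#' `U1 + U2 = n1 * n2`, matching the convention of mainstream clinical
#' statistics software. Inference is exact — two-sided p obtained by
#' doubling the one-tail probability `P(U <= min(U1, U2))` under the
#' enumerated null distribution, capped at 1 — whenever the pooled sample is
#' small (`n1 + n2 <= exact_limit`) and tie-free; otherwise the normal
#' approximation with the tie-corrected variance is used. Midranks handle
#' ties in the statistic itself.
#'
#' @param x,y Numeric samples.
#' @param exact_limit Largest pooled sample size for which the exact null is
#'   enumerated (default 25).
#' @return A `group_test_result` with `statistic_name = "U"`, the statistic,
#'   p-value, method (`"exact"` or `"normal_approx"`), and group sizes.
#' @examples
#' mann_whitney_u(c(5, 6, 7), c(1, 2, 3, 4))
#' @export
mann_whitney_u <- function(x, y, exact_limit = 25L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be nonempty")
  }
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled) # midranks
  r1 <- sum(r[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2 # pairs with x > y, ties counted 1/2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- table(pooled)
  has_ties <- any(ties > 1)

  if (!has_ties && n1 + n2 <= exact_limit) {
    counts <- .u_null_counts(n1, n2)
    total <- sum(counts)
    p_one <- sum(counts[seq_len(round(u) + 1)]) / total
    p <- min(1, 2 * p_one)
    method <- "exact"
  } else {
    n <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) stop("all pooled values identical; U test undefined")
    z <- (u1 - n1 * n2 / 2) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  .group_test_result("U", u, NA_real_, p, method, c(n1, n2))
}

#' Exact null distribution of the Mann-Whitney U statistic
#'
#' Probability mass function of U (pairs with x above y) for tie-free
#' samples of sizes `m` and `n`, on support `0..m*n`.
#'
#' @param m,n Group sizes.
#' @return Numeric vector of probabilities, names the U values.
#' @export
u_null_distribution <- function(m, n) {
  counts <- .u_null_counts(m, n)
  stats::setNames(counts / sum(counts), 0:(m * n))
}

#' Kruskal-Wallis rank test
#'
#' Omnibus k-group rank test with midranks and the tie correction
#' `1 - sum(t^3 - t) / (N^3 - N)`; p-value from the chi-square reference
#' distribution with `k - 1` degrees of freedom.
#'
#' @param groups List of numeric samples (length >= 2, each nonempty).
#' @return A `group_test_result` with `statistic_name = "H"`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least two groups")
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("every group must be nonempty")
  pooled <- as.numeric(unlist(groups))
  if (anyNA(pooled)) stop("samples must not contain NA")
  n <- length(pooled)
  if (n < 3L) stop("need at least 3 observations in total")
  if (length(unique(pooled)) == 1L) {
    stop("all values identical; rank variance is zero")
  }
  r <- rank(pooled)
  g <- rep(seq_along(groups), sizes)
  rank_sums <- tapply(r, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rank_sums^2 / sizes) - 3 * (n + 1)
  ties <- table(pooled)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / correction
  df <- length(groups) - 1
  p <- stats::pchisq(h, df = df, lower.tail = FALSE)
  .group_test_result("H", h, df, p, "chi_square_approx", as.integer(sizes))
}

#' Two-sample t test
#'
#' Student's pooled-variance t test (`n1 + n2 - 2` degrees of freedom) with
#' the Welch unpooled variant as an option.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param pooled Use the pooled-variance statistic (default `TRUE`).
#' @return A `group_test_result` with `statistic_name = "t"`.
#' @export
two_sample_t <- function(x, y, pooled = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each sample needs at least 2 observations")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) stop("zero variance in both samples")
  if (pooled) {
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (mean(x) - mean(y)) / sqrt(s2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "pooled"
  } else {
    se2 <- v1 / n1 + v2 / n2
    tt <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    method <- "welch"
  }
  p <- 2 * stats::pt(-abs(tt), df = df)
  .group_test_result("t", tt, df, p, method, c(n1, n2))
}
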