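#' Statistical test results
#'
#' Light container for the tests used to summarise calcium-imaging and
#' behaviour cohorts.
#'
#' @param statistic test statistic
#' @param p_value two-sided p-value in `[0, 1]`
#' @param method one of `"wilcoxon_exact"`, `"wilcoxon_normal"`,
#'   `"t_paired"`, `"t_unpaired"`, `"dagostino_pearson"`
#' @param n sample size after exclusions
#' @param ... extra fields (e.g. `df`, `pass`)
#' @return a `ciliomotor_test` object
#' @export
test_result <- function(statistic, p_value, method, n, ...) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(c(list(statistic = statistic, p_value = p_value,
                   method = method, n = n), list(...)),
            class = "ciliomotor_test")
}

#' @export
print.ciliomotor_test <- function(x, ...) {
  cat("<", x$method, "> statistic = ", format(x$statistic, digits = 5),
      ", p = ", format(x$p_value, digits = 4), ", n = ", x$n,
      if (!is.null(x$pass)) paste0(", pass = ", x$pass), "\n", sep = "")
  invisible(x)
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Tests whether the median of `values` differs from `center`. Values equal
#' to the centre are dropped; tied absolute differences get mid-ranks. For
#' `n <= 25` (or `mode = "exact"`) the null distribution of the
#' positive-rank sum is enumerated exactly over all sign assignments (by
#' dynamic programming over the rank generating function, which handles
#' mid-ranks); above that a normal approximation with tie and continuity
#' corrections is used. The two-sided p is `2 * min(P(W <= w), P(W >= w))`,
#' capped at 1.
#'
#' @param values numeric sample
#' @param center hypothesised median (default 0)
#' @param mode `"auto"` (exact up to n = 25), `"exact"`, or `"normal"`
#' @return a `ciliomotor_test` with method `wilcoxon_exact` or
#'   `wilcoxon_normal`; the statistic is the positive-rank sum W+
#' @export
wilcoxon_signed_rank <- function(values, center = 0,
                                 mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  d <- values - center
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) stop_validation("all values equal the centre: nothing to test")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  exact <- switch(mode, auto = n <= 25, exact = TRUE, normal = FALSE)
  if (exact) {
    p <- wilcoxon_exact_p(r, w)
    test_result(w, p, "wilcoxon_exact", n)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    test_result(w, p, "wilcoxon_normal", n, z = z)
  }
}

# Exact two-sided p for the signed-rank statistic with ranks r (possibly
# mid-ranks) and observed positive-rank sum w: distribution of W+ over all
# 2^n sign assignments via the generating function of doubled ranks.
wilcoxon_exact_p <- function(r, w) {
  r2 <- as.integer(round(2 * r))   # doubled mid-ranks are integers
  total <- sum(r2)
  # counts[k + 1] = number of assignments with doubled rank-sum k
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (rk in r2) {
    shifted <- c(numeric(rk), counts[seq_len(total + 1 - rk)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(r2)
  w2 <- round(2 * w)
  k <- 0:total
  p_le <- sum(probs[k <= w2 + 1e-9])
  p_ge <- sum(probs[k >= w2 - 1e-9])
  min(1, 2 * min(p_le, p_ge))
}

#' Student's t-test (paired, Welch or pooled)
#'
#' Thin wrapper mapping base R's t-test onto the cohort-comparison surface
#' used here (e.g. ciliary beat frequency or closure rate with and without
#' serotonin). Unpaired comparisons default to Welch's unequal-variance
#' form; `pooled = TRUE` gives the classic equal-variance test.
#'
#' @param a,b numeric samples (equal length when `paired`)
#' @param paired paired test on `a - b`?
#' @param pooled for unpaired tests, assume equal variances?
#' @return a `ciliomotor_test` with `df` attached
#' @export
t_test <- function(a, b, paired = FALSE, pooled = FALSE) {
  if (paired && length(a) != length(b))
    stop_validation("paired samples must have equal length")
  if (length(a) < 2 || length(b) < 2)
    stop_validation("need at least 2 observations per group")
  if (paired) {
    if (sd(a - b) == 0)
      stop_validation("zero variance of paired differences: t undefined")
  } else if (sd(a) == 0 && sd(b) == 0) {
    stop_validation("zero variance in both groups: t undefined")
  }
  ht <- t.test(a, b, paired = paired, var.equal = !paired && pooled)
  test_result(unname(ht$statistic), ht$p.value,
              if (paired) "t_paired" else "t_unpaired",
              if (paired) length(a) else length(a) + length(b),
              df = unname(ht$parameter))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness and kurtosis z-scores into the
#' omnibus statistic `K^2 = Z_skew^2 + Z_kurt^2`, referred to a chi-squared
#' distribution with 2 df. Used to justify parametric tests on cohort
#' summaries; requires n >= 20 for the approximations to hold.
#'
#' @param values numeric sample, n >= 20, non-constant
#' @param alpha significance level for the pass flag (default 0.05)
#' @return a `ciliomotor_test` with `pass = (p > alpha)` attached
#' @export
normality_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 20)
    stop_validation("D'Agostino-Pearson needs n >= 20 (got ", n,
                    "); collect more data or use a different test")
  if (sd(values) == 0) stop_validation("constant data: normality undefined")
  x <- values
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  # skewness z (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha_s <- sqrt(2 / (W2 - 1))
  z_skew <- delta * log(y / alpha_s + sqrt((y / alpha_s)^2 + 1))
  # kurtosis z (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  z_kurt <- ((1 - 2 / (9 * A)) -
             ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  k2 <- z_skew^2 + z_kurt^2
  p <- pchisq(k2, df = 2, lower.tail = FALSE)
  test_result(k2, p, "dagostino_pearson", n, pass = p > alpha,
              z_skew = z_skew, z_kurt = z_kurt)
}

#' Serialise test results to a data.frame (for CSV/JSON export)
#'
#' @param results a `ciliomotor_test` or list of them
#' @return data.frame with columns `method`, `n`, `statistic`, `p_value`
#' @export
test_results_table <- function(results) {
  if (inherits(results, "ciliomotor_test")) results <- list(results)
  do.call(rbind, lapply(results, function(x)
    data.frame(method = x$method, n = x$n, statistic = x$statistic,
               p_value = x$p_value)))
}
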