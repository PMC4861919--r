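# Statistical primitives used throughout the pipeline: a Mann-Whitney U test
# with an exact tie-aware enumeration mode, Pearson correlation with a
# percentile-bootstrap interval, and Benjamini-Hochberg FDR adjustment.

#' Mann-Whitney U test (exact enumeration or tie-corrected normal mode)
#'
#' The statistic is `U = #\{(x, y) pairs with x > y\} + 0.5` per tied pair,
#' computed from midranks. When `min(n, m) <= exact_max_small` and the number
#' of group labelings `choose(n + m, n)` does not exceed `exact_max_comb`,
#' the exact null distribution of U is obtained by enumerating every
#' labeling of the observed (possibly tied) values, so ties are handled
#' exactly. Otherwise a normal approximation with tie correction and a 0.5
#' continuity correction is used. The two-tailed p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))` in both modes.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_max_small Exact mode requires `min(n, m)` at or below this
#'   cap (default 8).
#' @param exact_max_comb Exact mode requires `choose(n + m, n)` at or below
#'   this cap (default 1e5).
#' @return An object of class `mwu_test`: a list with `u`, `p_value`,
#'   `mode` (`"exact"` or `"normal_approx"`), `n`, `m`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))   # exact two-tailed p = 1/3
#' @export
mann_whitney_u <- function(x, y, exact_max_small = 8, exact_max_comb = 1e5) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) abort("samples must be finite")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))                       # midranks
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  exact <- min(n, m) <= exact_max_small && choose(N, min(n, m)) <= exact_max_comb
  if (exact) {
    combs <- combn(N, n)
    u_all <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u + eps), mean(u_all >= u - eps)))
    mode <- "exact"
  } else {
    mu <- n * m / 2
    ties <- table(r)
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      s <- sqrt(sigma2)
      p_le <- pnorm((u + 0.5 - mu) / s)
      p_ge <- pnorm((u - 0.5 - mu) / s, lower.tail = FALSE)
      p <- min(1, 2 * min(p_le, p_ge))
    }
    mode <- "normal_approx"
  }
  structure(list(u = u, p_value = p, mode = mode, n = n, m = m),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s): U = %g (n = %d, m = %d), two-tailed p = %.4g\n",
              x$mode, x$u, x$n, x$m, x$p_value))
  invisible(x)
}

#' Tidy a Mann-Whitney U test result
#'
#' @param x An `mwu_test` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `p.value`, `method`, `n`, `m`.
#' @export
tidy.mwu_test <- function(x, ...) {
  tibble(statistic = x$u, p.value = x$p_value, method = x$mode,
         n = x$n, m = x$m)
}

#' Pearson correlation with t-test and percentile-bootstrap interval
#'
#' `r` by the product-moment formula, a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, and a
#' percentile confidence interval from `B` paired resamples.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with non-zero
#'   variance.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed RNG seed for the resampling (recorded in the result).
#' @param conf Confidence level of the percentile interval.
#' @return An object of class `boot_cor`: list with `r`, `p_value`,
#'   `ci_low`, `ci_high`, `B`, `seed`, `n`.
#' @export
pearson_bootstrap <- function(x, y, B = 1000, seed = 1, conf = 0.95) {
  n <- length(x)
  if (length(y) != n) abort("x and y must have the same length")
  if (n < 3) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in x or y")
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  boot <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sd(x[idx]) == 0 || sd(y[idx]) == 0) NA_real_ else cor(x[idx], y[idx])
    }, numeric(1))
  })
  ci <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE,
                 names = FALSE)
  structure(list(r = r, p_value = p, ci_low = ci[1], ci_high = ci[2],
                 B = B, seed = seed, n = n),
            class = "boot_cor")
}

#' @export
print.boot_cor <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d), p = %.4g, %d-resample percentile CI [%.3f, %.3f]\n",
              x$r, x$n, x$p_value, x$B, x$ci_low, x$ci_high))
  invisible(x)
}

#' Tidy a bootstrap correlation result
#'
#' @param x A `boot_cor` object.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `p.value`, `conf.low`,
#'   `conf.high`, `n`, `B`.
#' @export
tidy.boot_cor <- function(x, ...) {
  tibble(estimate = x$r, p.value = x$p_value,
         conf.low = x$ci_low, conf.high = x$ci_high, n = x$n, B = x$B)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: `q_(i) = min_{j >= i} p_(j) * m / j` on sorted
#' p-values, mapped back to the original order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}
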