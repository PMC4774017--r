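#' Wilson score binomial confidence interval
#'
#' Closed-form Wilson score interval without continuity correction. When
#' every trial succeeds (`x == n`) the lower bound reduces to
#' `n / (n + z^2)`; by symmetry the upper bound for `x == 0` is
#' `z^2 / (n + z^2)`. Bounds are clipped to `[0, 1]`.
#'
#' @param x Number of successes, `0 <= x <= n` (vectorized).
#' @param n Number of trials, `n >= 1`.
#' @param level Confidence level, default 0.95.
#' @return A `data.frame` with columns `estimate`, `low`, `high`.
#' @examples
#' binomial_ci(43, 47)  # low 0.801, high 0.966
#' binomial_ci(7, 7)    # low 0.646
#' @export
binomial_ci <- function(x, n, level = 0.95) {
  k <- max(length(x), length(n))
  x <- rep_len(as.numeric(x), k); n <- rep_len(as.numeric(n), k)
  if (any(n < 1)) stop("binomial_ci requires n >= 1")
  if (any(x < 0 | x > n)) stop("binomial_ci requires 0 <= x <= n")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  halfw <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  data.frame(estimate = p,
             low = pmax(0, center - halfw),
             high = pmin(1, center + halfw))
}
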