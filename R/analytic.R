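#' Constrained FN/FP rate pair sweep
#'
#' For a non-disjoint GT/AD pair, moving the boundary so that the FN region
#' gains (or loses) one pixel forces the FP region to gain (or lose) one
#' pixel too, because the intersection shrinks (or grows) by exactly that
#' pixel. Sweeping the shift `i` from `-m` to `n` therefore generates the
#' perfectly coupled rate pairs
#' `(r_fn_i, r_fp_i) = ((n_g + i)/n_G, (n_a + i)/n_A)` — the construction
#' behind the closed-form analytic treatment of the average MER.
#'
#' @inheritParams mer
#' @param m downward shift extent (`n_g - m >= 0` and `n_a - m >= 0`).
#' @param n upward shift extent (`n_g + n <= n_G` and `n_a + n <= n_A`).
#' @return Object of class `pair_sweep`: list with the base `counts`, `m`,
#'   `n`, and `pairs`, a data frame with columns `i`, `r_fn`, `r_fp`
#'   (`m + n + 1` rows).
#' @export
pair_sweep <- function(counts, m, n) {
  c <- as_pixel_counts(counts)
  if (!is.numeric(m) || !is.numeric(n) || m < 0 || n < 0 ||
      m != round(m) || n != round(n))
    stop("m and n must be non-negative integers")
  if (m + n < 1) stop("degenerate sweep: m + n must be at least 1")
  if (c$n_g - m < 0 || c$n_a - m < 0)
    stop("downward shift m exceeds an error-region size")
  if (c$n_g + n > c$n_G || c$n_a + n > c$n_A)
    stop("upward shift n exceeds a cell size")
  i <- seq.int(-m, n)
  structure(list(counts = c, m = m, n = n,
                 pairs = data.frame(i = i,
                                    r_fn = (c$n_g + i) / c$n_G,
                                    r_fp = (c$n_a + i) / c$n_A)),
            class = "pair_sweep")
}

#' @export
print.pair_sweep <- function(x, ...) {
  cat(sprintf("Constrained rate sweep: i = -%d..%d (%d pairs) from counts (%d, %d, %d, %d)\n",
              x$m, x$n, nrow(x$pairs),
              x$counts$n_G, x$counts$n_g, x$counts$n_A, x$counts$n_a))
  invisible(x)
}

#' Closed-form means of a rate pair sweep
#'
#' The sweep's mean FN and FP rates have the closed forms
#' `mean(r_fn) = n_g/n_G + (n - m) / (2 n_G)` and the analogue with `n_A`;
#' a symmetric sweep (`m = n`) leaves the means at the base rates.
#'
#' @param s a [pair_sweep()] object.
#' @return Named numeric vector `c(r_fn = , r_fp = )`.
#' @export
pair_sweep_means <- function(s) {
  stopifnot(inherits(s, "pair_sweep"))
  c0 <- s$counts
  c(r_fn = c0$n_g / c0$n_G + (s$n - s$m) / (2 * c0$n_G),
    r_fp = c0$n_a / c0$n_A + (s$n - s$m) / (2 * c0$n_A))
}

#' Correlation of the constrained rate pairs
#'
#' Both rates of a sweep are affine functions of the same shift `i`, so
#' their sample Pearson correlation is exactly 1 — the analytic fact that
#' makes the closed-form SE of the average MER possible.
#'
#' @param s a [pair_sweep()] object.
#' @return The sample Pearson correlation (1 up to numerical precision).
#' @export
pair_sweep_correlation <- function(s) {
  stopifnot(inherits(s, "pair_sweep"))
  stats::cor(s$pairs$r_fn, s$pairs$r_fp)
}

#' Analytic standard error of the average MER
#'
#' Because the FN and FP rates are perfectly correlated under the overlap
#' constraint, the SE of their average is the average of their individual
#' binomial SEs: `SE_a = (SE_fn + SE_fp) / 2` with
#' `SE_fn = sqrt(r_fn (1 - r_fn) / n_G)` and
#' `SE_fp = sqrt(r_fp (1 - r_fp) / n_A)`. This closed form tends to
#' underestimate the bootstrap SE and is provided for reference, not as the
#' package's uncertainty estimate.
#'
#' @inheritParams mer
#' @return The analytic SE of the average MER.
#'
#' @examples
#' analytic_se_average_mer(pixel_counts(1420, 5, 3492, 2077)) # ~0.0049398
#' @export
analytic_se_average_mer <- function(counts) {
  c <- as_pixel_counts(counts)
  r <- error_rates(c)
  n_A <- max(c$n_A, 1)  # absent-AD convention: rates (1,1) give SE 0 anyway
  se_fn <- sqrt(r[["r_fn"]] * (1 - r[["r_fn"]]) / c$n_G)
  se_fp <- sqrt(r[["r_fp"]] * (1 - r[["r_fp"]]) / n_A)
  (se_fn + se_fp) / 2
}
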