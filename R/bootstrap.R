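# RNG plumbing: every stochastic routine takes an optional integer seed and
# leaves the caller's RNG state untouched. Per-cell / per-iteration substreams
# are derived additively from the master seed so results do not depend on the
# order in which cells are processed, and serial / per-cell execution agree.

derive_seed <- function(seed, index = 0L, stream = 0L) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + index * 1000003 + stream * 7368787) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# MER of bootstrap replicates given replicate FN/FP counts (vectorized)
replicate_mers <- function(np_g, np_a, n_G, n_A, variant) {
  if (variant == "proportion") return((np_g + np_a) / (n_G + n_A))
  mer_from_rates(np_g / n_G, np_a / n_A, variant)
}

# Draw M accepted replicate FP counts n'_a for the AD-side resampling
# (Cases 4/5): n'_a ~ Binomial(n_A, n_a/n_A), accepted when the implied
# intersection n_A - n'_a fits inside the GT cell. The truncated-binomial
# draw is distributionally identical to literally resampling the n_A
# exchangeable 0/2 dummy scores with replacement and counting the 2s;
# method = "literal" does exactly that, for fidelity checking.
draw_fp_counts <- function(M, n_total, n_pos, accept_min, method, max_rejections) {
  if (method == "literal") {
    scores <- c(rep(2L, n_pos), rep(0L, n_total - n_pos))
    out <- integer(M)
    attempts <- 0L
    for (i in seq_len(M)) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > max_rejections)
          stop("bootstrap rejection cap exceeded; counts are pathological ",
               "(detected object vastly larger than its GT cell)")
        k <- sum(sample(scores, n_total, replace = TRUE) == 2L)
        if (k >= accept_min) { out[i] <- k; break }
      }
    }
    return(out)
  }
  p <- n_pos / n_total
  out <- integer(0)
  attempts <- 0
  while (length(out) < M) {
    need <- M - length(out)
    attempts <- attempts + need
    if (attempts > max_rejections)
      stop("bootstrap rejection cap exceeded; counts are pathological ",
           "(detected object vastly larger than its GT cell)")
    draw <- stats::rbinom(need, n_total, p)
    out <- c(out, draw[draw >= accept_min])
  }
  out[seq_len(M)]
}

#' Bootstrap standard error of the MER for a single cell
#'
#' Nonparametric one-sample bootstrap of the single-cell MER under the
#' constraint that the GT and AD pixel counts always describe a geometrically
#' possible overlap. The AD cell's pixels carry exchangeable dummy scores
#' (2 on the false-positive region, 0 on the intersection); a replicate
#' resamples those `n_A` scores with replacement, giving a new FP count
#' `n'_a`, and is accepted only when the implied intersection
#' `n_A - n'_a` fits inside the GT cell; the new FN count is then forced by
#' the constraint, `n'_g = n_G - (n_A - n'_a)`. For a detected cell lying
#' strictly inside its GT cell (Case 3, no FP pixels) the GT side is
#' resampled instead, with the mirrored acceptance rule. Disjoint and
#' identical pairs (Cases 1 and 2) have no resampling variability by
#' convention and return exactly 0.
#'
#' @inheritParams mer
#' @param M number of bootstrap replications (default 2000).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @param method `"binomial"` draws the replicate FP count directly from the
#'   truncated binomial distribution of the score resample (exact and O(1)
#'   per replicate); `"literal"` resamples the score multiset itself.
#' @param max_rejections cap on total draws before the constraint-rejection
#'   loop is declared pathological.
#' @param return_replicates if `TRUE` the M replicate MERs are attached as
#'   attribute `"replicates"`.
#' @return The sample standard deviation (denominator M - 1) of the M
#'   replicate MERs.
#'
#' @examples
#' bootstrap_se_mer(pixel_counts(4, 2, 4, 2), "weighted", seed = 1) # ~0.25
#' @export
bootstrap_se_mer <- function(counts, variant = c("weighted", "average", "proportion"),
                             M = 2000, seed = NULL,
                             method = c("binomial", "literal"),
                             max_rejections = 1e6, return_replicates = FALSE) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  c <- as_pixel_counts(counts)
  if (!is.numeric(M) || M < 2) stop("M must be at least 2")
  cs <- classify_case(c)
  if (cs %in% c(1L, 2L)) {
    out <- 0
    if (return_replicates)
      attr(out, "replicates") <- rep(mer(c, variant), M)
    return(out)
  }
  reps <- with_seed(seed, {
    if (cs == 3L) {
      # resample the GT-side scores: n'_g ~ truncated Binomial(n_G, n_g/n_G)
      np_g <- draw_fp_counts(M, c$n_G, c$n_g, max(0L, c$n_G - c$n_A),
                             method, max_rejections)
      np_a <- c$n_A - (c$n_G - np_g)
      replicate_mers(np_g, np_a, c$n_G, c$n_A, variant)
    } else {
      np_a <- draw_fp_counts(M, c$n_A, c$n_a, max(0L, c$n_A - c$n_G),
                             method, max_rejections)
      np_g <- c$n_G - (c$n_A - np_a)
      replicate_mers(np_g, np_a, c$n_G, c$n_A, variant)
    }
  })
  out <- stats::sd(reps)
  if (return_replicates) attr(out, "replicates") <- reps
  out
}

#' Exact distribution and SD of the bootstrap MER replicates
#'
#' Independent closed-form check on [bootstrap_se_mer()]: because a replicate
#' depends only on the resampled FP (or, in Case 3, FN) count, the full
#' bootstrap distribution is a binomial truncated to the constraint-accepted
#' region and can be enumerated. `oracle_mer_distribution()` returns the
#' support and probabilities; `exact_se_mer_oracle()` returns the population
#' standard deviation of that distribution. Cases 1 and 2 return 0 by the
#' same convention as the bootstrap.
#'
#' @inheritParams bootstrap_se_mer
#' @return For `exact_se_mer_oracle()`, the exact SD. For
#'   `oracle_mer_distribution()`, a data frame with columns `value` (MER)
#'   and `prob`.
#'
#' @examples
#' exact_se_mer_oracle(pixel_counts(4, 2, 4, 2), "weighted") # exactly 0.25
#' @export
exact_se_mer_oracle <- function(counts, variant = c("weighted", "average", "proportion")) {
  variant <- match.arg(variant)
  d <- oracle_mer_distribution(counts, variant)
  mu <- sum(d$value * d$prob)
  sqrt(max(0, sum(d$prob * (d$value - mu)^2)))
}

#' @rdname exact_se_mer_oracle
#' @export
oracle_mer_distribution <- function(counts, variant = c("weighted", "average", "proportion")) {
  variant <- match.arg(variant)
  c <- as_pixel_counts(counts)
  cs <- classify_case(c)
  if (cs %in% c(1L, 2L))
    return(data.frame(value = mer(c, variant), prob = 1))
  if (cs == 3L) {
    np_g <- 0:c$n_G
    w <- stats::dbinom(np_g, c$n_G, c$n_g / c$n_G)
    ok <- (c$n_G - np_g) <= c$n_A
    np_g <- np_g[ok]; w <- w[ok]
    np_a <- c$n_A - (c$n_G - np_g)
  } else {
    np_a <- 0:c$n_A
    w <- stats::dbinom(np_a, c$n_A, c$n_a / c$n_A)
    ok <- (c$n_A - np_a) <= c$n_G
    np_a <- np_a[ok]; w <- w[ok]
    np_g <- c$n_G - (c$n_A - np_a)
  }
  w <- w / sum(w)
  vals <- replicate_mers(np_g, np_a, c$n_G, c$n_A, variant)
  agg <- tapply(w, vals, sum)
  data.frame(value = as.numeric(names(agg)), prob = as.numeric(agg),
             row.names = NULL)
}

#' Variance of the TER from per-cell standard errors
#'
#' Under the assumption that the cells are segmented independently, the
#' variance of the size-weighted TER is the weight-squared combination of
#' the per-cell MER variances:
#' `Var = sum_i (S_i / sum_j S_j)^2 * SE_i^2`.
#'
#' @param e a `seg_eval` object (its GT sizes supply the weights), or a
#'   numeric vector of sizes.
#' @param per_cell_se numeric vector of per-cell MER standard errors, in the
#'   evaluation's cell order.
#' @return The variance of the TER estimate.
#' @export
ter_variance <- function(e, per_cell_se) {
  S <- if (inherits(e, "seg_eval")) e$cells$S else as.numeric(e)
  if (length(per_cell_se) != length(S))
    stop("need exactly one SE per cell")
  if (any(per_cell_se < 0)) stop("standard errors must be non-negative")
  w <- S / sum(S)
  sum(w^2 * per_cell_se^2)
}

#' Normal-approximation confidence interval for the TER
#'
#' `epsilon +/- z_{1-alpha/2} * se`. Bounds are not clamped to \[0, 1\];
#' if a bound falls outside the unit interval the result carries the
#' attribute `out_of_range = TRUE`.
#'
#' @param epsilon TER point estimate.
#' @param se its standard error (non-negative).
#' @param alpha significance level in (0, 1); 0.05 gives the usual 95% CI.
#' @return Numeric vector `c(lower, upper)`.
#' @export
ter_confidence_interval <- function(epsilon, se, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  if (se < 0) stop("se must be non-negative")
  z <- stats::qnorm(1 - alpha / 2)
  out <- c(lower = epsilon - z * se, upper = epsilon + z * se)
  if (out[1] < 0 || out[2] > 1) attr(out, "out_of_range") <- TRUE
  out
}

#' Relative error of an estimate
#'
#' `1.96 * se / center`, expressed as a percentage — the half-width of the
#' 95% interval relative to the point estimate.
#'
#' @param se standard error.
#' @param center positive point estimate (a TER, or the mean of an SE
#'   distribution).
#' @return The relative error in percent.
#' @export
relative_error <- function(se, center) {
  if (!is.numeric(center) || center <= 0)
    stop("relative error needs a positive center")
  100 * 1.96 * se / center
}

#' Sample quantile by inverting the EDF with averaging at discontinuities
#'
#' The quantile definition used for the confidence bounds of the
#' SE-variability distribution (type 2 in the Hyndman–Fan taxonomy).
#'
#' @param samples non-empty numeric vector.
#' @param p probabilities strictly between 0 and 1.
#' @return Quantile value(s).
#' @export
quantile_type2 <- function(samples, p) {
  if (length(samples) == 0L || anyNA(samples))
    stop("samples must be non-empty and free of NA")
  if (any(p <= 0) || any(p >= 1)) stop("p must lie strictly between 0 and 1")
  stats::quantile(samples, probs = p, type = 2, names = FALSE)
}

#' Monte-Carlo variability of the bootstrap SE of the TER
#'
#' The bootstrap SE of a TER is itself a random quantity. This routine
#' re-runs the whole per-cell bootstrap L times, each time recombining the
#' per-cell SEs into an SE of the TER, and summarizes the resulting
#' distribution: its mean, its SD, a confidence interval from type-2 sample
#' quantiles, and the relative error `1.96 * SD / mean`.
#'
#' @inheritParams bootstrap_se_mer
#' @param e a `seg_eval` object.
#' @param L number of Monte-Carlo repetitions of the full bootstrap
#'   (default 500).
#' @param alpha significance level for the quantile interval.
#' @return Object of class `se_ter_dist`: list with `mean`, `se`, `ci`,
#'   `relative_error` (percent), `samples` (the L values), `L`, `M`,
#'   `variant`, `alpha`.
#' @export
se_ter_distribution <- function(e, variant = c("weighted", "average", "proportion"),
                                M = 2000, L = 500, alpha = 0.05, seed = NULL,
                                method = c("binomial", "literal"),
                                max_rejections = 1e6) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  stopifnot(inherits(e, "seg_eval"))
  if (!is.numeric(L) || L < 2) stop("L must be at least 2 (a distribution needs spread)")
  samples <- vapply(seq_len(L), function(l) {
    ses <- vapply(seq_len(e$N), function(i) {
      bootstrap_se_mer(with(e$cells[i, ], pixel_counts(n_G, n_g, n_A, n_a)),
                       variant, M = M,
                       seed = derive_seed(seed, index = i, stream = l),
                       method = method, max_rejections = max_rejections)
    }, numeric(1))
    sqrt(ter_variance(e, ses))
  }, numeric(1))
  m <- mean(samples)
  s <- stats::sd(samples)
  structure(list(
    mean = m, se = s,
    ci = c(lower = quantile_type2(samples, alpha / 2),
           upper = quantile_type2(samples, 1 - alpha / 2)),
    relative_error = if (m > 0) relative_error(s, m) else 0,
    samples = samples, L = L, M = M, variant = variant, alpha = alpha),
    class = "se_ter_dist")
}

#' @export
print.se_ter_dist <- function(x, ...) {
  cat(sprintf("Variability of the bootstrap SE of TER (%s MER; L = %d, M = %d)\n",
              x$variant, x$L, x$M))
  cat(sprintf("  mean SE     : %.6f\n", x$mean))
  cat(sprintf("  SE of SEs   : %.6f (relative error %.2f%%)\n",
              x$se, x$relative_error))
  cat(sprintf("  %d%% CI      : (%.6f, %.6f)\n",
              round(100 * (1 - x$alpha)), x$ci[["lower"]], x$ci[["upper"]]))
  invisible(x)
}
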