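#' Correlation between two algorithms' TERs by synchronized resampling
#'
#' Two algorithms evaluated on the same GT cells produce correlated TERs,
#' because both error rates rise and fall with the same cells. The
#' correlation is estimated by resampling cell indices with replacement and
#' applying the *same* index vector to both evaluations: each of the M
#' synchronized resamples yields a paired TER replicate
#' (TER_A, TER_B), and the Pearson correlation over the M pairs estimates
#' rho. Because a single pass is itself stochastic, the estimate is averaged
#' over several independent runs (default 10).
#'
#' @param a,b `seg_eval` objects over the same ordered GT cells.
#' @param variant MER variant, see [mer()].
#' @param M resamples per run (default 2000).
#' @param runs independent runs averaged into the final estimate.
#' @param seed optional integer seed.
#' @param synchronized internal switch; `FALSE` resamples the two
#'   evaluations independently, which destroys the pairing (used only to
#'   demonstrate why synchronization matters).
#' @return The averaged correlation, with attribute `"runs"` holding the
#'   per-run estimates.
#' @export
ter_correlation <- function(a, b, variant = c("weighted", "average", "proportion"),
                            M = 2000, runs = 10, seed = NULL,
                            synchronized = TRUE) {
  variant <- match.arg(variant)
  check_same_cells(a, b)
  N <- a$N
  if (N < 2L) stop("correlation needs at least 2 GT cells")
  ma <- cell_mers(a, variant)
  mb <- cell_mers(b, variant)
  S <- a$cells$S
  one_run <- function(r) {
    with_seed(derive_seed(seed, stream = 600000 + r), {
      idx <- matrix(sample.int(N, N * M, replace = TRUE), nrow = M)
      wsum <- matrix(S[idx], nrow = M)
      terA <- rowSums(matrix((ma * S)[idx], nrow = M)) / rowSums(wsum)
      if (!synchronized) {
        idx <- matrix(sample.int(N, N * M, replace = TRUE), nrow = M)
        wsum <- matrix(S[idx], nrow = M)
      }
      terB <- rowSums(matrix((mb * S)[idx], nrow = M)) / rowSums(wsum)
      if (stats::sd(terA) == 0 || stats::sd(terB) == 0)
        stop("correlation undefined: a TER replicate series has zero variance ",
             "(all per-cell MERs identical within an algorithm)")
      stats::cor(terA, terB)
    })
  }
  per_run <- vapply(seq_len(runs), one_run, numeric(1))
  structure(mean(per_run), runs = per_run)
}

#' Z statistic for comparing two correlated TER estimates
#'
#' `Z = (T_A - T_B) / sqrt(SE_A^2 + SE_B^2 - 2 rho SE_A SE_B)`, the
#' two-sample statistic for estimators measured on the same GT cells and
#' hence correlated.
#'
#' @param tA,tB the two TER point estimates.
#' @param seA,seB their standard errors (non-negative).
#' @param rho correlation between the two estimates, in \[-1, 1\].
#' @return The Z statistic.
#'
#' @examples
#' z_statistic(0.171153, 0.001721, 0.173513, 0.000868, 0.370554) # ~ -1.46
#' @export
z_statistic <- function(tA, seA, tB, seB, rho) {
  if (seA < 0 || seB < 0) stop("standard errors must be non-negative")
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  denom2 <- seA^2 + seB^2 - 2 * rho * seA * seB
  if (denom2 <= 0)
    stop("degenerate comparison: the variance of the TER difference is not ",
         "positive (identical, perfectly correlated estimates)")
  (tA - tB) / sqrt(denom2)
}

#' Two-algorithm hypothesis test on TERs
#'
#' Tests H0: the two algorithms have equal TER, against a two-sided
#' alternative, using the correlated Z statistic: both TERs and their
#' bootstrap SEs are estimated, the correlation between the TERs is
#' estimated by synchronized resampling, and the two-tailed p-value is taken
#' from the standard normal. When the two evaluations have identical
#' per-cell MERs there is no variation to test and the result reports
#' "no detectable difference".
#'
#' @inheritParams ter_correlation
#' @param M bootstrap/resampling replications.
#' @param alpha significance level for the reject / fail-to-reject decision.
#' @param seed optional integer seed driving all stochastic stages.
#' @return Object of class `ter_comparison`: list with the two
#'   `ter_estimate`s (`fit_a`, `fit_b`), `rho`, `rho_runs`, `z`, `p`
#'   (two-tailed), `p_underflow` flag, `decision`, `alpha` and the pairwise
#'   per-cell comparison counts (`pairwise`).
#' @export
compare_ter <- function(a, b, variant = c("weighted", "average", "proportion"),
                        M = 2000, runs = 10, alpha = 0.05, seed = NULL) {
  variant <- match.arg(variant)
  check_same_cells(a, b)
  fit_a <- ter(a, variant, M = M, alpha = alpha, seed = derive_seed(seed, stream = 1))
  fit_b <- ter(b, variant, M = M, alpha = alpha, seed = derive_seed(seed, stream = 2))
  pw <- pairwise_compare(a, b, variant)
  identical_mers <- isTRUE(all.equal(cell_mers(a, variant), cell_mers(b, variant),
                                     tolerance = 1e-15))
  if (identical_mers) {
    res <- list(fit_a = fit_a, fit_b = fit_b, rho = 1, rho_runs = rep(1, runs),
                z = NA_real_, p = NA_real_, p_underflow = FALSE,
                decision = "no detectable difference", alpha = alpha,
                pairwise = pw, variant = variant)
    class(res) <- "ter_comparison"
    return(res)
  }
  rho <- ter_correlation(a, b, variant, M = M, runs = runs, seed = seed)
  z <- z_statistic(fit_a$estimate, fit_a$se, fit_b$estimate, fit_b$se, as.numeric(rho))
  p <- 2 * stats::pnorm(-abs(z))
  underflow <- p < 1e-300
  if (underflow) p <- 0
  res <- list(fit_a = fit_a, fit_b = fit_b,
              rho = as.numeric(rho), rho_runs = attr(rho, "runs"),
              z = z, p = p, p_underflow = underflow,
              decision = if (p < alpha) "reject H0: TERs differ"
                         else "fail to reject H0",
              alpha = alpha, pairwise = pw, variant = variant)
  class(res) <- "ter_comparison"
  res
}

#' @export
print.ter_comparison <- function(x, ...) {
  cat(sprintf("Two-algorithm TER comparison (%s MER): '%s' vs '%s'\n",
              x$variant, x$fit_a$algorithm, x$fit_b$algorithm))
  cat(sprintf("  TER A = %.6f (SE %.6f), TER B = %.6f (SE %.6f)\n",
              x$fit_a$estimate, x$fit_a$se, x$fit_b$estimate, x$fit_b$se))
  cat(sprintf("  per-cell MERs: %d less, %d greater, %d equal\n",
              x$pairwise[["less"]], x$pairwise[["greater"]], x$pairwise[["equal"]]))
  if (is.na(x$z)) {
    cat("  identical per-cell MERs: no detectable difference\n")
  } else {
    cat(sprintf("  rho = %.6f (mean of %d runs), Z = %.3f, two-tailed p = %s\n",
                x$rho, length(x$rho_runs), x$z,
                if (x$p_underflow) "< 1e-300 (reported 0)"
                else format(x$p, digits = 3)))
    cat(sprintf("  decision at alpha = %g: %s\n", x$alpha, x$decision))
  }
  invisible(x)
}

#' One-algorithm test of a TER against a hypothesized value
#'
#' Locates the confidence interval of a TER estimate relative to a
#' hypothesized accuracy value: `"below"` when the whole CI lies below the
#' value (the algorithm is demonstrably better than the criterion),
#' `"above"` when the whole CI lies above it, `"contains"` otherwise.
#'
#' @param t a `ter_estimate`.
#' @param hypothesized the hypothesized TER value.
#' @return One of `"below"`, `"contains"`, `"above"`.
#' @export
one_algorithm_test <- function(t, hypothesized) {
  stopifnot(inherits(t, "ter_estimate"), is.numeric(hypothesized))
  if (t$ci[["upper"]] < hypothesized) return("below")
  if (t$ci[["lower"]] > hypothesized) return("above")
  "contains"
}

#' Classify algorithms into performance classes by their TER error bars
#'
#' Given ordered accuracy criteria (e.g. 0.08 and 0.14), an algorithm is
#' placed in class k when its whole confidence interval lies between the
#' (k-1)-th and k-th criterion; class 1 is the best. An interval crossing a
#' criterion is reported as `"straddles"` — the one-algorithm test against
#' that criterion is then the appropriate follow-up.
#'
#' @param estimates a list of `ter_estimate` objects (a single estimate is
#'   accepted).
#' @param criteria strictly increasing accuracy thresholds in (0, 1).
#' @return Character vector, one entry per algorithm (named by algorithm):
#'   the class index as a string, or `"straddles"`.
#' @export
classify_algorithms <- function(estimates, criteria) {
  if (inherits(estimates, "ter_estimate")) estimates <- list(estimates)
  if (length(estimates) < 1L) stop("need at least one estimate")
  criteria <- as.numeric(criteria)
  if (length(criteria) < 1L || is.unsorted(criteria, strictly = TRUE) ||
      any(criteria <= 0) || any(criteria >= 1))
    stop("criteria must be strictly increasing values in (0, 1)")
  out <- vapply(estimates, function(t) {
    lo <- findInterval(t$ci[["lower"]], criteria)
    hi <- findInterval(t$ci[["upper"]], criteria)
    if (lo == hi) as.character(lo + 1L) else "straddles"
  }, character(1))
  names(out) <- vapply(estimates, `[[`, character(1), "algorithm")
  out
}
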