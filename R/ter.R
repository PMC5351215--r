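#' Size-weighted total error rate of an evaluation
#'
#' The TER aggregates the per-cell MERs into a single algorithm-level error
#' rate, weighting each cell by its share of the total GT area:
#' `TER = sum_i MER_i * S_i / sum_j S_j`. Larger cells therefore contribute
#' proportionally more, so an algorithm pays a larger penalty for
#' mis-segmenting large cells.
#'
#' @param e a `seg_eval` object.
#' @param variant MER variant, see [mer()].
#' @return The TER, a number in \[0, 1\] bounded by the smallest and largest
#'   per-cell MER.
#' @export
total_error_rate <- function(e, variant = c("weighted", "average", "proportion")) {
  variant <- match.arg(variant)
  stopifnot(inherits(e, "seg_eval"))
  if (e$N < 1L) stop("empty evaluation")
  stats::weighted.mean(cell_mers(e, variant), e$cells$S)
}

#' Estimate the total error rate with bootstrap uncertainty
#'
#' The package's central estimator. Computes the size-weighted TER of a
#' segmentation evaluation together with its standard error — obtained by
#' running the constrained single-cell bootstrap ([bootstrap_se_mer()]) on
#' every cell and combining the per-cell SEs through the weight-squared
#' variance formula ([ter_variance()]) — and a normal-approximation
#' confidence interval.
#'
#' @param e a `seg_eval` object (from [seg_eval()], [read_counts_csv()],
#'   [match_cells()] or [simulate_counts()]).
#' @param variant MER variant, see [mer()]; the weighted MER is the
#'   recommended default.
#' @param M bootstrap replications per cell (default 2000).
#' @param alpha significance level of the confidence interval.
#' @param seed optional integer seed. Per-cell substreams are derived from
#'   it, so the result is independent of cell processing order.
#' @param method bootstrap resampling mode, see [bootstrap_se_mer()].
#' @param max_rejections cap on constraint-rejection draws per cell.
#' @return Object of class `ter_estimate`: list with `estimate`, `se`, `ci`
#'   (named lower/upper), `ci_out_of_range`, `relative_error` (percent),
#'   `variant`, `M`, `alpha`, `N`, `algorithm`, `absent_ad` (number of GT
#'   cells with no detected object, scored by the disjoint convention), and
#'   `cells` — the per-cell table with sizes, cases, MERs and bootstrap SEs.
#'
#' @examples
#' ev <- simulate_counts(n_cells = 10, r_fn = 0.05, r_fp = 0.05, seed = 1)
#' fit <- ter(ev, M = 200, seed = 1)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
ter <- function(e, variant = c("weighted", "average", "proportion"),
                M = 2000, alpha = 0.05, seed = NULL,
                method = c("binomial", "literal"), max_rejections = 1e6) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  stopifnot(inherits(e, "seg_eval"))
  cells <- e$cells
  cells$mer <- cell_mers(e, variant)
  cells$se <- vapply(seq_len(e$N), function(i) {
    bootstrap_se_mer(with(cells[i, ], pixel_counts(n_G, n_g, n_A, n_a)),
                     variant, M = M, seed = derive_seed(seed, index = i),
                     method = method, max_rejections = max_rejections)
  }, numeric(1))
  epsilon <- stats::weighted.mean(cells$mer, cells$S)
  se <- sqrt(ter_variance(e, cells$se))
  ci <- ter_confidence_interval(epsilon, se, alpha)
  structure(list(
    estimate = epsilon, se = se,
    ci = c(ci), ci_out_of_range = isTRUE(attr(ci, "out_of_range")),
    relative_error = if (epsilon > 0) relative_error(se, epsilon) else 0,
    variant = variant, M = M, alpha = alpha, N = e$N,
    algorithm = e$algorithm, absent_ad = sum(cells$n_A == 0),
    cells = cells),
    class = "ter_estimate")
}

#' @export
print.ter_estimate <- function(x, digits = 6, ...) {
  cat(sprintf("Total error rate ('%s', %s MER, N = %d cells, M = %d)\n",
              x$algorithm, x$variant, x$N, x$M))
  cat(sprintf("  TER         : %.*f\n", digits, x$estimate))
  cat(sprintf("  SE          : %.*f (relative error %.2f%%)\n",
              digits, x$se, x$relative_error))
  cat(sprintf("  %d%% CI      : (%.*f, %.*f)%s\n",
              round(100 * (1 - x$alpha)),
              digits, x$ci[["lower"]], digits, x$ci[["upper"]],
              if (x$ci_out_of_range) "  [extends outside [0,1]]" else ""))
  if (x$absent_ad > 0)
    cat(sprintf("  note: %d GT cell(s) had no detected object; scored as disjoint (rates 1,1)\n",
                x$absent_ad))
  invisible(x)
}

#' @export
summary.ter_estimate <- function(object, ...) {
  print(object, ...)
  cat("\nPer-cell MERs by case:\n")
  print(stats::aggregate(mer ~ case, data = object$cells,
                         FUN = function(v) round(mean(v), 6)))
  invisible(object)
}

#' @export
coef.ter_estimate <- function(object, ...) c(ter = object$estimate)

#' @export
confint.ter_estimate <- function(object, parm = "ter", level = 1 - object$alpha, ...) {
  ci <- if (abs(level - (1 - object$alpha)) < 1e-12) object$ci
        else c(ter_confidence_interval(object$estimate, object$se, 1 - level))
  m <- matrix(ci, nrow = 1,
              dimnames = list("ter", sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                                1 - (1 - level) / 2))))
  m
}

#' @export
plot.ter_estimate <- function(x, criteria = NULL, ...) {
  graphics::plot(1, x$estimate, ylim = range(0, x$ci, criteria, 0.05),
                 xlim = c(0.5, 1.5), xaxt = "n", xlab = x$algorithm,
                 ylab = sprintf("TER (%s MER)", x$variant), pch = 19, ...)
  graphics::arrows(1, x$ci[["lower"]], 1, x$ci[["upper"]],
                   angle = 90, code = 3, length = 0.08)
  if (!is.null(criteria))
    graphics::abline(h = criteria, lty = 2, col = "grey40")
  invisible(x)
}

#' One-row report table for a TER estimate
#'
#' @param x a `ter_estimate`.
#' @return Data frame with columns `algorithm`, `variant`, `ter`, `se`,
#'   `relative_error_pct`, `ci_lower`, `ci_upper` — the layout of a
#'   per-algorithm results table.
#' @export
ter_report <- function(x) {
  stopifnot(inherits(x, "ter_estimate"))
  data.frame(algorithm = x$algorithm, variant = x$variant,
             ter = x$estimate, se = x$se,
             relative_error_pct = x$relative_error,
             ci_lower = x$ci[["lower"]], ci_upper = x$ci[["upper"]],
             stringsAsFactors = FALSE)
}
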