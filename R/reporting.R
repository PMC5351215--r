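# Report-building layer behind the command-line interface. Each cmd_*
# function takes plain inputs (evaluations or file paths), runs the
# corresponding estimator, and returns the tables a run would write to disk.

resolve_evaluation <- function(input, algorithm = NULL, connectivity = 8) {
  if (inherits(input, "seg_eval")) return(input)
  if (is.character(input) && length(input) == 1L) {
    if (!file.exists(input)) stop("input file not found: ", input)
    if (tolower(tools::file_ext(input)) == "csv")
      return(read_counts_csv(input,
                             algorithm = algorithm %||% sub("\\.csv$", "", basename(input))))
    stop("single-file input must be a counts CSV: ", input)
  }
  if (is.character(input) && length(input) == 2L) {
    if (!all(file.exists(input)))
      stop("mask file not found: ", paste(input[!file.exists(input)], collapse = ", "))
    return(match_cells(read_label_mask(input[1]), read_label_mask(input[2]),
                       algorithm = algorithm %||% sub("\\.[^.]+$", "", basename(input[2])),
                       connectivity = connectivity))
  }
  stop("input must be a seg_eval, a counts CSV path, or c(gt_mask, ad_mask) paths")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate one algorithm: TER, SE, CI and per-cell table
#'
#' @param input a `seg_eval`, a counts CSV path, or a two-element character
#'   vector `c(gt_mask_path, ad_mask_path)`.
#' @param variant MER variant, see [mer()].
#' @param M bootstrap replications per cell.
#' @param alpha significance level.
#' @param seed optional integer seed.
#' @param bin_width MER histogram bin width.
#' @param connectivity component connectivity for binary masks.
#' @return List with `fit` (the `ter_estimate`), `summary` (one-row report
#'   table), `per_cell` (per-cell counts, cases, MERs, SEs), `mer_histogram`
#'   and `size_histogram`.
#' @export
cmd_evaluate <- function(input, variant = "weighted", M = 2000, alpha = 0.05,
                         seed = NULL, bin_width = 0.05, connectivity = 8) {
  e <- resolve_evaluation(input, connectivity = connectivity)
  fit <- ter(e, variant, M = M, alpha = alpha, seed = seed)
  sizes <- e$cells$S
  size_breaks <- pretty(sizes, 20)
  size_hist <- data.frame(lower = size_breaks[-length(size_breaks)],
                          upper = size_breaks[-1])
  size_hist$count <- vapply(seq_len(nrow(size_hist)), function(i)
    sum(sizes >= size_hist$lower[i] & (sizes < size_hist$upper[i] |
        (i == nrow(size_hist) & sizes == size_hist$upper[i]))), numeric(1))
  list(fit = fit, summary = ter_report(fit), per_cell = fit$cells,
       mer_histogram = mer_histogram(e, variant, bin_width),
       size_histogram = size_hist)
}

#' Compare two algorithms: pairwise counts, correlation, Z test, classes
#'
#' @param input_a,input_b inputs for the two algorithms, as in
#'   [cmd_evaluate()]; both must cover the same ordered GT cells.
#' @param criteria optional accuracy criteria for error-bar classification.
#' @inheritParams cmd_evaluate
#' @param runs independent correlation runs averaged.
#' @return List with `comparison` (the `ter_comparison`), `pairwise`,
#'   `classification` (present when `criteria` given; straddling intervals
#'   carry an advisory to run the one-algorithm test).
#' @export
cmd_compare <- function(input_a, input_b, variant = "weighted", M = 2000,
                        runs = 10, alpha = 0.05, seed = NULL,
                        criteria = NULL, connectivity = 8) {
  a <- resolve_evaluation(input_a, connectivity = connectivity)
  b <- resolve_evaluation(input_b, connectivity = connectivity)
  cmp <- compare_ter(a, b, variant, M = M, runs = runs, alpha = alpha, seed = seed)
  out <- list(comparison = cmp, pairwise = cmp$pairwise)
  if (!is.null(criteria)) {
    cls <- classify_algorithms(list(cmp$fit_a, cmp$fit_b), criteria)
    advisory <- ifelse(cls == "straddles",
                       "CI crosses a criterion: run one_algorithm_test()", "")
    out$classification <- data.frame(algorithm = names(cls), class = unname(cls),
                                     advisory = unname(advisory),
                                     stringsAsFactors = FALSE)
  }
  out
}

#' Variability study of the bootstrap SE of the TER
#'
#' @inheritParams cmd_evaluate
#' @param L Monte-Carlo repetitions of the full bootstrap.
#' @return List with `distribution` (the `se_ter_dist`), `summary` (one-row
#'   table: mean, SE, relative error, CI), and `samples` (the L raw values,
#'   for histogramming).
#' @export
cmd_variability <- function(input, variant = "weighted", M = 2000, L = 500,
                            alpha = 0.05, seed = NULL, connectivity = 8) {
  e <- resolve_evaluation(input, connectivity = connectivity)
  d <- se_ter_distribution(e, variant, M = M, L = L, alpha = alpha, seed = seed)
  list(distribution = d,
       summary = data.frame(algorithm = e$algorithm, variant = variant,
                            mean_se = d$mean, se_of_se = d$se,
                            relative_error_pct = d$relative_error,
                            ci_lower = d$ci[["lower"]], ci_upper = d$ci[["upper"]],
                            L = L, M = M, stringsAsFactors = FALSE),
       samples = d$samples)
}
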