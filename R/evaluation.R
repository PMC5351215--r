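#' Per-cell segmentation evaluation for one algorithm
#'
#' Assembles the ordered per-cell pixel-count records of one segmentation
#' algorithm over one set of ground-truth cells. Each row is validated as a
#' [pixel_counts()] quadruple; the intersection size and set-theoretic case
#' are derived. The cell order is the canonical GT ordering and must be
#' shared by every algorithm evaluated on the same GT set, which is what
#' makes evaluations comparable and synchronized resampling meaningful.
#'
#' @param counts a data frame with columns `cell_id`, `n_G`, `n_g`, `n_A`,
#'   `n_a` (one row per matched GT cell), or a single [pixel_counts()]
#'   object.
#' @param algorithm name of the algorithm under evaluation.
#' @return An object of class `seg_eval`: a list with elements `algorithm`,
#'   `cells` (a data frame with the validated counts plus `n_I`, `case` and
#'   `S`, the GT size used as the TER weight) and `N`, the number of GT
#'   cells.
#' @seealso [ter()], [read_counts_csv()], [match_cells()]
#' @export
seg_eval <- function(counts, algorithm = "algorithm") {
  if (inherits(counts, "pixel_counts"))
    counts <- data.frame(cell_id = "cell_1", n_G = counts$n_G, n_g = counts$n_g,
                         n_A = counts$n_A, n_a = counts$n_a)
  if (!is.data.frame(counts))
    stop("counts must be a data frame or a pixel_counts object")
  need <- c("cell_id", "n_G", "n_g", "n_A", "n_a")
  if (!all(need %in% names(counts)))
    stop("counts must have columns ", paste(need, collapse = ", "))
  if (nrow(counts) < 1L) stop("evaluation must cover at least one GT cell")
  if (anyDuplicated(counts$cell_id))
    stop("cell_id values must be unique")
  pcs <- lapply(seq_len(nrow(counts)), function(i)
    tryCatch(pixel_counts(counts$n_G[i], counts$n_g[i], counts$n_A[i], counts$n_a[i]),
             error = function(e) stop(sprintf("cell '%s': %s",
                                              counts$cell_id[i], conditionMessage(e)),
                                      call. = FALSE)))
  cells <- data.frame(
    cell_id = as.character(counts$cell_id),
    n_G = vapply(pcs, `[[`, numeric(1), "n_G"),
    n_g = vapply(pcs, `[[`, numeric(1), "n_g"),
    n_A = vapply(pcs, `[[`, numeric(1), "n_A"),
    n_a = vapply(pcs, `[[`, numeric(1), "n_a"),
    n_I = vapply(pcs, `[[`, numeric(1), "n_I"),
    case = vapply(pcs, classify_case, integer(1)),
    stringsAsFactors = FALSE)
  cells$S <- cells$n_G
  structure(list(algorithm = algorithm, cells = cells, N = nrow(cells)),
            class = "seg_eval")
}

#' @export
print.seg_eval <- function(x, ...) {
  cat(sprintf("Segmentation evaluation: '%s', %d GT cells\n", x$algorithm, x$N))
  tab <- table(factor(x$cells$case, levels = 1:5))
  cat("  cases (1 disjoint / 2 identical / 3 AD-in-GT / 4 GT-in-AD / 5 partial):\n  ")
  cat(paste(sprintf("%d: %d", 1:5, as.integer(tab)), collapse = ", "), "\n")
  cat(sprintf("  GT sizes: %d..%d px (mean %.0f)\n",
              min(x$cells$S), max(x$cells$S), mean(x$cells$S)))
  invisible(x)
}

#' @export
summary.seg_eval <- function(object, variant = "weighted", ...) {
  m <- cell_mers(object, variant)
  cat(sprintf("Evaluation '%s' (%s MER): N = %d, TER = %.6f\n",
              object$algorithm, variant, object$N,
              total_error_rate(object, variant)))
  print(summary(m))
  invisible(object)
}

# per-cell MERs of an evaluation, vectorized over rows
cell_mers <- function(e, variant = "weighted") {
  stopifnot(inherits(e, "seg_eval"))
  cells <- e$cells
  if (variant == "proportion")
    return((cells$n_g + cells$n_a) / (cells$n_G + cells$n_A))
  absent <- cells$n_A == 0
  r_fn <- ifelse(absent, 1, cells$n_g / cells$n_G)
  r_fp <- ifelse(absent, 1, cells$n_a / pmax(cells$n_A, 1))
  mer_from_rates(r_fn, r_fp, variant)
}

check_same_cells <- function(a, b) {
  stopifnot(inherits(a, "seg_eval"), inherits(b, "seg_eval"))
  if (a$N != b$N ||
      !identical(a$cells$cell_id, b$cells$cell_id) ||
      !identical(a$cells$n_G, b$cells$n_G))
    stop("evaluations do not cover the same ordered GT cells ",
         "(cell ids and GT sizes must match)")
  invisible(TRUE)
}

#' Pairwise per-cell comparison of two algorithms' MERs
#'
#' For every GT cell, compares the MER the two algorithms achieve and counts
#' how often the first is smaller, larger, or equal — the cell-by-cell
#' dominance summary that supports ranking algorithms before any aggregate
#' statistic is computed.
#'
#' @param a,b `seg_eval` objects over the same ordered GT cells.
#' @param variant MER variant, see [mer()].
#' @param tol absolute tolerance for calling two MERs equal.
#' @return Named integer vector `c(less = , greater = , equal = )` summing
#'   to the number of GT cells.
#' @export
pairwise_compare <- function(a, b, variant = "weighted", tol = 1e-12) {
  check_same_cells(a, b)
  ma <- cell_mers(a, variant)
  mb <- cell_mers(b, variant)
  eq <- abs(ma - mb) <= tol
  c(less = sum(!eq & ma < mb), greater = sum(!eq & ma > mb), equal = sum(eq))
}

#' Histogram of per-cell MERs
#'
#' @param e a `seg_eval` object.
#' @param variant MER variant, see [mer()].
#' @param bin_width histogram bin width on \[0, 1\].
#' @return Data frame with `lower`, `upper` bin edges and `count`; counts
#'   sum to the number of cells. Bins are left-closed, right-open, with the
#'   final bin closed at 1.
#' @export
mer_histogram <- function(e, variant = "weighted", bin_width = 0.05) {
  stopifnot(inherits(e, "seg_eval"))
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a positive number")
  m <- cell_mers(e, variant)
  if (length(m) == 0L) stop("no MER values to bin")
  edges <- seq(0, 1 + bin_width, by = bin_width)
  idx <- pmin(findInterval(m, edges), length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  keep <- edges[-length(edges)] < 1 + 1e-12
  data.frame(lower = edges[-length(edges)][keep],
             upper = edges[-1L][keep],
             count = counts[keep])
}

#' Read and write the per-cell counts interchange CSV
#'
#' The interchange format between all stages is a plain CSV with header
#' `cell_id,n_G,n_g,n_A,n_a`, one row per matched GT cell.
#'
#' @param path file path.
#' @param algorithm algorithm name attached to the evaluation on read.
#' @return `read_counts_csv()` returns a `seg_eval`; `write_counts_csv()`
#'   invisibly returns `path`.
#' @export
read_counts_csv <- function(path, algorithm = sub("\\.csv$", "", basename(path))) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  seg_eval(df, algorithm = algorithm)
}

#' @rdname read_counts_csv
#' @param e a `seg_eval` object to write.
#' @export
write_counts_csv <- function(e, path) {
  stopifnot(inherits(e, "seg_eval"))
  utils::write.csv(e$cells[c("cell_id", "n_G", "n_g", "n_A", "n_a")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
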