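#' Pixel-count quadruple for one matched ground-truth / detected cell pair
#'
#' Builds and validates the pixel counts describing how an algorithm-detected
#' (AD) cell overlaps its ground-truth (GT) cell: the GT cell size `n_G`, the
#' false-negative (missed) region size `n_g`, the AD cell size `n_A`, and the
#' false-positive (spurious) region size `n_a`. The intersection size
#' `n_I = n_G - n_g` is derived. The counts must satisfy the constraint
#' `n_G - n_g == n_A - n_a`, i.e. both differences equal the size of the
#' intersection region.
#'
#' @param n_G GT cell size in pixels (integer, at least 1).
#' @param n_g false-negative region size (GT pixels the algorithm missed).
#' @param n_A AD cell size in pixels. `n_A = 0` encodes a GT cell for which
#'   the algorithm produced no object at all (treated as a disjoint pair).
#' @param n_a false-positive region size (AD pixels outside the GT cell).
#'
#' @return An object of class `pixel_counts`: a named list with elements
#'   `n_G`, `n_g`, `n_A`, `n_a` and the derived `n_I`.
#'
#' @examples
#' pc <- pixel_counts(4694, 16, 5276, 598)
#' pc$n_I           # 4678
#' classify_case(pc) # 5: partial overlap
#' @export
pixel_counts <- function(n_G, n_g, n_A, n_a) {
  vals <- c(n_G = n_G, n_g = n_g, n_A = n_A, n_a = n_a)
  if (length(vals) != 4L || anyNA(vals) || !is.numeric(vals))
    stop("pixel counts must be four non-missing numbers")
  if (any(vals < 0))
    stop("pixel counts must be non-negative")
  if (any(abs(vals - round(vals)) > 1e-8))
    stop("pixel counts must be integers")
  vals <- round(vals)
  if (vals[["n_G"]] < 1)
    stop("n_G must be at least 1 (a GT cell has at least one pixel)")
  if (vals[["n_g"]] > vals[["n_G"]])
    stop("n_g cannot exceed n_G")
  if (vals[["n_a"]] > vals[["n_A"]])
    stop("n_a cannot exceed n_A")
  if ((vals[["n_G"]] - vals[["n_g"]]) != (vals[["n_A"]] - vals[["n_a"]]))
    stop(sprintf(
      "constraint violation: n_G - n_g = %d but n_A - n_a = %d (both must equal n_I)",
      vals[["n_G"]] - vals[["n_g"]], vals[["n_A"]] - vals[["n_a"]]))
  out <- as.list(vals)
  out$n_I <- vals[["n_G"]] - vals[["n_g"]]
  class(out) <- "pixel_counts"
  out
}

#' @export
print.pixel_counts <- function(x, ...) {
  cat(sprintf(
    "pixel_counts: n_G = %d, n_g = %d, n_A = %d, n_a = %d (n_I = %d), Case %d\n",
    x$n_G, x$n_g, x$n_A, x$n_a, x$n_I, classify_case(x)))
  invisible(x)
}

as_pixel_counts <- function(x) {
  if (inherits(x, "pixel_counts")) return(x)
  if (is.numeric(x) && length(x) == 4L)
    return(pixel_counts(x[[1L]], x[[2L]], x[[3L]], x[[4L]]))
  stop("cannot interpret input as pixel counts")
}

#' Set-theoretic case of a GT/AD cell pair
#'
#' Classifies the relationship between a ground-truth cell and its detected
#' counterpart into the five possible cases: 1 disjoint, 2 identical,
#' 3 AD strictly inside GT, 4 GT strictly inside AD, 5 partial overlap.
#'
#' @param counts a [pixel_counts()] object (or a numeric quadruple).
#' @return Integer case label in 1..5.
#' @export
classify_case <- function(counts) {
  c <- as_pixel_counts(counts)
  if (c$n_I == 0L) return(1L)
  if (c$n_g == 0L && c$n_a == 0L) return(2L)
  if (c$n_a == 0L) return(3L)
  if (c$n_g == 0L) return(4L)
  5L
}

#' False-negative and false-positive rates of one cell pair
#'
#' The FN rate is the fraction of GT pixels the algorithm missed,
#' `r_fn = n_g / n_G`; the FP rate is the fraction of AD pixels that fall
#' outside the GT cell, `r_fp = n_a / n_A`. When the algorithm produced no
#' object at all (`n_A = 0`) both rates are defined to be 1, the disjoint-pair
#' convention; the result then carries the attribute `absent_ad = TRUE`.
#'
#' @inheritParams classify_case
#' @return Named numeric vector `c(r_fn = , r_fp = )`, each in \[0, 1\].
#' @export
error_rates <- function(counts) {
  c <- as_pixel_counts(counts)
  if (c$n_A == 0L) {
    out <- c(r_fn = 1, r_fp = 1)
    attr(out, "absent_ad") <- TRUE
    return(out)
  }
  c(r_fn = c$n_g / c$n_G, r_fp = c$n_a / c$n_A)
}

mer_variants <- c("weighted", "average", "proportion")

# vectorized MER from rates; proportion needs counts and is handled separately
mer_from_rates <- function(r_fn, r_fp, variant) {
  switch(variant,
    average = (r_fn + r_fp) / 2,
    weighted = {
      s <- r_fn + r_fp
      ifelse(s == 0, 0, (r_fn^2 + r_fp^2) / s)
    },
    stop("unknown MER variant: ", variant))
}

#' Misclassification error rate (MER) of one cell pair
#'
#' Three single-cell error measures built from the FN and FP rates:
#' \describe{
#'   \item{`weighted`}{`(r_fn^2 + r_fp^2) / (r_fn + r_fp)` — each rate
#'     weighted by itself, so the larger error pays the larger penalty;
#'     defined as 0 in the perfect-segmentation limit `r_fn = r_fp = 0`.
#'     The recommended default throughout the package.}
#'   \item{`average`}{the arithmetic mean `(r_fn + r_fp) / 2`.}
#'   \item{`proportion`}{the fraction of misclassified pixels,
#'     `(n_g + n_a) / (n_G + n_A)`.}
#' }
#' All variants lie in \[0, 1\]; disjoint pairs give 1, identical pairs 0.
#'
#' @inheritParams classify_case
#' @param variant one of `"weighted"`, `"average"`, `"proportion"`.
#' @return The MER, a number in \[0, 1\].
#'
#' @examples
#' mer(pixel_counts(4694, 16, 5276, 598), "average")    # 0.058376
#' mer(pixel_counts(1420, 5, 3492, 2077), "proportion") # 0.423860
#' @export
mer <- function(counts, variant = c("weighted", "average", "proportion")) {
  variant <- match.arg(variant)
  c <- as_pixel_counts(counts)
  if (variant == "proportion") {
    if (c$n_G + c$n_A == 0L) stop("degenerate pair with no pixels")
    return((c$n_g + c$n_a) / (c$n_G + c$n_A))
  }
  r <- error_rates(c)
  mer_from_rates(r[["r_fn"]], r[["r_fp"]], variant)
}
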