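# Synthetic fixtures at two levels: pixel-count quadruples with planted
# FN/FP rate structure, and label-mask pairs with planted morphological
# perturbations. Everything downstream depends only on pixel counts, so
# ellipse-ish blobs are a sufficient stand-in for real cell morphologies.

resolve_rate_law <- function(r, default_shape = c(2, 18)) {
  if (is.function(r)) return(r)
  if (is.numeric(r) && length(r) == 1L) {
    if (r < 0 || r > 1) stop("a constant rate must lie in [0, 1]")
    force(r)
    return(function(n) rep(r, n))
  }
  if (is.numeric(r) && length(r) == 2L)
    return(function(n) stats::rbeta(n, r[1], r[2]))
  stop("rate law must be a constant, Beta shape pair, or function(n)")
}

#' Simulate a segmentation evaluation from planted error rates
#'
#' Draws per-cell GT sizes from a log-uniform law spanning the size range
#' typical of cultured-cell fluorescence data (647 to 27,562 pixels by
#' default) and plants FN/FP rates per cell, then constructs integer pixel
#' counts honouring the overlap constraint: `n_g = round(r_fn * n_G)`,
#' `n_I = n_G - n_g`, and `n_a` chosen so that `n_a / n_A` matches the
#' planted FP rate as closely as integer pixels allow
#' (`n_a = round(r_fp * n_I / (1 - r_fp))`, `n_A = n_I + n_a`). A planted
#' `r_fn = 1` produces a disjoint (Case 1) record with a size-matched
#' disjoint AD object. Planted FP rates so close to 1 that no finite AD
#' size fits are redrawn up to a cap.
#'
#' @param n_cells number of GT cells.
#' @param size_range two-element range of GT sizes in pixels; sizes are
#'   drawn log-uniformly over it.
#' @param r_fn,r_fp planted rate laws: a constant in \[0, 1\], a length-2
#'   Beta shape pair, or a `function(n)` returning n draws. Default
#'   Beta(2, 18), mean 0.1.
#' @param seed optional integer seed (all randomness flows from it).
#' @param algorithm algorithm name for the evaluation.
#' @param max_redraws cap on redraws of infeasible rate pairs per cell.
#' @return A `seg_eval` with attribute `"planted"`, a data frame of the
#'   per-cell planted rates.
#'
#' @examples
#' ev <- simulate_counts(n_cells = 5, r_fn = 0.1, r_fp = 0.1, seed = 42)
#' ev$cells
#' @export
simulate_counts <- function(n_cells = 20, size_range = c(647, 27562),
                            r_fn = c(2, 18), r_fp = c(2, 18),
                            seed = NULL, algorithm = "simulated",
                            max_redraws = 100) {
  if (!is.numeric(n_cells) || n_cells < 1) stop("n_cells must be at least 1")
  if (length(size_range) != 2L || any(size_range < 1) ||
      size_range[1] > size_range[2])
    stop("size_range must be an increasing pair of sizes >= 1")
  fn_law <- resolve_rate_law(r_fn)
  fp_law <- resolve_rate_law(r_fp)
  with_seed(seed, {
    n_G <- round(exp(stats::runif(n_cells, log(size_range[1]), log(size_range[2]))))
    fn <- fn_law(n_cells)
    fp <- fp_law(n_cells)
    if (any(fn < 0 | fn > 1 | fp < 0 | fp > 1))
      stop("rate law produced values outside [0, 1]")
    rows <- lapply(seq_len(n_cells), function(i) {
      g <- n_G[i]; rfn <- fn[i]; rfp <- fp[i]
      for (try in seq_len(max_redraws)) {
        n_g <- round(rfn * g)
        n_I <- g - n_g
        if (n_I == 0) {  # fully missed: disjoint, size-matched AD object
          return(data.frame(cell_id = paste0("cell_", i), n_G = g, n_g = g,
                            n_A = g, n_a = g, r_fn = rfn, r_fp = 1))
        }
        n_a <- round(rfp * n_I / (1 - rfp))
        if (is.finite(n_a) && n_a <= 100 * n_I)
          return(data.frame(cell_id = paste0("cell_", i), n_G = g, n_g = n_g,
                            n_A = n_I + n_a, n_a = n_a, r_fn = rfn, r_fp = rfp))
        rfp <- fp_law(1)  # infeasible FP rate for this cell: redraw
      }
      stop("could not realize a feasible FP rate for cell ", i,
           " after ", max_redraws, " redraws")
    })
    df <- do.call(rbind, rows)
    e <- seg_eval(df[c("cell_id", "n_G", "n_g", "n_A", "n_a")],
                  algorithm = algorithm)
    attr(e, "planted") <- df[c("cell_id", "r_fn", "r_fp")]
    e
  })
}

#' Generate a synthetic ground-truth label mask
#'
#' Places `n_cells` pairwise-disjoint convex-ish blobs (ellipses with
#' low-frequency boundary noise) on an empty grid. Objects keep a margin
#' from each other and from the border so that small morphological
#' perturbations cannot merge or clip them.
#'
#' @param width,height mask dimensions in pixels.
#' @param n_cells number of objects to place.
#' @param area_range two-element range of target object areas in pixels.
#' @param boundary_noise relative amplitude of the radial boundary
#'   modulation (0 gives pure ellipses).
#' @param margin minimum pixel gap kept between objects and to the border.
#' @param seed optional integer seed.
#' @param max_tries placement attempts per object before failing.
#' @return Integer label matrix with objects labeled 1..n_cells.
#' @export
generate_gt_mask <- function(width = 128, height = 128, n_cells = 5,
                             area_range = c(80, 400), boundary_noise = 0.1,
                             margin = 3, seed = NULL, max_tries = 500) {
  if (any(area_range <= 0)) stop("requested object area must be positive")
  if (n_cells < 1) stop("n_cells must be at least 1")
  with_seed(seed, {
    mask <- matrix(0L, height, width)
    blocked <- matrix(FALSE, height, width)  # occupied + margin halo
    for (k in seq_len(n_cells)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        area <- stats::runif(1, area_range[1], area_range[2])
        aspect <- stats::runif(1, 1, 2.2)
        b <- sqrt(area / (pi * aspect)); a <- aspect * b
        theta <- stats::runif(1, 0, pi)
        # low-frequency radial modulation, same for the whole boundary
        ks <- 2:4
        amp <- boundary_noise * stats::runif(3, 0, 1)
        phase <- stats::runif(3, 0, 2 * pi)
        rmax <- a * (1 + sum(amp))
        pad <- ceiling(rmax) + margin
        if (2 * pad + 2 >= min(width, height)) next
        cx <- stats::runif(1, pad + 1, width - pad)
        cy <- stats::runif(1, pad + 1, height - pad)
        rows <- max(1L, floor(cy - pad)):min(height, ceiling(cy + pad))
        cols <- max(1L, floor(cx - pad)):min(width, ceiling(cx + pad))
        yy <- matrix(rows - cy, length(rows), length(cols))
        xx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
        xr <- xx * cos(theta) + yy * sin(theta)
        yr <- -xx * sin(theta) + yy * cos(theta)
        phi <- atan2(yr / b, xr / a)
        mod <- 1 + amp[1] * sin(ks[1] * phi + phase[1]) +
               amp[2] * sin(ks[2] * phi + phase[2]) +
               amp[3] * sin(ks[3] * phi + phase[3])
        inside <- (xr / a)^2 + (yr / b)^2 <= mod^2
        if (!any(inside)) next
        if (any(blocked[rows, cols][inside])) next
        sub <- mask[rows, cols]
        sub[inside] <- k
        mask[rows, cols] <- sub
        # extend the no-go halo: object pixels dilated by the margin
        hr <- max(1L, min(rows) - margin):min(height, max(rows) + margin)
        hc <- max(1L, min(cols) - margin):min(width, max(cols) + margin)
        obj <- matrix(as.integer(mask[hr, hc] == k), length(hr), length(hc))
        halo <- matrix(FALSE, length(hr), length(hc))
        for (dr in -margin:margin) for (dc in -margin:margin) {
          halo <- halo | shift_matrix(obj, dr, dc) > 0
        }
        blocked[hr, hc] <- blocked[hr, hc] | halo
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place object ", k, " after ", max_tries,
             " attempts; reduce n_cells or area_range")
    }
    mask
  })
}

#' Perturb a ground-truth mask into a synthetic detection mask
#'
#' Applies per-object morphological perturbations with known qualitative
#' effect on the error structure: dilation adds FP pixels only (GT inside
#' AD, Case 4), erosion removes boundary pixels only (AD inside GT, Case 3),
#' translation creates partial overlap (Case 5), and dropping an object
#' creates a miss (Case 1). Identity parameters return the GT mask itself
#' (all Case 2).
#'
#' @param gt a GT label mask from [generate_gt_mask()].
#' @param erode_radius,dilate_radius disc radius in pixels (0 = none;
#'   mutually exclusive per call).
#' @param shift integer `c(rows, cols)` translation applied to every object.
#' @param drop_probability probability of removing each object entirely.
#' @param seed optional integer seed (drives dropping only).
#' @return Integer label mask of detected objects, labels matching the GT
#'   labels of the surviving objects.
#' @export
perturb_mask <- function(gt, erode_radius = 0, dilate_radius = 0,
                         shift = c(0, 0), drop_probability = 0, seed = NULL) {
  stopifnot(is.matrix(gt))
  if (erode_radius > 0 && dilate_radius > 0)
    stop("choose erosion or dilation, not both")
  labs <- sort(unique(gt[gt > 0]))
  with_seed(seed, {
    drop <- stats::runif(length(labs)) < drop_probability
    out <- matrix(0L, nrow(gt), ncol(gt))
    for (j in seq_along(labs)) {
      if (drop[j]) next
      l <- labs[j]
      obj <- matrix(as.integer(gt == l), nrow(gt), ncol(gt))
      if (erode_radius > 0)
        obj <- EBImage::erode(obj, EBImage::makeBrush(2 * erode_radius + 1, "disc"))
      if (dilate_radius > 0)
        obj <- EBImage::dilate(obj, EBImage::makeBrush(2 * dilate_radius + 1, "disc"))
      obj <- matrix(as.integer(obj > 0), nrow(gt), ncol(gt))
      if (any(shift != 0)) obj <- shift_matrix(obj, shift[1], shift[2])
      out[obj > 0] <- l
    }
    out
  })
}
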