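# Label masks are plain integer matrices: 0 is background, positive values
# are object labels (not necessarily contiguous). Coordinates are 0-based
# row-major in the file; in R they are ordinary matrix indices.

#' Read a 2-D label mask from TIFF or PNG
#'
#' Accepts 8- or 16-bit integer-valued grayscale rasters. Multi-channel
#' (RGB) images and floating-point pixel data are rejected: a label mask is
#' a single integer grid.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @return Integer matrix of labels.
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bps <- attr(img, "bits.per.sample")
    if (!is.null(bps) && any(bps > 16))
      stop("pixel data are not 8- or 16-bit integer labels: ", path)
  } else if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 2L) {
      # readPNG rescales to [0,1]; undo the 8- or 16-bit scaling
      v8 <- img * 255
      img <- if (max(abs(v8 - round(v8))) < 1e-6) round(v8) else {
        v16 <- img * 65535
        if (max(abs(v16 - round(v16))) < 1e-6) round(v16)
        else stop("PNG pixel values are not integer labels: ", path)
      }
    }
  } else stop("unsupported mask format '", ext, "' (use TIFF or PNG): ", path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1L]
    else stop("multi-channel (RGB) image is not a label mask: ", path)
  }
  if (!is.matrix(img)) stop("mask is not a 2-D image: ", path)
  if (max(abs(img - round(img))) > 1e-8)
    stop("floating-point pixels are not integer labels: ", path)
  if (any(img < 0)) stop("negative pixel values in mask: ", path)
  matrix(as.integer(round(img)), nrow(img), ncol(img))
}

#' Write a label mask to TIFF (16-bit) or PNG (8-bit) grayscale
#'
#' @param mask integer matrix of labels (0 = background); up to 65535
#'   labels for TIFF, 255 for PNG.
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return Invisibly, `path`.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask >= 0), max(mask) <= 65535)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  } else if (ext == "png") {
    if (max(mask) > 255) stop("PNG label masks support at most 255 labels")
    png::writePNG(mask / 255, path)
  } else stop("unsupported mask format '", ext, "'")
  invisible(path)
}

# shift a matrix by (dr, dc), padding with 0
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' Label connected components of a binary mask
#'
#' A mask holding a single positive value is split into connected
#' components, labeled 1..K; a mask that is already multi-labeled is
#' returned unchanged. Connectivity 8 (edge or corner adjacency) is the
#' default for cell masks; connectivity 4 uses edge adjacency only.
#'
#' @param mask integer matrix (0 = background).
#' @param connectivity 4 or 8.
#' @return Integer label matrix with components numbered 1..K in order of
#'   first (column-major) occurrence.
#' @export
label_binary_mask <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  pos <- unique(mask[mask > 0])
  if (length(pos) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  if (length(pos) > 1L) return(mask)  # already labeled
  fg <- mask > 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[fg] <- seq_len(sum(fg))
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  # iterative minimum-label propagation until a fixed point
  repeat {
    new <- lab
    for (o in offs) {
      nb <- shift_matrix(lab, o[1], o[2])
      take <- fg & nb > 0 & (new == 0 | nb < new)
      new[take] <- nb[take]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab[fg] <- match(lab[fg], sort(unique(lab[fg])))
  lab
}

#' Match GT and AD objects and extract per-cell pixel counts
#'
#' Builds the bipartite overlap graph between ground-truth and detected
#' objects (an edge whenever two objects share at least one pixel) and takes
#' its connected components as match groups, so that several AD fragments
#' covering one GT cell are pooled into one detected region, and several GT
#' cells covered by one AD object are likewise pooled — both merging rules
#' hold simultaneously by transitive closure. Each group yields one
#' pixel-count record: `n_G` pooled GT pixels, `n_A` pooled AD pixels,
#' `n_I` shared pixels, `n_g = n_G - n_I`, `n_a = n_A - n_I`. GT cells with
#' no overlapping AD object become disjoint (Case 1) records with `n_A = 0`
#' (the absent-detection convention). AD objects overlapping no GT cell do
#' not enter the evaluation; see [unmatched_ad_objects()].
#'
#' @param gt,ad label masks of identical shape (binary masks are labeled
#'   first).
#' @param algorithm algorithm name for the resulting evaluation.
#' @param connectivity component connectivity used if a mask is binary.
#' @return A `seg_eval` whose records are the match groups, ordered by
#'   smallest GT label. The attribute `"match_groups"` lists the GT and AD
#'   labels pooled into each record; `"unmatched_ad"` holds the spurious AD
#'   object table of [unmatched_ad_objects()].
#' @export
match_cells <- function(gt, ad, algorithm = "algorithm", connectivity = 8) {
  stopifnot(is.matrix(gt), is.matrix(ad))
  if (!all(dim(gt) == dim(ad)))
    stop(sprintf("mask shapes differ: %dx%d vs %dx%d",
                 nrow(gt), ncol(gt), nrow(ad), ncol(ad)))
  gt <- label_binary_mask(gt, connectivity)
  ad <- label_binary_mask(ad, connectivity)
  gsize <- table(gt[gt > 0])
  asize <- table(ad[ad > 0])
  both <- gt > 0 & ad > 0
  ov <- if (any(both)) {
    agg <- stats::aggregate(list(n = rep(1L, sum(both))),
                            by = list(g = gt[both], a = ad[both]), FUN = sum)
    agg
  } else data.frame(g = integer(0), a = integer(0), n = integer(0))
  # paste0 on zero-length input yields "" not character(0); guard empties
  tag <- function(prefix, x) if (length(x)) paste0(prefix, x) else character(0)
  gnames <- tag("G", names(gsize))
  anames <- tag("A", names(asize))
  graph <- igraph::graph_from_data_frame(
    data.frame(from = tag("G", ov$g), to = tag("A", ov$a)),
    directed = FALSE, vertices = data.frame(name = c(gnames, anames)))
  comp <- igraph::components(graph)
  membership <- comp$membership
  groups <- split(names(membership), membership)
  # keep only groups containing at least one GT object
  groups <- Filter(function(gp) any(startsWith(gp, "G")), groups)
  recs <- lapply(groups, function(gp) {
    gl <- as.integer(sub("^G", "", gp[startsWith(gp, "G")]))
    al <- as.integer(sub("^A", "", gp[startsWith(gp, "A")]))
    n_G <- sum(gsize[as.character(gl)])
    n_A <- if (length(al)) sum(asize[as.character(al)]) else 0L
    n_I <- sum(ov$n[ov$g %in% gl & ov$a %in% al])
    list(gt_labels = gl, ad_labels = al,
         row = data.frame(cell_id = paste0("G", min(gl)),
                          n_G = as.integer(n_G), n_g = as.integer(n_G - n_I),
                          n_A = as.integer(n_A), n_a = as.integer(n_A - n_I)))
  })
  ord <- order(vapply(recs, function(r) min(r$gt_labels), numeric(1)))
  recs <- recs[ord]
  counts <- do.call(rbind, lapply(recs, `[[`, "row"))
  e <- seg_eval(counts, algorithm = algorithm)
  attr(e, "match_groups") <- lapply(recs, function(r)
    list(gt_labels = r$gt_labels, ad_labels = r$ad_labels))
  attr(e, "unmatched_ad") <- unmatched_ad_objects(gt, ad, connectivity)
  e
}

#' Detected objects with no ground-truth overlap
#'
#' The TER is defined per GT cell, so a spurious detected object touching no
#' GT pixel contributes nothing to it. Such objects are listed here so the
#' limitation stays visible in reports.
#'
#' @inheritParams match_cells
#' @return Data frame with columns `ad_label` and `size` (pixels).
#' @export
unmatched_ad_objects <- function(gt, ad, connectivity = 8) {
  stopifnot(is.matrix(gt), is.matrix(ad))
  if (!all(dim(gt) == dim(ad))) stop("mask shapes differ")
  gt <- label_binary_mask(gt, connectivity)
  ad <- label_binary_mask(ad, connectivity)
  matched <- unique(ad[gt > 0 & ad > 0])
  labs <- sort(unique(ad[ad > 0]))
  labs <- setdiff(labs, matched)
  data.frame(ad_label = labs,
             size = vapply(labs, function(l) sum(ad == l), numeric(1)))
}
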