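test_that("label masks round-trip through 16-bit TIFF and PNG", {
  m <- matrix(0L, 8, 10)
  m[2:3, 2:4] <- 1L
  m[6:7, 7:9] <- 2L
  for (ext in c(".tif", ".png")) {
    path <- tempfile(fileext = ext)
    write_label_mask(m, path)
    back <- read_label_mask(path)
    expect_identical(back, m)
    expect_equal(sort(unique(back[back > 0])), c(1L, 2L))
  }
  # all-background image: an empty mask, zero objects
  empty <- tempfile(fileext = ".tif")
  write_label_mask(matrix(0L, 4, 4), empty)
  expect_equal(sum(read_label_mask(empty) > 0), 0)
  expect_error(read_label_mask(tempfile(fileext = ".tif")), "not found")
  bmp <- tempfile(fileext = ".bmp")
  writeLines("not a raster", bmp)
  expect_error(read_label_mask(bmp), "unsupported")
})

test_that("multi-channel and floating-point rasters are rejected", {
  rgb <- tempfile(fileext = ".png")
  png::writePNG(array(runif(48), dim = c(4, 4, 3)), rgb)
  expect_error(read_label_mask(rgb), "RGB")
  flt <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(16), 4, 4), flt, bits.per.sample = 32)
  expect_error(read_label_mask(flt), "integer")
})

test_that("binary masks are labeled under the requested connectivity", {
  m <- matrix(0L, 6, 6)
  m[1:2, 1:2] <- 1L
  m[5:6, 5:6] <- 1L
  lab <- label_binary_mask(m)
  expect_equal(sort(unique(lab[lab > 0])), c(1L, 2L))
  single <- matrix(0L, 3, 3); single[2, 2] <- 1L
  expect_equal(max(label_binary_mask(single)), 1L)
  diag2 <- matrix(0L, 4, 4); diag2[1, 1] <- 1L; diag2[2, 2] <- 1L
  expect_equal(max(label_binary_mask(diag2, connectivity = 8)), 1L)
  expect_equal(max(label_binary_mask(diag2, connectivity = 4)), 2L)
  # an already-labeled mask passes through unchanged
  multi <- matrix(c(0L, 3L, 0L, 7L), 2, 2)
  expect_identical(label_binary_mask(multi), multi)
  expect_error(label_binary_mask(m, connectivity = 6), "4 or 8")
})

test_that("GT/AD matching pools overlapping objects and emits valid counts", {
  # GT: one 4-pixel square; AD: 3 of those pixels plus 2 outside
  gt <- matrix(0L, 6, 6); gt[2:3, 2:3] <- 1L
  ad <- matrix(0L, 6, 6); ad[2:3, 2] <- 1L; ad[2, 3] <- 1L; ad[2, 4:5] <- 1L
  e <- match_cells(gt, ad, "toy")
  expect_equal(e$N, 1L)
  expect_equal(unlist(e$cells[1, c("n_G", "n_g", "n_A", "n_a")], use.names = FALSE),
               c(4, 1, 5, 2))
  expect_equal(e$cells$case, 5L)

  # a GT object with zero AD overlap becomes a disjoint record
  gt2 <- gt; gt2[5:6, 5:6] <- 2L
  e2 <- match_cells(gt2, ad)
  expect_equal(e2$N, 2L)
  expect_equal(e2$cells$case[2], 1L)
  expect_equal(e2$cells$n_A[2], 0)

  # two AD fragments over one GT cell are pooled into one detected region
  gt3 <- matrix(0L, 6, 8); gt3[2:5, 2:7] <- 1L
  ad3 <- matrix(0L, 6, 8); ad3[2:5, 2:3] <- 1L; ad3[2:5, 6:7] <- 2L
  e3 <- match_cells(gt3, ad3)
  expect_equal(e3$N, 1L)
  expect_equal(e3$cells$n_A, 16)
  groups <- attr(e3, "match_groups")
  expect_equal(sort(groups[[1]]$ad_labels), c(1L, 2L))

  # two GT cells under one AD object are pooled likewise
  gt4 <- matrix(0L, 6, 8); gt4[2:5, 2:3] <- 1L; gt4[2:5, 6:7] <- 2L
  ad4 <- matrix(0L, 6, 8); ad4[2:5, 2:7] <- 1L
  e4 <- match_cells(gt4, ad4)
  expect_equal(e4$N, 1L)
  expect_equal(e4$cells$n_G, 16)
  expect_equal(e4$cells$n_g, 0)
  expect_equal(e4$cells$case, 4L)

  expect_error(match_cells(gt, matrix(0L, 5, 6)), "shapes differ")
})

test_that("matching conserves shared pixels and satisfies the constraint", {
  set.seed(41)
  for (rep in 1:5) {
    gt <- matrix(as.integer(runif(400) < 0.3), 20, 20)
    ad <- matrix(as.integer(runif(400) < 0.3), 20, 20)
    e <- match_cells(gt, ad)   # seg_eval() already validates every record
    shared <- sum(gt > 0 & ad > 0)
    expect_equal(sum(e$cells$n_I), shared)
    expect_equal(e$cells$n_G - e$cells$n_g, e$cells$n_A - e$cells$n_a)
  }
})

test_that("spurious detections are reported, not silently scored", {
  gt <- matrix(0L, 8, 8); gt[2:3, 2:3] <- 1L
  ad <- matrix(0L, 8, 8); ad[2:3, 2:3] <- 1L; ad[6:7, 6:7] <- 2L
  sp <- unmatched_ad_objects(gt, ad)
  expect_equal(sp$ad_label, 2L)
  expect_equal(sp$size, 4)
  expect_equal(nrow(unmatched_ad_objects(gt, gt)), 0)
  e <- match_cells(gt, ad)
  expect_equal(attr(e, "unmatched_ad")$ad_label, 2L)
  expect_equal(e$N, 1L)  # the spurious object does not enter the TER
})
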