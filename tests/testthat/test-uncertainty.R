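test_that("bootstrap SE matches the exact truncated-binomial oracle", {
  pc <- pixel_counts(4, 2, 4, 2)
  expect_equal(exact_se_mer_oracle(pc, "weighted"), 0.25)
  expect_equal(exact_se_mer_oracle(pixel_counts(2, 1, 2, 1), "average"),
               sqrt(1 / 8))
  expect_equal(exact_se_mer_oracle(pixel_counts(10, 0, 10, 0)), 0)
  se <- bootstrap_se_mer(pc, "weighted", M = 2000, seed = 1)
  expect_lt(abs(se - 0.25), sd_mc_tolerance(pc, "weighted", 2000))
  # a spread of cases and variants against the oracle
  for (pc in case345_grid()[seq(1, 54, by = 3)]) {
    for (v in c("weighted", "average", "proportion")) {
      se <- bootstrap_se_mer(pc, v, M = 2000, seed = 7)
      expect_lt(abs(se - exact_se_mer_oracle(pc, v)),
                sd_mc_tolerance(pc, v, 2000))
    }
  }
})

test_that("literal score resampling agrees with the binomial shortcut", {
  for (pc in list(pixel_counts(12, 3, 15, 6), pixel_counts(20, 6, 14, 0),
                  pixel_counts(10, 0, 16, 6))) {
    lit <- bootstrap_se_mer(pc, "weighted", M = 2000, seed = 5, method = "literal")
    expect_lt(abs(lit - exact_se_mer_oracle(pc, "weighted")),
              sd_mc_tolerance(pc, "weighted", 2000))
  }
})

test_that("disjoint and identical pairs have zero SE by convention", {
  for (pc in list(pixel_counts(5, 5, 7, 7), pixel_counts(8, 8, 0, 0))) {
    expect_identical(bootstrap_se_mer(pc, "weighted", M = 100), 0)
    expect_identical(exact_se_mer_oracle(pc, "average"), 0)
  }
  expect_identical(bootstrap_se_mer(pixel_counts(9, 0, 9, 0), "proportion", M = 100), 0)
})

test_that("no rejection occurs when the detected cell fits in the GT cell", {
  # with n_A <= n_G every draw is accepted, so a rejection budget of
  # exactly M draws must suffice
  pc <- pixel_counts(30, 10, 25, 5)
  expect_no_error(bootstrap_se_mer(pc, "weighted", M = 500, seed = 2,
                                   max_rejections = 500))
  # pathological counts trip the cap instead of silently biasing
  expect_error(bootstrap_se_mer(pixel_counts(2, 1, 101, 100), "weighted",
                                M = 500, seed = 2, max_rejections = 50),
               "rejection cap")
})

test_that("TER variance combines per-cell SEs with squared weights", {
  expect_equal(ter_variance(c(100, 300), c(0.1, 0.02)), 0.00085)
  expect_equal(sqrt(ter_variance(c(100, 300), c(0.1, 0.02))), 0.0291548,
               tolerance = 1e-5)
  expect_equal(ter_variance(c(10, 20), c(0, 0)), 0)
  expect_equal(sqrt(ter_variance(500, 0.07)), 0.07)
  # duplicating an identical cell halves the variance (weights 1/4, 2 terms)
  expect_equal(ter_variance(c(100, 100), c(0.1, 0.1)),
               ter_variance(100, 0.1) / 2)
  expect_error(ter_variance(c(100, 300), 0.1), "one SE per cell")
  expect_error(ter_variance(c(100, 300), c(0.1, -0.1)), "non-negative")
})

test_that("the TER confidence interval is the unclamped normal interval", {
  ci <- ter_confidence_interval(0.5, 0.01, 0.05)
  expect_equal(unname(c(ci)), c(0.4804, 0.5196), tolerance = 1e-4)
  expect_equal(unname(c(ter_confidence_interval(0.3, 0, 0.05))), c(0.3, 0.3))
  low <- ter_confidence_interval(0.1, 0.1, 0.05)
  expect_equal(unname(c(low)), c(-0.096, 0.296), tolerance = 1e-3)
  expect_true(isTRUE(attr(low, "out_of_range")))
  expect_error(ter_confidence_interval(0.5, 0.01, 1.2), "alpha")
})

test_that("type-2 quantiles invert the EDF with averaging at jumps", {
  expect_equal(quantile_type2(c(1, 2, 3, 4), 0.5), 2.5)
  expect_equal(quantile_type2(c(1, 2, 3), 0.5), 2)
  expect_equal(quantile_type2(5, 0.3), 5)
  expect_error(quantile_type2(numeric(0), 0.5), "non-empty")
  expect_error(quantile_type2(1:3, 0), "strictly between")
})

test_that("relative error reproduces the published percentages", {
  expect_equal(round(relative_error(0.000893, 0.057524), 2), 3.04)
  expect_equal(round(relative_error(0.000095, 0.224444), 2), 0.08)
  expect_equal(relative_error(0, 0.5), 0)
  expect_error(relative_error(0.1, 0), "positive center")
})

test_that("the SE(TER) variability study behaves at the edges", {
  perfect <- eval_with_mers(c(0, 0, 0))
  d <- se_ter_distribution(perfect, M = 50, L = 10, seed = 1)
  expect_true(all(d$samples == 0))
  expect_equal(unname(d$ci), c(0, 0))
  expect_error(se_ter_distribution(perfect, M = 50, L = 1), "L must be")
  # single-cell evaluation: the distribution is that cell's bootstrap SE,
  # centred on the oracle SD
  pc <- pixel_counts(40, 8, 36, 4)
  e1 <- seg_eval(data.frame(cell_id = "c", n_G = 40, n_g = 8, n_A = 36, n_a = 4))
  d1 <- se_ter_distribution(e1, M = 2000, L = 40, seed = 9)
  expect_lt(abs(d1$mean - exact_se_mer_oracle(pc, "weighted")),
            3 * stats::sd(d1$samples) / sqrt(40) + 1e-4)
  # deterministic under a fixed seed
  d2 <- se_ter_distribution(e1, M = 200, L = 10, seed = 9)
  d3 <- se_ter_distribution(e1, M = 200, L = 10, seed = 9)
  expect_identical(d2$samples, d3$samples)
})
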