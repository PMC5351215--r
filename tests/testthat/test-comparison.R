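test_that("the correlated Z statistic reproduces the published comparisons", {
  # overlapping error bars: Z ~ -1.46, two-tailed p ~ 14.4%
  z56 <- z_statistic(0.171153, 0.001721, 0.173513, 0.000868, 0.370554)
  expect_equal(2 * pnorm(-abs(z56)), 0.144, tolerance = 1e-3)
  # clearly separated algorithms: p below any conventional level
  z12 <- z_statistic(0.057524, 0.000893, 0.066889, 0.000093, 0.215203)
  expect_lt(2 * pnorm(-abs(z12)), 0.001)
  expect_equal(z_statistic(0.1, 0.01, 0.1, 0.02, 0.3), 0)
  expect_equal(z_statistic(0.3, 0.05, 0.2, 0, 0), 2)
  # antisymmetry in the two algorithms
  expect_equal(z_statistic(0.2, 0.01, 0.25, 0.02, 0.4),
               -z_statistic(0.25, 0.02, 0.2, 0.01, 0.4))
  expect_error(z_statistic(0.1, 0.01, 0.1, 0.01, 1), "degenerate")
  expect_error(z_statistic(0.1, -0.01, 0.1, 0.01, 0), "non-negative")
})

test_that("synchronized resampling recovers exact correlations", {
  a <- eval_with_mers(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(as.numeric(ter_correlation(a, a, M = 200, runs = 2, seed = 1)), 1)
  # perfect affine dependence between the two algorithms' MERs
  b <- eval_with_mers(0.5 * c(0.1, 0.2, 0.3, 0.4) + 0.1, algorithm = "affine")
  expect_equal(as.numeric(ter_correlation(a, b, M = 500, runs = 2, seed = 2)), 1,
               tolerance = 1e-10)
  # N = 2: exhaustive enumeration over the 4 equally likely index vectors
  a2 <- eval_with_mers(c(0.1, 0.3), sizes = c(500, 1500))
  b2 <- eval_with_mers(c(0.4, 0.2), sizes = c(500, 1500), algorithm = "b")
  exact <- enumerate_ter_correlation(a2, b2)
  M <- 4000
  est <- as.numeric(ter_correlation(a2, b2, M = M, runs = 10, seed = 3))
  tol <- 3 * (1 - exact^2) / sqrt(M - 3) / sqrt(10)
  expect_lte(abs(est - exact), tol + 1e-12)
  expect_error(ter_correlation(a, eval_with_mers(1:3 / 10)), "same ordered")
  expect_error(ter_correlation(eval_with_mers(0.2), eval_with_mers(0.2)),
               "at least 2")
  expect_error(ter_correlation(eval_with_mers(c(0.2, 0.2)),
                               eval_with_mers(c(0.1, 0.3)), M = 50, runs = 1,
                               seed = 1),
               "zero variance")
})

test_that("breaking synchronization destroys the pairing", {
  rates <- seq(0.05, 0.4, length.out = 10)
  a <- eval_with_mers(rates)
  b <- eval_with_mers(rates + 0.05, algorithm = "b")
  synced <- as.numeric(ter_correlation(a, b, M = 2000, runs = 3, seed = 4))
  broken <- as.numeric(ter_correlation(a, b, M = 2000, runs = 3, seed = 4,
                                       synchronized = FALSE))
  expect_gt(synced, 0.99)
  expect_lt(abs(broken), 0.2)
  # shuffling the common cell order identically changes nothing material
  perm <- c(3, 1, 4, 2, 5, 10, 8, 6, 9, 7)
  ash <- eval_with_mers(rates[perm])
  bsh <- eval_with_mers(rates[perm] + 0.05, algorithm = "b")
  shuffled <- as.numeric(ter_correlation(ash, bsh, M = 2000, runs = 3, seed = 4))
  expect_equal(shuffled, synced, tolerance = 0.02)
})

test_that("averaging independent runs stabilizes the correlation", {
  a <- eval_with_mers(c(0.12, 0.3, 0.08, 0.22, 0.18), sizes = c(200, 900, 400, 1500, 700))
  b <- eval_with_mers(c(0.2, 0.25, 0.15, 0.3, 0.1),
                      sizes = c(200, 900, 400, 1500, 700), algorithm = "b")
  rho <- ter_correlation(a, b, M = 300, runs = 10, seed = 6)
  per_run <- attr(rho, "runs")
  expect_length(per_run, 10)
  averages <- vapply(1:8, function(k)
    as.numeric(ter_correlation(a, b, M = 300, runs = 10, seed = 100 + k)),
    numeric(1))
  expect_lt(stats::sd(averages), stats::sd(per_run))
})

test_that("the two-algorithm test assembles rho, Z, p and a decision", {
  a <- simulate_counts(n_cells = 12, r_fn = 0.05, r_fp = 0.05, seed = 31,
                       algorithm = "good")
  cmp_same <- compare_ter(a, a, M = 200, seed = 1)
  expect_equal(cmp_same$decision, "no detectable difference")
  expect_true(is.na(cmp_same$z))
  expect_equal(unname(cmp_same$pairwise), c(0, 0, 12))
  # a planted large MER gap with small SEs must be detected
  b <- simulate_counts(n_cells = 12, r_fn = 0.3, r_fp = 0.3, seed = 31,
                       algorithm = "bad")
  cmp <- compare_ter(a, b, M = 500, runs = 3, seed = 2)
  expect_match(cmp$decision, "reject")
  expect_lt(cmp$p, 0.05)
  expect_lt(cmp$z, 0)           # sign follows TER_A - TER_B
  expect_equal(cmp$p, if (cmp$p_underflow) 0 else 2 * pnorm(-abs(cmp$z)))
  expect_equal(unname(cmp$pairwise), c(12, 0, 0))
})

test_that("one-algorithm test locates the CI against a criterion", {
  est <- function(lo, hi) structure(list(ci = c(lower = lo, upper = hi),
                                         estimate = (lo + hi) / 2,
                                         algorithm = "x"),
                                    class = "ter_estimate")
  expect_equal(one_algorithm_test(est(0.055775, 0.059274), 0.08), "below")
  expect_equal(one_algorithm_test(est(0.9, 0.95), 0.1), "above")
  expect_equal(one_algorithm_test(est(0.07, 0.09), 0.08), "contains")
  expect_equal(one_algorithm_test(est(0.1, 0.1), 0.1), "contains")
})

test_that("error-bar classification reproduces the published class structure", {
  cis <- list(c(0.055775, 0.059274), c(0.066707, 0.067071),
              c(0.088042, 0.090684), c(0.104976, 0.105215),
              c(0.167780, 0.174526), c(0.171812, 0.175213),
              c(0.224257, 0.224631))
  ests <- lapply(seq_along(cis), function(i)
    structure(list(ci = c(lower = cis[[i]][1], upper = cis[[i]][2]),
                   algorithm = paste0("alg", i)), class = "ter_estimate"))
  cls <- classify_algorithms(ests, c(0.08, 0.14))
  expect_equal(unname(cls), c("1", "1", "2", "2", "3", "3", "3"))
  straddle <- structure(list(ci = c(lower = 0.075, upper = 0.085),
                             algorithm = "s"), class = "ter_estimate")
  expect_equal(unname(classify_algorithms(list(straddle), c(0.08, 0.14))),
               "straddles")
  expect_equal(unname(classify_algorithms(ests[1:2], 0.5)), c("1", "1"))
  expect_error(classify_algorithms(ests, c(0.14, 0.08)), "strictly increasing")
})
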