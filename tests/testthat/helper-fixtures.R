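# Shared fixture builders. All fixtures are generated in code; tests fix
# their seeds so runs are reproducible.

# counts whose FN and FP rates are both exactly `rate` (n_G = n_A = size),
# so every MER variant equals `rate` exactly
equal_rate_counts <- function(rate, size = 100) {
  k <- round(rate * size)
  c(n_G = size, n_g = k, n_A = size, n_a = k)
}

# evaluation whose per-cell MERs are exactly `rates` (any variant), with
# equal or custom GT sizes
eval_with_mers <- function(rates, sizes = rep(1000, length(rates)),
                           algorithm = "fixture") {
  rows <- lapply(seq_along(rates), function(i) {
    k <- round(rates[i] * sizes[i])
    data.frame(cell_id = paste0("cell_", i), n_G = sizes[i], n_g = k,
               n_A = sizes[i], n_a = k)
  })
  seg_eval(do.call(rbind, rows), algorithm = algorithm)
}

# random valid pixel counts drawn from interior of the constraint set
random_counts <- function(n, seed = 1, max_region = 60) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    n_I <- sample(0:max_region, 1)
    n_g <- sample(0:max_region, 1)
    n_a <- if (n_I == 0 && n_g == 0) sample(1:max_region, 1) else sample(0:max_region, 1)
    n_G <- n_I + n_g
    if (n_G == 0) { n_g <- 1; n_G <- 1 }
    pixel_counts(n_G, n_g, n_I + n_a, n_a)
  })
}

# deterministic grid of Case 3/4/5 counts with n_G, n_A bounded
case345_grid <- function(max_size = 50) {
  out <- list()
  for (n_I in c(2, 5, 10, 20)) {
    for (n_g in c(1, 3, 8)) {
      for (n_a in c(1, 4, 12)) {
        if (n_I + n_g <= max_size && n_I + n_a <= max_size)
          out[[length(out) + 1]] <- pixel_counts(n_I + n_g, n_g, n_I + n_a, n_a) # Case 5
      }
      if (n_I + n_g <= max_size) {
        out[[length(out) + 1]] <- pixel_counts(n_I + n_g, n_g, n_I, 0)          # Case 3
        out[[length(out) + 1]] <- pixel_counts(n_I, 0, n_I + n_g, n_g)          # Case 4
      }
    }
  }
  out
}

# 3 sigma Monte-Carlo tolerance for a sample SD at M replicates, from the
# exact central moments of the replicate distribution (independent of the
# bootstrap under test)
sd_mc_tolerance <- function(counts, variant, M, nsig = 3) {
  d <- oracle_mer_distribution(counts, variant)
  mu <- sum(d$value * d$prob)
  s2 <- sum(d$prob * (d$value - mu)^2)
  mu4 <- sum(d$prob * (d$value - mu)^4)
  var_s2 <- (mu4 - s2^2 * (M - 3) / (M - 1)) / M
  nsig * sqrt(max(var_s2, 0)) / (2 * sqrt(s2))
}

# exact correlation of the two TERs over all N^N equally likely index
# vectors of a small evaluation pair (enumeration oracle for the
# synchronized-resampling correlation)
enumerate_ter_correlation <- function(a, b, variant = "weighted") {
  N <- a$N
  ma <- terseg:::cell_mers(a, variant)
  mb <- terseg:::cell_mers(b, variant)
  S <- a$cells$S
  grid <- expand.grid(rep(list(seq_len(N)), N))
  terA <- apply(grid, 1, function(idx) sum(ma[idx] * S[idx]) / sum(S[idx]))
  terB <- apply(grid, 1, function(idx) sum(mb[idx] * S[idx]) / sum(S[idx]))
  n <- length(terA)
  num <- mean(terA * terB) - mean(terA) * mean(terB)
  num / sqrt((mean(terA^2) - mean(terA)^2) * (mean(terB^2) - mean(terB)^2))
}
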