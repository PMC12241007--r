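# direct-summation entropy/MI oracle for small contingency tables
mi_oracle <- function(stim, resp) {
  tab <- table(stim, resp)
  n <- sum(tab)
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hr <- H(colSums(tab) / n)
  hrs <- sum(vapply(seq_len(nrow(tab)), function(i)
    (sum(tab[i, ]) / n) * H(tab[i, ] / sum(tab[i, ])), numeric(1)))
  hr - hrs
}

test_that("plugin MI reproduces closed-form channels", {
  # noiseless channel: 12 stimuli mapped to 12 distinct responses
  s <- rep(letters[1:12], each = 10)
  expect_equal(plugin_mi(s, s)$mi_bits, log2(12))
  # stimulus-independent responses with exact counts -> 0 bits
  s2 <- rep(c("a", "b"), each = 50)
  r2 <- rep(rep(c("x", "y"), c(30, 20)), 2)
  expect_equal(plugin_mi(s2, r2)$mi_bits, 0)
  # binary symmetric channel, flip p = 0.25 with exact 75/25 counts
  s3 <- rep(0:1, each = 100)
  r3 <- c(rep(c(0, 1), c(75, 25)), rep(c(1, 0), c(75, 25)))
  h2 <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(plugin_mi(s3, r3)$mi_bits, 1 - h2(0.25))
  expect_error(plugin_mi(character(0), character(0)), "empty")
})

test_that("plugin MI agrees exactly with hand-summed entropies", {
  set.seed(13)
  for (i in 1:15) {
    s <- sample(letters[1:sample(2:4, 1)], 40, replace = TRUE)
    r <- sample(1:sample(2:4, 1), 40, replace = TRUE)
    est <- plugin_mi(s, r)
    expect_equal(est$mi_bits, mi_oracle(s, r), tolerance = 1e-14)
    expect_gte(est$mi_bits, -1e-12)
    expect_lte(est$mi_bits, est$h_response_bits + 1e-12)
    expect_lte(est$mi_bits, log2(est$n_stimuli) + 1e-12)
    # permutation invariance
    p <- sample(40)
    expect_equal(plugin_mi(s[p], r[p])$mi_bits, est$mi_bits)
  }
})

test_that("Panzeri-Treves bias matches the naive-count closed form", {
  # Ns = 2, each stimulus occupies all 8 response bins, N = 20
  s <- rep(c("a", "b"), each = 10)
  r <- c(c(1:8, 1, 2), c(1:8, 3, 4))
  est <- pt_corrected_mi(s, r)
  bias <- (2 * 7 - 7) / (2 * 20 * log(2))
  expect_equal(est$bias_bits, bias)
  expect_equal(bias, 0.2525, tolerance = 2e-4)
  expect_equal(est$mi_bits, est$mi_plugin_bits - bias)
  # deterministic channel: one occupied bin per stimulus
  sd_ <- rep(letters[1:4], each = 5)
  estd <- pt_corrected_mi(sd_, sd_)
  expect_equal(estd$bias_bits, -(4 - 1) / (2 * 20 * log(2)))
  expect_lte(estd$mi_bits - estd$mi_plugin_bits, 1e-12 + abs(estd$bias_bits))
})

test_that("PT correction vanishes at large N", {
  set.seed(19)
  n <- 1e5
  s <- sample(letters[1:4], n, replace = TRUE)
  r <- sample(1:6, n, replace = TRUE)
  est <- pt_corrected_mi(s, r)
  expect_lt(abs(est$mi_bits - est$mi_plugin_bits), 1e-3)
})

test_that("quantize_responses builds equipopulated per-unit symbols", {
  x <- c(1, 2, 3, 4, 5, 6)
  q <- quantize_responses(x, 2)
  expect_equal(q, c("1", "1", "1", "2", "2", "2"),
               ignore_attr = TRUE)  # median split
  const <- quantize_responses(rep(4, 10), 3)
  expect_equal(length(unique(const)), 1)
  expect_equal(attr(const, "n_bins_actual"), 1L)
  set.seed(3)
  m <- matrix(rpois(60, 5), ncol = 3)
  q3 <- quantize_responses(m, 2)
  expect_lte(length(unique(q3)), 8)
  expect_error(quantize_responses(x, 1), "n_bins")
})

test_that("MI curve: size-1 equivalence, redundant units, monotonicity", {
  rec <- sim_recording_cached()
  # size-1 means stay within the range of per-unit MI values
  mc <- mi_vs_population_size(rec, sizes = 1, n_subsets = 12, seed = 4)
  conds <- condition_labels(rec$protocol)
  stim_r <- rep(conds, times = rec$protocol$n_sweeps)
  per_unit <- vapply(rec$units$unit_id, function(u) {
    sym <- quantize_responses(as.numeric(unit_counts(rec, u)[conds, ]), 2)
    pt_corrected_mi(stim_r, sym)$mi_bits
  }, numeric(1))
  expect_gte(mc$mi_mean_bits[1], min(per_unit))
  expect_lte(mc$mi_mean_bits[1], max(per_unit))
  expect_error(mi_vs_population_size(rec, sizes = integer(0)), "non-empty")
  expect_error(mi_vs_population_size(rec, sizes = 99), "exceeds")
  # adding an identical copy of a unit leaves MI unchanged
  stim <- rep(letters[1:13], each = 10)
  set.seed(5)
  u1 <- rpois(130, 5) + rep(0:12, each = 10)
  m1 <- quantize_responses(matrix(u1, ncol = 1), 2)
  m2 <- quantize_responses(cbind(u1, u1), 2)
  expect_equal(pt_corrected_mi(stim, m1)$mi_plugin_bits,
               pt_corrected_mi(stim, m2)$mi_plugin_bits)
  # noiseless tuned units: mean MI non-decreasing with population size
  resp <- cbind(rep(0:1, times = c(60, 70)),
                rep(c(0, 1, 0), times = c(30, 60, 40)),
                rep(c(0, 1), times = c(90, 40)))
  mi_m <- vapply(1:3, function(m) {
    sym <- apply(resp[, 1:m, drop = FALSE], 1, paste, collapse = "|")
    plugin_mi(stim, sym)$mi_bits
  }, numeric(1))
  expect_true(all(diff(mi_m) >= -1e-12))
})

test_that("determinism and seed isolation of the MI curve", {
  rec <- sim_recording_cached()
  a <- mi_vs_population_size(rec, sizes = 1:3, n_subsets = 4, seed = 10)
  b <- mi_vs_population_size(rec, sizes = 1:3, n_subsets = 4, seed = 10)
  expect_identical(a$mi_mean_bits, b$mi_mean_bits)
  # global RNG stream is untouched
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(mi_vs_population_size(rec, sizes = 2, n_subsets = 2, seed = 99))
  expect_identical(runif(1), before)
})
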