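test_that("trial z-scores standardise within condition and drop zero-SD", {
  z <- trial_z_scores(list(a = c(12, 8)))
  expect_equal(z$z, c(1, -1))  # mean 10, population SD 2
  zs <- trial_z_scores(list(a = c(5, 5, 5), b = c(1, 2, 3)))
  expect_equal(unname(zs$valid), c(FALSE, TRUE))
  expect_length(zs$z, 3)
  expect_equal(mean(zs$z), 0)
  expect_equal(sqrt(mean(zs$z^2)), 1)  # population SD 1 per block
  expect_error(trial_z_scores(list(a = c(2, 2))), "positive standard")
})

test_that("noise_correlation is Pearson on pooled z with guard rails", {
  set.seed(9)
  za <- rnorm(30)
  expect_equal(noise_correlation(za, za), 1)
  expect_equal(noise_correlation(za, -za), -1)
  expect_error(noise_correlation(za, za[1:10]), "equal length")
  expect_error(noise_correlation(rep(0, 10), rnorm(10)), "zero variance")
})

test_that("independent units give small r_sc at 600 pooled trials", {
  set.seed(55)
  bad <- 0
  for (i in 1:20) {
    r <- noise_correlation(rnorm(600), rnorm(600))
    if (abs(r) >= 0.1) bad <- bad + 1
  }
  expect_lte(bad, 1)  # 95% coverage of |r| < 0.1 under independence
})

test_that("response_covariance equals the expectation-form oracle exactly", {
  expect_equal(response_covariance(c(1, 2, 3), c(1, 2, 3)), 2 / 3)
  expect_equal(response_covariance(c(1, 2, 3), c(7, 7, 7)), 0)
  set.seed(2)
  for (i in 1:10) {
    na <- rpois(sample(2:20, 1), 6); nb <- rpois(length(na), 6)
    oracle <- mean(na * nb) - mean(na) * mean(nb)
    expect_equal(response_covariance(na, nb), oracle, tolerance = 1e-12)
  }
  expect_error(response_covariance(1:3, 1:4), "equal length")
})

test_that("pair r_sc matches the printed-formula oracle and is symmetric", {
  rec <- sim_recording_cached()
  ids <- rec$units$unit_id
  labs <- condition_labels(rec$protocol, blank = FALSE)
  # oracle: z by the printed definition, then the E-operator correlation
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  oracle_rsc <- function(a, b) {
    ma <- unit_counts(rec, a)[labs, ]; mb <- unit_counts(rec, b)[labs, ]
    za <- zb <- NULL
    for (i in seq_len(nrow(ma))) {
      if (psd(ma[i, ]) == 0 || psd(mb[i, ]) == 0) next
      za <- c(za, (ma[i, ] - mean(ma[i, ])) / psd(ma[i, ]))
      zb <- c(zb, (mb[i, ] - mean(mb[i, ])) / psd(mb[i, ]))
    }
    (mean(za * zb) - mean(za) * mean(zb)) / (psd(za) * psd(zb))
  }
  for (pr in list(c(1, 2), c(3, 7), c(5, 6))) {
    a <- ids[pr[1]]; b <- ids[pr[2]]
    got <- pair_noise_correlation(rec, a, b, "evoked")$rsc
    expect_equal(got, oracle_rsc(a, b), tolerance = 1e-12)
    expect_equal(pair_noise_correlation(rec, b, a, "evoked")$rsc, got)
  }
})

test_that("r_sc is invariant to per-condition affine transforms", {
  labs <- c("0", "90", "180", "270", "300", "330")
  set.seed(12)
  base <- matrix(rpois(6 * 8, 10), nrow = 6)
  m2 <- base * 3 + matrix(rep(c(1, 5, 2, 0, 7, 3), 8), nrow = 6)  # per-cond affine
  mk <- function(m) setNames(split(m, row(m)), labs)
  z1 <- trial_z_scores(mk(base)); z2 <- trial_z_scores(mk(m2))
  expect_equal(z1$z, z2$z, tolerance = 1e-12)
})

test_that("decorrelation index clamps positive differences at zero", {
  expect_equal(decorrelation_index(0.3, 0.1), 0)
  expect_equal(decorrelation_index(0.1, 0.3), -0.2)
  expect_equal(decorrelation_index(0.2, 0.2), 0)
  set.seed(1)
  expect_true(all(decorrelation_index(runif(100, -1, 1),
                                      runif(100, -1, 1)) <= 0))
})

test_that("pair_stats table: fields, symmetry of membership, FS-RS typing", {
  rec <- sim_recording_cached()
  ps <- pair_stats(rec)
  expect_equal(nrow(ps), choose(n_units(rec), 2))
  expect_true(all(ps$distance_um >= 0))
  expect_true(all(ps$rsc_evoked >= -1 & ps$rsc_evoked <= 1, na.rm = TRUE))
  expect_true(all(is.na(ps$delta_po_deg) |
                    (ps$delta_po_deg >= 0 & ps$delta_po_deg <= 90)))
  expect_true(all(is.na(ps$decorrelation) | ps$decorrelation <= 0))
  expect_true(all(is.na(ps$decorrelation[ps$pair_type != "FS-RS"])))
})

test_that("bin_relation assigns half-open bins with overflow reporting", {
  pairs <- data.frame(pair_rate = c(5, 10, 49.9, 55), distance_um = 1,
                      delta_po_deg = 1,
                      rsc_evoked = c(0.1, 0.2, 0.3, 0.4))
  br <- bin_relation(pairs, "rate")
  expect_equal(br$bin_ns, c(1L, 1L, 0L, 0L, 1L))
  expect_equal(br$bin_means[1], 0.1)
  expect_equal(br$bin_means[2], 0.2)  # 10 goes to [10, 20)
  expect_true(is.na(br$bin_means[3]))
  expect_equal(br$overflow$n, 1)
  expect_equal(br$overflow$mean, 0.4)
})

test_that("bin_relation recovers a constant signal across bins", {
  set.seed(6)
  pairs <- data.frame(pair_rate = runif(100, 0, 50), distance_um = 1,
                      delta_po_deg = 1,
                      rsc_evoked = 0.25 + rnorm(100, 0, 0.01))
  br <- bin_relation(pairs, "rate")
  ok <- !is.na(br$bin_means)
  expect_true(all(abs(br$bin_means[ok] - 0.25) < 3 * pmax(br$bin_sems[ok],
                                                          0.005)))
})
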