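# brute-force AUC oracle: all pairwise comparisons, ties worth 1/2
auc_oracle <- function(e, s) {
  cmp <- outer(e, s, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("roc_snr reproduces hand-derivable AUC values", {
  expect_identical(roc_snr(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  expect_identical(roc_snr(11:20, 1:10)$auc, 1.0)
  expect_equal(roc_snr(c(3, 5, 5), c(1, 5, 2))$auc, 7 / 9)
  expect_error(roc_snr(numeric(0), 1:3), "non-empty")
})

test_that("roc curve is a monotone path from (0,0) to (1,1)", {
  set.seed(21)
  r <- roc_snr(rpois(40, 6), rpois(30, 3))
  pts <- r$roc_points
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_equal(r$n_evoked_bins, 40)
})

test_that("AUC equals the exhaustive pairwise oracle and is rank-based", {
  set.seed(8)
  for (i in 1:20) {
    e <- rpois(sample(3:50, 1), sample(2:8, 1))
    s <- rpois(sample(3:50, 1), sample(2:8, 1))
    a <- roc_snr(e, s)$auc
    expect_equal(a, auc_oracle(e, s))
    # complement symmetry with half-tie handling
    expect_equal(a + roc_snr(s, e)$auc, 1)
    # invariance under a strictly monotone transform
    expect_equal(roc_snr(exp(e / 3), exp(s / 3))$auc, a)
  }
})

test_that("make_response_bins places spikes and pools across sweeps", {
  proto <- pn_protocol(directions = 0, n_sweeps = 10)
  units <- data.frame(unit_id = "u1", channel_index = 1L, depth_um = 0,
                      group_label = "g", stringsAsFactors = FALSE)
  units$waveform <- list(make_waveform(0.4, 0.5, 0.02))
  counts <- array(0, dim = c(2, 10, 1),
                  dimnames = list(c("0", "BLANK"), as.character(1:10), "u1"))
  counts["0", 1, 1] <- 2
  st <- data.frame(condition = "0", sweep = 1L, unit_id = "u1",
                   time_s = c(0.05, 0.55))
  rec <- pn_recording(proto, units, counts, st)
  bins <- make_response_bins(rec, "u1", "0", bin_s = 0.1)
  expect_length(bins, 100)          # 10 trials x 10 bins of 0.1 s
  expect_equal(bins[1], 1)
  expect_equal(bins[6], 1)
  expect_equal(sum(bins), 2)
  expect_equal(sum(make_response_bins(rec, "u1", BLANK, 0.1)), 0)
  expect_error(make_response_bins(rec, "u1", "0", 0.3), "divide")
  # counts-only fallback: one bin per trial
  rec2 <- pn_recording(proto, units, counts)
  expect_warning(b2 <- make_response_bins(rec2, "u1", "0", 0.1), "fall")
  expect_length(b2, 10)
})

test_that("fano_factor uses unbiased variance per condition", {
  ff0 <- fano_factor(list(a = c(4, 4, 4, 4), b = c(4, 4, 4, 4)))
  expect_equal(ff0$ff, 0)
  expect_equal(fano_factor(list(a = c(2, 4, 6)))$ff, 1)  # var 4 / mean 4
  expect_error(fano_factor(list(a = c(0, 0, 0))), "zero mean")
  expect_error(fano_factor(list(a = 1)), ">= 2 trials")
  set.seed(17)
  x <- rpois(5000, 8)
  ff <- fano_factor(list(a = x))$ff
  expect_gt(ff, 0.95); expect_lt(ff, 1.05)
})

test_that("fano factor scales linearly with integer count scaling", {
  set.seed(4)
  x <- rpois(100, 5) + 1
  expect_equal(fano_factor(list(a = 3 * x))$ff,
               3 * fano_factor(list(a = x))$ff)
})

test_that("MUA fano: degenerate single unit, and shared gain inflates it", {
  p1 <- population_params(n_units = 2, fs_fraction = 0, baseline_rate_hz = 8,
                          amplitude_hz = 0, gain_sd_evoked = 0,
                          gain_sd_spont = 0, seed = 31)
  rec <- simulate_recording(p1, pn_protocol(n_sweeps = 100),
                            spike_times = FALSE)
  # independent Poisson units: the summed series stays near FF = 1
  expect_lt(abs(mua_fano(rec)$ff - 1), 0.2)
  # strong shared gain: MUA FF far exceeds the mean single-unit FF
  p2 <- population_params(n_units = 8, fs_fraction = 0, baseline_rate_hz = 8,
                          amplitude_hz = 0, gain_sd_evoked = 0.4,
                          gain_sd_spont = 0.4, seed = 32)
  rec2 <- simulate_recording(p2, pn_protocol(n_sweeps = 50),
                             spike_times = FALSE)
  single <- vapply(rec2$units$unit_id, function(u) {
    labs <- condition_labels(rec2$protocol, blank = FALSE)
    m <- unit_counts(rec2, u)[labs, ]
    fano_factor(setNames(split(m, row(m)), labs))$ff
  }, numeric(1))
  expect_gt(mua_fano(rec2)$ff, mean(single))
})

test_that("unit_metrics table wires rates, SNR and the 6 spikes/s split", {
  rec <- sim_recording_cached()
  um <- unit_metrics(rec)
  expect_equal(nrow(um), n_units(rec))
  expect_true(all(um$snr_auc >= 0 & um$snr_auc <= 1))
  expect_equal(um$rate_group, ifelse(um$evoked_minus_spont > 6,
                                     "high", "low"))
  u <- um$unit_id[1]
  expect_equal(um$peak_rate[1], mean_rate(rec, u, optimal_condition(rec, u)))
})
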