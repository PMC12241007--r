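# Independent oracle for the von Mises normaliser: numerical integration of
# exp(k cos t) over the circle instead of besselI().
i0_numeric <- function(k) {
  stats::integrate(function(t) exp(k * cos(t)) / (2 * pi), 0, 2 * pi,
                   rel.tol = 1e-12)$value
}

test_that("tuning_rate matches direct formula evaluation with an integral oracle", {
  dirs <- seq(0, 330, by = 30)
  got <- tuning_rate(dirs, theta1 = 90, theta2 = 270, k1 = 2, k2 = 2,
                     mu = 1, amplitude = 10)
  want <- vapply(dirs, function(x) {
    vm <- function(th, k) exp(k * cos((x - th) * pi / 180)) /
      (2 * pi * i0_numeric(k))
    10 * (vm(90, 2) + vm(270, 2)) + 1
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("tuning_rate limiting cases: flat at k = 0, mode at theta1", {
  dirs <- seq(0, 330, by = 30)
  flat <- tuning_rate(dirs, 0, 180, 0, 0, mu = 3, amplitude = 5)
  expect_equal(flat, rep(5 * 2 / (2 * pi) + 3, length(dirs)))
  peaked <- tuning_rate(dirs, 60, 240, 8, 0, mu = 0, amplitude = 1)
  expect_equal(dirs[which.max(peaked)], 60)
  expect_error(tuning_rate(0, 0, 180, -1, 0, 0), "concentration")
})

test_that("simulation is deterministic given the seed", {
  p <- preset_params("young", n_units = 6, seed = 11)
  a <- simulate_recording(p)
  b <- simulate_recording(p)
  expect_identical(a$counts, b$counts)
  expect_identical(a$spike_times, b$spike_times)
  expect_equal(a$units$waveform, b$units$waveform)
  p2 <- p; p2$seed <- 12
  expect_false(identical(simulate_recording(p2)$counts, a$counts))
})

test_that("generated FS fraction and probe depths follow the parameters", {
  for (s in 1:3) {
    p <- population_params(n_units = 13, fs_fraction = 0.15, seed = s)
    rec <- simulate_recording(p, spike_times = FALSE)
    cl <- classify_units(rec)
    expect_lte(abs(sum(cl$class == "FS") - round(13 * 0.15)), 1)
    expect_equal(rec$units$depth_um, rec$units$channel_index * 30)
  }
  expect_error(simulate_recording(population_params(n_units = 1)),
               "n_units >= 2")
})

test_that("empirical condition means recover the tuning-curve targets", {
  # no shared gain, many sweeps: counts are plain Poisson around the target
  p <- population_params(n_units = 3, fs_fraction = 0, baseline_rate_hz = 4,
                         amplitude_hz = 15, concentration = 2,
                         preferred_dirs = c(0, 90, 200),
                         gain_sd_evoked = 0, gain_sd_spont = 0, seed = 5)
  proto <- pn_protocol(n_sweeps = 200)
  rec <- simulate_recording(p, proto, spike_times = FALSE)
  labs <- condition_labels(proto, blank = FALSE)
  for (i in 1:3) {
    u <- rec$units$unit_id[i]
    target <- tuning_rate(as.numeric(labs), c(0, 90, 200)[i],
                          c(0, 90, 200)[i] + 180, 2, 2, 4, 15)
    got <- vapply(labs, function(cc) mean_rate(rec, u, cc), numeric(1))
    se <- sqrt(target / 200)  # Poisson SE of a 200-trial mean rate
    expect_true(all(abs(got - target) < 3.5 * se))
  }
})

test_that("independent units (zero gain SD) show near-zero mean correlation", {
  p <- population_params(n_units = 10, fs_fraction = 0, baseline_rate_hz = 10,
                         amplitude_hz = 0, gain_sd_evoked = 0,
                         gain_sd_spont = 0, seed = 2)
  rec <- simulate_recording(p, pn_protocol(n_sweeps = 10),
                            spike_times = FALSE)
  ps <- pair_stats(rec)
  expect_lt(abs(mean(ps$rsc_evoked)), 2 / sqrt(nrow(ps)))
})

test_that("expected_pair_rsc closed form and sign behaviour", {
  p <- population_params(gain_sd_evoked = 0.3, gain_sd_spont = 0,
                         fs_gain_coupling_evoked = -0.5)
  expect_equal(expected_pair_rsc(p, 10, 10, epoch = "spont"), 0)
  expect_equal(expected_pair_rsc(p, 10, 10, epoch = "evoked"),
               9 / 19)  # cov = 100 * 0.09, var = 10 + 100 * 0.09 each
  expect_lt(expected_pair_rsc(p, 10, 10, epoch = "evoked", type_b = "FS"), 0)
  expect_error(expected_pair_rsc(p, 0, 10), "rates")
})

test_that("presets differ in the documented directions", {
  y <- preset_params("young"); a <- preset_params("aged")
  m <- preset_params("met")
  expect_gt(a$gain_sd_evoked, y$gain_sd_evoked)
  expect_lt(a$concentration, y$concentration)
  expect_equal(a$fs_gain_coupling_evoked, a$fs_gain_coupling_spont)
  expect_lt(y$fs_gain_coupling_evoked, y$fs_gain_coupling_spont)
  expect_lt(m$baseline_rate_hz, y$baseline_rate_hz)
})
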