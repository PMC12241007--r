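#' Parameters of the synthetic population generator
#'
#' Forward model: each unit is direction tuned via [tuning_rate()] (von
#' Mises concentration `concentration`, baseline `baseline_rate_hz`,
#' amplitude `amplitude_hz`); on every trial a latent multiplicative gain
#' `g ~ Normal(1, gain_sd)` (truncated at 0, epoch-specific SD) is shared
#' by the whole population and each unit fires Poisson with mean
#' `rate * duration * (1 + c_i (g - 1))`, where the gain coupling `c_i` is
#' 1 for RS units and the epoch-specific `fs_gain_coupling_*` for FS
#' units. This doubly-stochastic (shared-gain Poisson) construction is the
#' minimal model producing jointly controllable Fano factors above 1 and
#' positive noise correlations; epoch-dependent FS coupling implements
#' inhibition-mediated decorrelation (evoked FS-RS correlations below
#' spontaneous ones when `fs_gain_coupling_evoked < fs_gain_coupling_spont`).
#'
#' @param n_units number of units (>= 2).
#' @param fs_fraction fraction of fast-spiking units in `[0, 1]`.
#' @param baseline_rate_hz spontaneous/baseline rate (mu analogue, Hz).
#' @param amplitude_hz tuning amplitude (Hz).
#' @param concentration von Mises concentration of both tuning lobes.
#' @param preferred_dirs `"uniform"` (evenly spaced with seeded jitter) or
#'   a numeric vector of preferred directions in degrees.
#' @param gain_sd_evoked,gain_sd_spont SD of the shared gain on grating /
#'   blank trials (>= 0).
#' @param fs_gain_coupling_evoked,fs_gain_coupling_spont signed coupling of
#'   FS units to the shared gain per epoch.
#' @param probe_spacing_um linear-probe contact pitch (micrometers).
#' @param group_label tag stored on every generated unit.
#' @param seed RNG seed.
#' @return list of class `pn_population_params`.
#' @export
population_params <- function(n_units = 24, fs_fraction = 0.15,
                              baseline_rate_hz = 5, amplitude_hz = 20,
                              concentration = 3,
                              preferred_dirs = "uniform",
                              gain_sd_evoked = 0.15, gain_sd_spont = 0.15,
                              fs_gain_coupling_evoked = 0.3,
                              fs_gain_coupling_spont = 1,
                              probe_spacing_um = 30,
                              group_label = "synthetic", seed = 1) {
  stopifnot(fs_fraction >= 0, fs_fraction <= 1, baseline_rate_hz >= 0,
            amplitude_hz >= 0, gain_sd_evoked >= 0, gain_sd_spont >= 0,
            concentration >= 0)
  structure(as.list(environment()), class = "pn_population_params")
}

#' Preset synthetic populations for the three experimental groups
#'
#' Qualitative group presets: `aged` has a larger shared-gain SD (higher
#' noise correlation, covariance and MUA Fano factor), broader tuning
#' (lower OSI), a higher baseline, and epoch-independent FS coupling (no
#' decorrelation); `met` resembles `young` (restored gain SD and FS
#' decorrelation) with a lower baseline. Magnitudes are generator knobs
#' chosen to reproduce the direction of every group contrast, not printed
#' medians (the source recordings are not public).
#'
#' @param name `"young"`, `"aged"` or `"met"`.
#' @param ... overrides passed to [population_params()].
#' @return a `pn_population_params`.
#' @export
preset_params <- function(name = c("young", "aged", "met"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    young = list(n_units = 23, fs_fraction = 0.16, baseline_rate_hz = 5,
                 amplitude_hz = 20, concentration = 3,
                 gain_sd_evoked = 0.15, gain_sd_spont = 0.15,
                 fs_gain_coupling_evoked = 0.3, fs_gain_coupling_spont = 1),
    aged = list(n_units = 28, fs_fraction = 0.14, baseline_rate_hz = 10,
                amplitude_hz = 20, concentration = 1.5,
                gain_sd_evoked = 0.3, gain_sd_spont = 0.3,
                fs_gain_coupling_evoked = 1, fs_gain_coupling_spont = 1),
    met = list(n_units = 21, fs_fraction = 0.12, baseline_rate_hz = 2.5,
               amplitude_hz = 16, concentration = 3,
               gain_sd_evoked = 0.15, gain_sd_spont = 0.15,
               fs_gain_coupling_evoked = 0.25, fs_gain_coupling_spont = 1))
  args <- utils::modifyList(c(base, list(group_label = name)), list(...))
  do.call(population_params, args)
}

rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- out < 0
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < 0
  }
  out
}

#' Simulate a trial-structured recording
#'
#' Draws a full [pn_recording()] from the shared-gain Poisson forward model
#' of [population_params()]: tuned condition rates, one truncated-normal
#' shared gain per trial, conditionally independent Poisson counts,
#' FS/RS template waveforms with seeded feature jitter, probe depths
#' `channel_index * probe_spacing_um`, and (optionally) uniformly placed
#' spike times within each trial. Fully reproducible given `params$seed`.
#'
#' @param params a [population_params()].
#' @param protocol a [pn_protocol()] (default: 12 directions in 30 degree
#'   steps, blank, 10 sweeps, 1 s trials).
#' @param spike_times generate per-spike times (uniform within the trial)?
#' @return a [pn_recording()].
#' @export
simulate_recording <- function(params, protocol = pn_protocol(),
                               spike_times = TRUE) {
  stopifnot(inherits(params, "pn_population_params"))
  if (params$n_units < 2)
    stop("need n_units >= 2 (pair statistics are undefined otherwise)")
  n <- params$n_units
  with_seed(params$seed, {
    n_fs <- round(n * params$fs_fraction)
    is_fs <- rep(FALSE, n)
    if (n_fs > 0) is_fs[sample.int(n, n_fs)] <- TRUE
    tmpl <- waveform_templates()
    waveforms <- lapply(seq_len(n), function(i) {
      tp <- tmpl[[if (is_fs[i]) "FS" else "RS"]]
      make_waveform(tp$trough_peak_ms + stats::runif(1, -0.02, 0.02),
                    tp$peak_trough_ratio + stats::runif(1, -0.05, 0.05),
                    tp$end_slope + stats::runif(1, -0.01, 0.01),
                    sampling_rate_hz = protocol$sampling_rate_hz)
    })
    channel <- as.integer(round(seq(1, 32, length.out = n)))
    pd <- if (identical(params$preferred_dirs, "uniform"))
      (seq(0, 360, length.out = n + 1)[seq_len(n)] +
         stats::runif(n, -10, 10)) %% 360
    else as.numeric(params$preferred_dirs)
    units <- data.frame(unit_id = sprintf("u%02d", seq_len(n)),
                        channel_index = channel,
                        depth_um = channel * params$probe_spacing_um,
                        group_label = params$group_label,
                        stringsAsFactors = FALSE)
    units$waveform <- waveforms
    labs <- condition_labels(protocol)
    dur <- protocol$duration_s
    rates <- vapply(seq_len(n), function(i) {
      vapply(labs, function(cc) {
        if (cc == BLANK) params$baseline_rate_hz
        else tuning_rate(as.numeric(cc), pd[i], pd[i] + 180,
                         params$concentration, params$concentration,
                         params$baseline_rate_hz, params$amplitude_hz)
      }, numeric(1))
    }, numeric(length(labs)))
    rates <- matrix(rates, nrow = length(labs))  # condition x unit
    coupling <- function(epoch) ifelse(is_fs,
                                       if (epoch == "spont")
                                         params$fs_gain_coupling_spont
                                       else params$fs_gain_coupling_evoked,
                                       1)
    counts <- array(0, dim = c(length(labs), protocol$n_sweeps, n),
                    dimnames = list(labs,
                                    as.character(seq_len(protocol$n_sweeps)),
                                    units$unit_id))
    for (ci in seq_along(labs)) {
      epoch <- if (labs[ci] == BLANK) "spont" else "evoked"
      sdg <- if (epoch == "spont") params$gain_sd_spont
      else params$gain_sd_evoked
      cc <- coupling(epoch)
      for (sw in seq_len(protocol$n_sweeps)) {
        g <- rtruncnorm_pos(1, 1, sdg)
        lam <- pmax(0, rates[ci, ] * dur * (1 + cc * (g - 1)))
        counts[ci, sw, ] <- stats::rpois(n, lam)
      }
    }
    st <- NULL
    if (spike_times) {
      tot <- sum(counts)
      idx <- which(counts > 0, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        reps <- counts[idx]
        st <- data.frame(
          condition = rep(labs[idx[, 1]], reps),
          sweep = rep(as.integer(idx[, 2]), reps),
          unit_id = rep(units$unit_id[idx[, 3]], reps),
          time_s = stats::runif(tot, 0, dur),
          stringsAsFactors = FALSE)
      } else {
        st <- data.frame(condition = character(0), sweep = integer(0),
                         unit_id = character(0), time_s = numeric(0))
      }
    }
    pn_recording(protocol, units, counts, st)
  })
}

#' Analytic noise correlation implanted by the shared-gain model
#'
#' Law-of-total-variance closed form for a pair of conditionally Poisson
#' units with per-trial count means `lambda_a`, `lambda_b` (stimulus
#' duration folded in) and gain couplings `c_a`, `c_b` under a shared gain
#' of SD `sigma_g`:
#' `cov = c_a c_b lambda_a lambda_b sigma_g^2`,
#' `var_i = lambda_i + c_i^2 lambda_i^2 sigma_g^2`,
#' `r_sc = cov / sqrt(var_a var_b)`. The truncation of the gain at 0 is
#' ignored (negligible for `sigma_g <= 0.3`).
#'
#' @param params a [population_params()].
#' @param lambda_a,lambda_b expected counts per trial (> 0).
#' @param epoch `"evoked"` or `"spont"` (selects the gain SD).
#' @param type_a,type_b `"RS"` or `"FS"` (selects the couplings).
#' @return expected Pearson noise correlation.
#' @export
expected_pair_rsc <- function(params, lambda_a, lambda_b,
                              epoch = c("evoked", "spont"),
                              type_a = "RS", type_b = "RS") {
  epoch <- match.arg(epoch)
  if (lambda_a <= 0 || lambda_b <= 0) stop("rates must be > 0")
  sg <- if (epoch == "spont") params$gain_sd_spont else params$gain_sd_evoked
  cpl <- function(type) {
    if (type == "RS") 1
    else if (epoch == "spont") params$fs_gain_coupling_spont
    else params$fs_gain_coupling_evoked
  }
  ca <- cpl(type_a); cb <- cpl(type_b)
  va <- lambda_a + ca^2 * lambda_a^2 * sg^2
  vb <- lambda_b + cb^2 * lambda_b^2 * sg^2
  if (va <= 0 || vb <= 0) stop("zero variance: correlation undefined")
  ca * cb * lambda_a * lambda_b * sg^2 / sqrt(va * vb)
}

#' Simulate a cohort of animals from one preset
#'
#' @param preset preset name or a [population_params()] object used as the
#'   per-animal template.
#' @param n_animals number of recordings.
#' @param seed master seed; animal `i` uses `seed + i`.
#' @param protocol a [pn_protocol()].
#' @param ... preset overrides (ignored when `preset` is already a params
#'   object).
#' @return list of [pn_recording()]s.
#' @export
simulate_cohort <- function(preset, n_animals = 5, seed = 1,
                            protocol = pn_protocol(), ...) {
  lapply(seq_len(n_animals), function(i) {
    p <- if (inherits(preset, "pn_population_params")) preset
    else preset_params(preset, ...)
    p$seed <- seed + i
    simulate_recording(p, protocol)
  })
}
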