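#' Extract spike-waveform features
#'
#' Measures the three features used to separate fast-spiking (FS, putative
#' PV+ inhibitory) from regular-spiking (RS, putative excitatory) units on
#' an extracellular mean waveform:
#' \describe{
#'   \item{trough_peak_ms}{time from the global trough to the subsequent
#'     peak, in milliseconds;}
#'   \item{peak_trough_ratio}{|peak amplitude| / |trough amplitude|;}
#'   \item{end_slope}{signed slope of the waveform 0.5 ms after the trough,
#'     in amplitude units per ms (central difference).}
#' }
#' At typical acquisition rates (30 kHz) the raw sample grid quantises the
#' trough-to-peak duration to ~0.033 ms, which is coarse relative to the
#' 0.26 ms classification boundary; the waveform is therefore cubic-spline
#' upsampled (`upsample` x, default 30, i.e. ~1 microsecond resolution)
#' before the extrema are located, the standard practice for waveform-based
#' cell typing.
#'
#' @param waveform numeric vector of amplitude samples (>= 3) containing a
#'   negative-going trough followed by at least one sample.
#' @param sampling_rate_hz sampling rate of `waveform` in Hz.
#' @param upsample integer >= 1 spline-upsampling factor.
#' @param slope_at_ms where (after the trough) the end slope is measured.
#' @return list of class `pn_waveform_features` with fields
#'   `trough_peak_ms`, `peak_trough_ratio`, `end_slope`.
#' @export
extract_features <- function(waveform, sampling_rate_hz, upsample = 30L,
                             slope_at_ms = 0.5) {
  if (length(waveform) < 3) stop("waveform must have >= 3 samples")
  upsample <- max(1L, as.integer(upsample))
  if (upsample > 1L) {
    n_out <- (length(waveform) - 1L) * upsample + 1L
    y <- stats::spline(seq_along(waveform), waveform, n = n_out)$y
  } else {
    y <- waveform
  }
  rate <- sampling_rate_hz * upsample
  i_tr <- which.min(y)
  if (i_tr >= length(y))
    stop("trough at final sample: no post-trough peak")
  post <- y[(i_tr + 1L):length(y)]
  i_pk <- i_tr + which.max(post)
  dt_ms <- 1000 / rate
  i_sl <- i_tr + as.integer(round(slope_at_ms / dt_ms))
  if (i_sl + 1L > length(y) || i_sl - 1L < 1L)
    stop("waveform too short to measure end slope ", slope_at_ms,
         " ms after the trough")
  structure(list(
    trough_peak_ms = (i_pk - i_tr) * dt_ms,
    peak_trough_ratio = abs(y[i_pk]) / abs(y[i_tr]),
    end_slope = (y[i_sl + 1L] - y[i_sl - 1L]) / (2 * dt_ms)
  ), class = "pn_waveform_features")
}

#' Classify a unit as fast-spiking or regular-spiking
#'
#' A unit is FS iff all three hold, with strict boundaries: trough-to-peak
#' duration < 0.26 ms, peak-to-trough amplitude ratio > 0.8, and negative
#' end slope. The end-slope criterion is a sign test by default
#' (`slope_max = 0`); a numeric threshold can be supplied instead.
#'
#' @param f a `pn_waveform_features` object from [extract_features()].
#' @param tp_max_ms FS requires `trough_peak_ms` strictly below this.
#' @param ratio_min FS requires `peak_trough_ratio` strictly above this.
#' @param slope_max FS requires `end_slope` strictly below this.
#' @return `"FS"` or `"RS"`.
#' @export
classify_unit <- function(f, tp_max_ms = 0.26, ratio_min = 0.8,
                          slope_max = 0) {
  stopifnot(is.finite(f$trough_peak_ms), is.finite(f$peak_trough_ratio),
            is.finite(f$end_slope))
  fs <- f$trough_peak_ms < tp_max_ms &&
    f$peak_trough_ratio > ratio_min &&
    f$end_slope < slope_max
  if (fs) "FS" else "RS"
}

#' Classify every unit in a recording
#'
#' @param rec a [pn_recording()].
#' @param ... passed to [extract_features()] and [classify_unit()].
#' @return data.frame: `unit_id`, `trough_peak_ms`, `peak_trough_ratio`,
#'   `end_slope`, `class`.
#' @export
classify_units <- function(rec, ...) {
  rate <- rec$protocol$sampling_rate_hz
  out <- lapply(seq_len(nrow(rec$units)), function(i) {
    f <- extract_features(rec$units$waveform[[i]], rate)
    data.frame(unit_id = rec$units$unit_id[i],
               trough_peak_ms = f$trough_peak_ms,
               peak_trough_ratio = f$peak_trough_ratio,
               end_slope = f$end_slope,
               class = classify_unit(f, ...),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate a parametric extracellular spike waveform
#'
#' Builds a biphasic waveform (unit-amplitude negative Gaussian trough, a
#' positive Gaussian after-peak, and a controlled linear-slope segment 0.5
#' ms after the trough) whose measured features closely match the requested
#' ones. Used as the FS/RS template bank of the synthetic-recording
#' generator and for boundary-location tests of [classify_unit()].
#'
#' @param trough_peak_ms requested trough-to-peak duration (ms).
#' @param peak_trough_ratio requested |peak|/|trough| amplitude ratio.
#' @param end_slope requested signed slope (amplitude units / ms) 0.5 ms
#'   after the trough.
#' @param sampling_rate_hz sample rate (default 30 kHz).
#' @param window_ms total waveform duration; trough sits at `trough_at_ms`.
#' @param trough_at_ms trough location from waveform start.
#' @return numeric vector of amplitude samples (trough amplitude -1).
#' @export
make_waveform <- function(trough_peak_ms, peak_trough_ratio, end_slope,
                          sampling_rate_hz = 30000, window_ms = 2.5,
                          trough_at_ms = 0.8) {
  stopifnot(trough_peak_ms > 0, peak_trough_ratio >= 0)
  t_ms <- seq(0, window_ms, by = 1000 / sampling_rate_hz)
  s_tr <- 0.06   # trough width (ms)
  s_pk <- 0.07   # after-peak width (ms)
  tau <- 0.2     # slope-bump width (ms); x*exp(-(x/tau)^2) has slope 1 at x=0
  x0 <- t_ms - trough_at_ms
  xs <- x0 - 0.5
  w <- -exp(-(x0 / s_tr)^2) +
    peak_trough_ratio * exp(-((x0 - trough_peak_ms) / s_pk)^2) +
    end_slope * xs * exp(-(xs / tau)^2)
  w
}

#' FS and RS template waveform parameters
#'
#' Central feature values for the two synthetic cell classes, placed well
#' inside their respective decision regions so that seeded jitter never
#' crosses a classification boundary.
#'
#' @return named list with `FS` and `RS` entries, each a list of
#'   `trough_peak_ms`, `peak_trough_ratio`, `end_slope`.
#' @export
waveform_templates <- function() {
  list(FS = list(trough_peak_ms = 0.18, peak_trough_ratio = 1.1,
                 end_slope = -0.05),
       RS = list(trough_peak_ms = 0.45, peak_trough_ratio = 0.45,
                 end_slope = 0.02))
}
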