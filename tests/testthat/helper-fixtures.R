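# Hand-constructed minimal recording: 1 unit, conditions {0, BLANK},
# 2 sweeps, counts 0 deg: (3, 5), BLANK: (1, 0).
tiny_recording <- function(duration_s = 1, counts0 = c(3, 5),
                           counts_blank = c(1, 0)) {
  proto <- pn_protocol(directions = 0, duration_s = duration_s, n_sweeps = 2)
  units <- data.frame(unit_id = "u1", channel_index = 1L, depth_um = 30,
                      group_label = "test", stringsAsFactors = FALSE)
  units$waveform <- list(make_waveform(0.4, 0.5, 0.02))
  counts <- array(rbind(counts0, counts_blank), dim = c(2, 2, 1),
                  dimnames = list(c("0", "BLANK"), c("1", "2"), "u1"))
  pn_recording(proto, units, counts)
}

# Multi-unit hand-built recording with prescribed per-unit count matrices
# (condition x sweep), default protocol directions/blank inferred.
build_recording <- function(count_mats, directions, duration_s = 1,
                            depths = NULL, waveform_classes = NULL,
                            has_blank = TRUE) {
  n_sweeps <- ncol(count_mats[[1]])
  proto <- pn_protocol(directions = directions, duration_s = duration_s,
                       n_sweeps = n_sweeps, has_blank = has_blank)
  labs <- condition_labels(proto)
  n <- length(count_mats)
  if (is.null(depths)) depths <- 30 * seq_len(n)
  if (is.null(waveform_classes)) waveform_classes <- rep("RS", n)
  tmpl <- waveform_templates()
  units <- data.frame(unit_id = sprintf("u%d", seq_len(n)),
                      channel_index = seq_len(n), depth_um = depths,
                      group_label = "test", stringsAsFactors = FALSE)
  units$waveform <- lapply(waveform_classes, function(cl) {
    tp <- tmpl[[cl]]
    make_waveform(tp$trough_peak_ms, tp$peak_trough_ratio, tp$end_slope)
  })
  counts <- array(NA_real_, dim = c(length(labs), n_sweeps, n),
                  dimnames = list(labs, as.character(seq_len(n_sweeps)),
                                  units$unit_id))
  for (i in seq_len(n)) {
    m <- count_mats[[i]]
    stopifnot(nrow(m) == length(labs))
    counts[, , i] <- m
  }
  pn_recording(proto, units, counts)
}

# Small cached simulated recording shared across tests.
sim_recording_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_recording(
        preset_params("young", n_units = 8, seed = 42),
        pn_protocol(n_sweeps = 10))
    cache
  }
})
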