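#' @keywords internal
"_PACKAGE"

#' Reserved condition label for blank (gray-screen) trials
#' @export
BLANK <- "BLANK"

#' Construct a stimulus protocol
#'
#' Describes the trial structure of a drifting-grating recording session:
#' the set of motion directions (degrees), whether blank gray-screen trials
#' are interleaved, the stimulus duration, the number of sweeps (one sweep =
#' one pseudorandom pass through all conditions) and the waveform sampling
#' rate of the acquisition system.
#'
#' @param directions numeric vector of distinct grating directions in
#'   degrees, each in `[0, 360)`. Default: 0 to 330 in 30 degree steps.
#' @param duration_s stimulus duration per trial in seconds (> 0).
#' @param n_sweeps number of sweeps (>= 1).
#' @param sampling_rate_hz waveform sampling rate in Hz.
#' @param has_blank logical; include a blank condition.
#' @return an object of class `pn_protocol`.
#' @export
pn_protocol <- function(directions = seq(0, 330, by = 30), duration_s = 1,
                        n_sweeps = 10, sampling_rate_hz = 30000,
                        has_blank = TRUE) {
  directions <- as.numeric(directions)
  if (anyDuplicated(directions)) stop("directions must be distinct")
  if (any(directions < 0 | directions >= 360))
    stop("directions must lie in [0, 360)")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0")
  if (n_sweeps < 1) stop("n_sweeps must be >= 1")
  structure(list(directions = directions, has_blank = isTRUE(has_blank),
                 duration_s = duration_s, n_sweeps = as.integer(n_sweeps),
                 sampling_rate_hz = sampling_rate_hz),
            class = "pn_protocol")
}

#' Condition labels of a protocol
#'
#' Grating directions are labelled by their integer-formatted degree value;
#' the blank condition carries the reserved token `"BLANK"`.
#'
#' @param protocol a [pn_protocol()].
#' @param blank include the blank label (if the protocol has one).
#' @return character vector of condition labels.
#' @export
condition_labels <- function(protocol, blank = TRUE) {
  labs <- format_direction(protocol$directions)
  if (blank && protocol$has_blank) labs <- c(labs, BLANK)
  labs
}

format_direction <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9, as.character(as.integer(round(x))),
         as.character(x))
}

#' Construct a trial-structured recording
#'
#' The canonical container for one animal/session: a protocol, a unit table
#' (identifier, probe channel, depth, group tag and mean spike waveform) and
#' a 3-way spike-count array `condition x sweep x unit`. Spike times are
#' optional and only needed for sub-trial response binning.
#'
#' @param protocol a [pn_protocol()].
#' @param units data.frame with columns `unit_id`, `channel_index`,
#'   `depth_um`, `group_label` and a list-column `waveform` of numeric
#'   vectors (>= 3 samples each).
#' @param counts integer array `[condition, sweep, unit]` with dimnames
#'   matching `condition_labels(protocol)`, sweep indices and `unit_id`s.
#' @param spike_times optional data.frame with columns `condition`, `sweep`,
#'   `unit_id`, `time_s` (one row per spike, time relative to stimulus
#'   onset).
#' @return an object of class `pn_recording`.
#' @export
pn_recording <- function(protocol, units, counts, spike_times = NULL) {
  rec <- structure(list(protocol = protocol, units = units, counts = counts,
                        spike_times = spike_times),
                   class = "pn_recording")
  validate_recording(rec)
  rec
}

#' Validate a recording's invariants
#'
#' Checks non-negative integer counts, exactly one count cell per
#' (condition, sweep, unit), condition labels within the protocol's set,
#' and well-formed unit records.
#'
#' @param rec a [pn_recording()].
#' @return `rec`, invisibly; stops with an informative error otherwise.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec$protocol, "pn_protocol"))
  u <- rec$units
  need <- c("unit_id", "channel_index", "depth_um", "group_label", "waveform")
  if (!all(need %in% names(u)))
    stop("units table missing columns: ",
         paste(setdiff(need, names(u)), collapse = ", "))
  if (anyDuplicated(u$unit_id)) stop("duplicate unit_id in units table")
  if (any(u$depth_um < 0)) stop("depth_um must be >= 0")
  wl <- vapply(u$waveform, length, integer(1))
  if (any(wl < 3)) stop("waveforms must have >= 3 samples")
  cn <- dimnames(rec$counts)
  labs <- condition_labels(rec$protocol)
  if (is.null(cn) || length(dim(rec$counts)) != 3)
    stop("counts must be a 3-way array condition x sweep x unit")
  if (!setequal(cn[[1]], labs) || length(cn[[1]]) != length(labs))
    stop("count condition labels must match the protocol's condition set")
  if (dim(rec$counts)[2] != rec$protocol$n_sweeps)
    stop("counts sweep dimension must equal protocol n_sweeps")
  if (!identical(sort(cn[[3]]), sort(u$unit_id)))
    stop("count unit labels must match the units table")
  if (anyNA(rec$counts)) stop("missing count cell (every (condition, sweep) ",
                              "must be present exactly once per unit)")
  if (any(rec$counts < 0)) stop("negative spike count")
  if (any(abs(rec$counts - round(rec$counts)) > 1e-9))
    stop("spike counts must be integers")
  if (!is.null(rec$spike_times)) {
    st <- rec$spike_times
    if (!all(c("condition", "sweep", "unit_id", "time_s") %in% names(st)))
      stop("spike_times must have condition, sweep, unit_id, time_s")
    if (!all(st$condition %in% labs)) stop("spike_times condition not in protocol")
  }
  invisible(rec)
}

#' @export
print.pn_recording <- function(x, ...) {
  p <- x$protocol
  cat("<pn_recording> ", nrow(x$units), " units, ",
      length(p$directions), " directions",
      if (p$has_blank) " + blank", ", ", p$n_sweeps, " sweeps, ",
      p$duration_s, " s trials\n", sep = "")
  cat("  groups:", paste(unique(x$units$group_label), collapse = ", "), "\n")
  invisible(x)
}

#' Number of units in a recording
#' @param rec a [pn_recording()].
#' @return integer count.
#' @export
n_units <- function(rec) nrow(rec$units)

#' Per-unit count matrix
#'
#' @param rec a [pn_recording()].
#' @param unit a `unit_id`.
#' @return numeric matrix `condition x sweep`.
#' @export
unit_counts <- function(rec, unit) {
  if (!unit %in% dimnames(rec$counts)[[3]]) stop("unknown unit: ", unit)
  m <- rec$counts[, , unit, drop = FALSE]
  matrix(m, nrow = dim(m)[1], ncol = dim(m)[2],
         dimnames = dimnames(rec$counts)[1:2])
}

#' Mean firing rate of a unit in a condition
#'
#' Mean spike count across sweeps divided by the stimulus duration; with the
#' blank condition this is the spontaneous rate, with a grating condition
#' the evoked rate.
#'
#' @param rec a [pn_recording()].
#' @param unit a `unit_id`.
#' @param condition a condition label (see [condition_labels()]).
#' @return rate in spikes per second.
#' @export
mean_rate <- function(rec, unit, condition) {
  m <- unit_counts(rec, unit)
  if (!condition %in% rownames(m)) stop("unknown condition: ", condition)
  mean(m[condition, ]) / rec$protocol$duration_s
}

#' Write a recording bundle to disk
#'
#' The bundle is a directory of plain-text files: `protocol.json`,
#' `units.tsv` (waveform stored as a comma-joined decimal string),
#' `trials.tsv` (one row per condition/sweep/unit cell) and, when spike
#' times are present, `spike_times.tsv`. UTF-8, LF, header rows.
#'
#' @param rec a [pn_recording()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create bundle directory: ", path)
  p <- rec$protocol
  jsonlite::write_json(
    list(directions = p$directions, has_blank = p$has_blank,
         duration_s = p$duration_s, n_sweeps = p$n_sweeps,
         sampling_rate_hz = p$sampling_rate_hz),
    file.path(path, "protocol.json"), auto_unbox = TRUE, digits = NA)
  u <- rec$units
  udf <- data.frame(unit_id = u$unit_id, channel_index = u$channel_index,
                    depth_um = u$depth_um, group_label = u$group_label,
                    waveform = vapply(u$waveform, function(w)
                      paste(format(w, digits = 15, scientific = FALSE,
                                   trim = TRUE), collapse = ","),
                      character(1)),
                    stringsAsFactors = FALSE)
  write_tsv(udf, file.path(path, "units.tsv"))
  cn <- dimnames(rec$counts)
  tdf <- expand.grid(condition = cn[[1]], sweep = seq_along(cn[[2]]),
                     unit_id = cn[[3]], KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  tdf$count <- as.integer(rec$counts[cbind(tdf$condition,
                                           as.character(tdf$sweep),
                                           tdf$unit_id)])
  write_tsv(tdf, file.path(path, "trials.tsv"))
  tf <- file.path(path, "spike_times.tsv")
  if (!is.null(rec$spike_times)) {
    write_tsv(rec$spike_times[c("condition", "sweep", "unit_id", "time_s")], tf)
  } else if (file.exists(tf)) {
    unlink(tf)
  }
  invisible(path)
}

write_tsv <- function(df, file) {
  con <- file(file, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
}

#' Read a recording bundle
#'
#' Inverse of [write_recording()]: reconstructs a validated
#' [pn_recording()] from a bundle directory. Row order in `trials.tsv` is
#' immaterial; duplicated (condition, sweep, unit) rows or negative counts
#' raise integrity errors.
#'
#' @param path bundle directory.
#' @return a [pn_recording()].
#' @export
read_recording <- function(path) {
  pj <- file.path(path, "protocol.json")
  uf <- file.path(path, "units.tsv")
  tf <- file.path(path, "trials.tsv")
  for (f in c(pj, uf, tf))
    if (!file.exists(f)) stop("bundle is missing required file: ", basename(f))
  pl <- jsonlite::read_json(pj, simplifyVector = TRUE)
  protocol <- pn_protocol(directions = pl$directions,
                          duration_s = pl$duration_s,
                          n_sweeps = pl$n_sweeps,
                          sampling_rate_hz = pl$sampling_rate_hz,
                          has_blank = pl$has_blank)
  udf <- utils::read.delim(uf, stringsAsFactors = FALSE,
                           colClasses = c(unit_id = "character"))
  units <- data.frame(unit_id = udf$unit_id,
                      channel_index = as.integer(udf$channel_index),
                      depth_um = as.numeric(udf$depth_um),
                      group_label = udf$group_label,
                      stringsAsFactors = FALSE)
  units$waveform <- lapply(strsplit(udf$waveform, ","), as.numeric)
  tdf <- utils::read.delim(tf, stringsAsFactors = FALSE,
                           colClasses = c(condition = "character",
                                          unit_id = "character"))
  key <- paste(tdf$condition, tdf$sweep, tdf$unit_id, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate trial row for (condition, sweep, unit): ",
         key[which(duplicated(key))[1]])
  if (any(tdf$count < 0)) stop("negative spike count in trials.tsv")
  labs <- condition_labels(protocol)
  counts <- array(NA_real_,
                  dim = c(length(labs), protocol$n_sweeps, nrow(units)),
                  dimnames = list(labs, as.character(seq_len(protocol$n_sweeps)),
                                  units$unit_id))
  counts[cbind(tdf$condition, as.character(tdf$sweep), tdf$unit_id)] <- tdf$count
  stf <- file.path(path, "spike_times.tsv")
  spike_times <- NULL
  if (file.exists(stf))
    spike_times <- utils::read.delim(stf, stringsAsFactors = FALSE,
                                     colClasses = c(condition = "character",
                                                    unit_id = "character"))
  pn_recording(protocol, units, counts, spike_times)
}
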