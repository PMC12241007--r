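pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Per-condition trial z-scores, pooled
#'
#' For each condition the trial responses are standardised to
#' `z = (R_trial - E(R)) / sigma` using that condition's across-sweep mean
#' and population-form (divide by n) standard deviation, matching the
#' expectation-operator definitions, removing the stimulus-driven component;
#' the z-vectors are then pooled across conditions in fixed
#' (condition, sweep) order. Conditions with zero standard deviation carry
#' no variability information and are dropped (the `valid` mask lets a
#' caller drop them jointly for both members of a pair).
#'
#' @param counts_by_condition named list of per-condition trial-count
#'   vectors (each length >= 2).
#' @return list: `z` (pooled z-scores over valid conditions), `valid`
#'   (logical per condition), `conditions` (names).
#' @export
trial_z_scores <- function(counts_by_condition) {
  if (any(vapply(counts_by_condition, length, integer(1)) < 2))
    stop("need >= 2 trials per condition")
  sds <- vapply(counts_by_condition, pop_sd, numeric(1))
  valid <- sds > 0
  if (!any(valid)) stop("no condition with positive standard deviation")
  zl <- lapply(counts_by_condition[valid],
               function(x) (x - mean(x)) / pop_sd(x))
  list(z = unlist(zl, use.names = FALSE), valid = valid,
       conditions = names(counts_by_condition) %||%
         as.character(seq_along(counts_by_condition)))
}

#' Noise correlation of two pooled z-score vectors
#'
#' Pearson correlation coefficient of the trial-to-trial response
#' fluctuations (z-scores) of two simultaneously recorded units.
#'
#' @param za,zb numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
noise_correlation <- function(za, zb) {
  if (length(za) != length(zb)) stop("z vectors must have equal length")
  if (length(za) < 3) stop("need >= 3 pooled trials")
  if (stats::sd(za) == 0 || stats::sd(zb) == 0)
    stop("noise correlation undefined: zero variance after pooling")
  stats::cor(za, zb)
}

#' Response covariance of two spike-count vectors
#'
#' Population-form covariance exactly as the expectation identity:
#' `cov(N1, N2) = E(N1 * N2) - E(N1) * E(N2)` (divide by n, not n-1).
#'
#' @param na,nb numeric vectors of equal length >= 2.
#' @return covariance in counts^2.
#' @export
response_covariance <- function(na, nb) {
  if (length(na) != length(nb)) stop("count vectors must have equal length")
  if (length(na) < 2) stop("need >= 2 trials")
  mean(na * nb) - mean(na) * mean(nb)
}

#' Decorrelation index of an FS-RS pair
#'
#' Difference between evoked and spontaneous noise correlations, clamped at
#' zero: `min(0, rsc_evoked - rsc_spont)`. A positive difference indicates
#' no decorrelation effect and is assigned zero; the more negative the
#' value, the stronger the inhibition-mediated decorrelation.
#'
#' @param rsc_evoked,rsc_spont noise correlations.
#' @return value <= 0.
#' @export
decorrelation_index <- function(rsc_evoked, rsc_spont) {
  pmin(0, rsc_evoked - rsc_spont)
}

pair_condition_counts <- function(rec, unit, conditions) {
  m <- unit_counts(rec, unit)[conditions, , drop = FALSE]
  stats::setNames(split(m, row(m)), conditions)
}

#' Noise correlation of one unit pair
#'
#' Computes r_sc from pooled per-condition z-scores; conditions where
#' either unit has zero across-sweep standard deviation are dropped for
#' both members. `epoch = "evoked"` pools over all grating conditions,
#' `"spont"` uses the blank condition alone.
#'
#' @param rec a [pn_recording()].
#' @param unit_a,unit_b unit ids.
#' @param epoch `"evoked"` or `"spont"`.
#' @return list: `rsc`, `n_trials_used`.
#' @export
pair_noise_correlation <- function(rec, unit_a, unit_b,
                                   epoch = c("evoked", "spont")) {
  epoch <- match.arg(epoch)
  conds <- if (epoch == "evoked")
    condition_labels(rec$protocol, blank = FALSE)
  else BLANK
  ca <- pair_condition_counts(rec, unit_a, conds)
  cb <- pair_condition_counts(rec, unit_b, conds)
  sda <- vapply(ca, pop_sd, numeric(1))
  sdb <- vapply(cb, pop_sd, numeric(1))
  valid <- sda > 0 & sdb > 0
  if (sum(valid) == 0)
    return(list(rsc = NA_real_, n_trials_used = 0L))
  zs <- function(x) (x - mean(x)) / pop_sd(x)
  za <- unlist(lapply(ca[valid], zs), use.names = FALSE)
  zb <- unlist(lapply(cb[valid], zs), use.names = FALSE)
  if (length(za) < 3) return(list(rsc = NA_real_, n_trials_used = length(za)))
  list(rsc = noise_correlation(za, zb), n_trials_used = length(za))
}

#' Pairwise statistics table for a recording
#'
#' One row per unordered pair of simultaneously recorded units: probe
#' distance, preferred-orientation difference (for pairs where both tuning
#' fits pass the goodness filter), evoked and spontaneous noise
#' correlations, raw-count response covariance pooled over grating
#' conditions (as printed, this mixes signal and noise covariance), the
#' pair's mean evoked firing rate, the pair type from waveform
#' classification, and the decorrelation index (FS-RS pairs only).
#'
#' @param rec a [pn_recording()].
#' @param fits optional list from [fit_tuning()] (computed if `NULL`).
#' @param classes optional data.frame from [classify_units()].
#' @param gof_threshold goodness filter for delta-PO (see
#'   [apply_gof_filter()]).
#' @param rate_mean `"arithmetic"` (default) or `"geometric"` combination
#'   of the two units' evoked rates.
#' @return data.frame of pair statistics.
#' @export
pair_stats <- function(rec, fits = NULL, classes = NULL, gof_threshold = 0.6,
                       rate_mean = c("arithmetic", "geometric")) {
  rate_mean <- match.arg(rate_mean)
  if (n_units(rec) < 2) stop("pair statistics need >= 2 units")
  if (is.null(fits)) fits <- fit_tuning(rec)
  if (is.null(classes)) classes <- classify_units(rec)
  ids <- rec$units$unit_id
  depth <- stats::setNames(rec$units$depth_um, ids)
  cls <- stats::setNames(classes$class, classes$unit_id)
  glabs <- condition_labels(rec$protocol, blank = FALSE)
  ev_rate <- vapply(ids, function(u)
    mean(vapply(glabs, function(cc) mean_rate(rec, u, cc), numeric(1))),
    numeric(1))
  po <- vapply(ids, function(u) {
    f <- fits[[u]]
    if (is.finite(f$gof) && f$gof > gof_threshold) f$preferred_orientation
    else NA_real_
  }, numeric(1))
  raw <- lapply(ids, function(u)
    as.numeric(t(unit_counts(rec, u)[glabs, , drop = FALSE])))
  names(raw) <- ids
  idx <- utils::combn(length(ids), 2)
  rows <- lapply(seq_len(ncol(idx)), function(j) {
    a <- ids[idx[1, j]]; b <- ids[idx[2, j]]
    ev <- pair_noise_correlation(rec, a, b, "evoked")
    sp <- if (rec$protocol$has_blank)
      pair_noise_correlation(rec, a, b, "spont")
    else list(rsc = NA_real_, n_trials_used = 0L)
    pt <- paste(sort(c(cls[[a]], cls[[b]])), collapse = "-")
    dec <- if (pt == "FS-RS" && !is.na(ev$rsc) && !is.na(sp$rsc))
      decorrelation_index(ev$rsc, sp$rsc)
    else NA_real_
    pr <- if (rate_mean == "arithmetic") mean(c(ev_rate[[a]], ev_rate[[b]]))
    else sqrt(ev_rate[[a]] * ev_rate[[b]])
    data.frame(unit_a = a, unit_b = b,
               distance_um = abs(depth[[a]] - depth[[b]]),
               delta_po_deg = if (is.na(po[[a]]) || is.na(po[[b]])) NA_real_
               else delta_po(po[[a]], po[[b]]),
               rsc_evoked = ev$rsc, rsc_spont = sp$rsc,
               covariance = response_covariance(raw[[a]], raw[[b]]),
               pair_rate = pr, pair_type = pt, decorrelation = dec,
               n_trials_used = ev$n_trials_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

default_bin_edges <- function(key) {
  switch(key,
         rate = seq(0, 50, by = 10),
         distance = seq(0, 300, by = 50),
         dpo = seq(0, 90, by = 30),
         stop("unknown binning key: ", key))
}

#' Bin pairwise noise correlations against a pair covariate
#'
#' Assigns pairs to half-open bins `[lo, hi)` of the chosen covariate
#' (pair firing rate, probe distance, or delta-PO) and reports the mean,
#' SEM and count of `rsc_evoked` per bin. Default edges: rate 0-50 by 10
#' spikes/s, distance 0-300 by 50 um, delta-PO 0-90 by 30 degrees. Values
#' at or beyond the final edge go to a separately reported overflow bin.
#'
#' @param pairs data.frame from [pair_stats()] (rows with `NA` covariate or
#'   `NA` r_sc are dropped).
#' @param key `"rate"`, `"distance"` or `"dpo"`.
#' @param edges ascending numeric bin edges.
#' @param value column of `pairs` to aggregate (default `"rsc_evoked"`).
#' @return list of class `pn_binned`: `key`, `bin_edges`, `bin_means`,
#'   `bin_sems`, `bin_ns`, `overflow` (list with `n`, `mean`).
#' @export
bin_relation <- function(pairs, key = c("rate", "distance", "dpo"),
                         edges = NULL, value = "rsc_evoked") {
  key <- match.arg(key)
  if (is.null(edges)) edges <- default_bin_edges(key)
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be ascending")
  xcol <- switch(key, rate = "pair_rate", distance = "distance_um",
                 dpo = "delta_po_deg")
  x <- pairs[[xcol]]
  y <- pairs[[value]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  nb <- length(edges) - 1
  bin <- findInterval(x, edges, rightmost.closed = FALSE)
  means <- sems <- rep(NA_real_, nb)
  ns <- integer(nb)
  for (b in seq_len(nb)) {
    yb <- y[bin == b]
    ns[b] <- length(yb)
    if (ns[b] > 0) means[b] <- mean(yb)
    if (ns[b] > 1) sems[b] <- stats::sd(yb) / sqrt(ns[b])
  }
  over <- y[bin > nb | bin < 1]
  structure(list(key = key, bin_edges = edges, bin_means = means,
                 bin_sems = sems, bin_ns = ns,
                 overflow = list(n = length(over),
                                 mean = if (length(over)) mean(over)
                                 else NA_real_)),
            class = "pn_binned")
}
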