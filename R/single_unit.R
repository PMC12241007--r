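#' ROC-based signal-to-noise ratio
#'
#' Discriminability between stimulus-evoked and spontaneous response
#' distributions. A threshold is swept across all observed response values;
#' at each threshold the true positive rate (proportion of evoked bins
#' strictly above it) and false positive rate (proportion of spontaneous
#' bins strictly above it) give one ROC point; the SNR is the area under
#' the resulting curve (trapezoidal integration). 0.5 is chance-level
#' discrimination, 1.0 perfect separation. With this threshold sweep the
#' AUC equals the Mann-Whitney U statistic divided by `n * m`, ties counted
#' one half.
#'
#' @param evoked_bins numeric vector of evoked response bins (non-empty).
#' @param spont_bins numeric vector of spontaneous response bins.
#' @return list of class `pn_roc`: `auc`, `roc_points` (data.frame `fpr`,
#'   `tpr`, monotone from (0,0) to (1,1)), `n_evoked_bins`, `n_spont_bins`.
#' @export
roc_snr <- function(evoked_bins, spont_bins) {
  if (length(evoked_bins) == 0 || length(spont_bins) == 0)
    stop("evoked and spontaneous bin lists must be non-empty")
  thr <- sort(unique(c(evoked_bins, spont_bins)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(evoked_bins > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(spont_bins > t), numeric(1))
  # threshold above the maximum gives (0,0); the minimum itself gives (1,1)
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(auc = auc, roc_points = pts,
                 n_evoked_bins = length(evoked_bins),
                 n_spont_bins = length(spont_bins)),
            class = "pn_roc")
}

#' Within-trial response bins for ROC analysis
#'
#' Splits each 1 s (or `duration_s`) stimulus window of the given condition
#' into consecutive bins of `bin_s` seconds and counts spikes per bin,
#' pooling bins across the condition's sweeps. Requires per-spike times;
#' without them, falls back to one bin per trial (the whole-trial count).
#'
#' @param rec a [pn_recording()].
#' @param unit a `unit_id`.
#' @param condition a condition label.
#' @param bin_s bin width in seconds; must divide the stimulus duration.
#' @return numeric vector of per-bin spike counts.
#' @export
make_response_bins <- function(rec, unit, condition, bin_s = 0.1) {
  dur <- rec$protocol$duration_s
  if (bin_s <= 0) stop("bin_s must be > 0")
  nb <- dur / bin_s
  if (abs(nb - round(nb)) > 1e-9)
    stop("bin_s must divide the stimulus duration")
  nb <- as.integer(round(nb))
  if (is.null(rec$spike_times)) {
    if (nb > 1)
      warning("no spike times in recording; falling back to one bin per trial")
    return(as.numeric(unit_counts(rec, unit)[condition, ]))
  }
  st <- rec$spike_times
  st <- st[st$unit_id == unit & st$condition == condition, , drop = FALSE]
  edges <- seq(0, dur, length.out = nb + 1)
  out <- numeric(0)
  for (sw in seq_len(rec$protocol$n_sweeps)) {
    t_sw <- st$time_s[st$sweep == sw]
    t_sw <- t_sw[t_sw >= 0 & t_sw < dur]
    h <- if (length(t_sw)) tabulate(findInterval(t_sw, edges,
                                                 rightmost.closed = FALSE),
                                    nbins = nb)
    else integer(nb)
    out <- c(out, h)
  }
  out
}

#' Fano factor of a single unit
#'
#' Trial-to-trial response variability: the variance-to-mean ratio of spike
#' counts across repeats of the same grating condition (unbiased, n-1,
#' variance), averaged over grating conditions. Conditions with zero mean
#' are skipped; 1 is the Poisson benchmark.
#'
#' @param counts_by_condition list (or matrix rows = conditions) of
#'   per-condition trial-count vectors, each of length >= 2.
#' @return list of class `pn_fano`: `ff` (grand average), `variance` and
#'   `mean` (per used condition, averaged), `scope`, `per_condition`
#'   data.frame.
#' @export
fano_factor <- function(counts_by_condition) {
  if (is.matrix(counts_by_condition))
    counts_by_condition <- split(counts_by_condition,
                                 row(counts_by_condition))
  if (any(vapply(counts_by_condition, length, integer(1)) < 2))
    stop("need >= 2 trials per condition")
  mu <- vapply(counts_by_condition, mean, numeric(1))
  v <- vapply(counts_by_condition, stats::var, numeric(1))
  use <- mu > 0
  if (!any(use)) stop("Fano factor undefined: all conditions have zero mean")
  per <- data.frame(condition = names(counts_by_condition) %||%
                      as.character(seq_along(mu)),
                    mean = mu, variance = v, ff = v / mu, used = use)
  structure(list(ff = mean(per$ff[use]), variance = mean(v[use]),
                 mean = mean(mu[use]), scope = "single-unit",
                 per_condition = per),
            class = "pn_fano")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-unit activity Fano factor
#'
#' Spike counts are summed across all simultaneously recorded units per
#' trial; [fano_factor()] is applied to the summed series. Captures
#' population-level (shared) variability: with independent Poisson units
#' the MUA FF stays near 1, while shared gain fluctuations inflate it.
#'
#' @param rec a [pn_recording()] with >= 2 units (a single unit degenerates
#'   to its own FF).
#' @param conditions condition labels to use (default: gratings only).
#' @return `pn_fano` with scope `"MUA"`.
#' @export
mua_fano <- function(rec, conditions = condition_labels(rec$protocol,
                                                        blank = FALSE)) {
  summed <- apply(rec$counts[conditions, , , drop = FALSE], c(1, 2), sum)
  res <- fano_factor(stats::setNames(split(summed, row(summed)), conditions))
  res$scope <- "MUA"
  res
}

#' Grating condition with maximal mean response for a unit
#'
#' The raw argmax over grating condition means (not the fitted optimum), so
#' SNR does not depend on tuning-fit success.
#'
#' @param rec a [pn_recording()].
#' @param unit a `unit_id`.
#' @return condition label.
#' @export
optimal_condition <- function(rec, unit) {
  labs <- condition_labels(rec$protocol, blank = FALSE)
  m <- rowMeans(unit_counts(rec, unit)[labs, , drop = FALSE])
  labs[which.max(m)]
}

#' Single-unit response metrics table
#'
#' Per unit: spontaneous rate (blank trials), peak evoked rate (optimal
#' condition), their difference, ROC-based SNR (evoked bins from the
#' optimal condition vs spontaneous bins from blank trials) and the Fano
#' factor. `rate_split` groups units by evoked rate difference (strictly
#' greater than the split goes to the `"high"` group).
#'
#' @param rec a [pn_recording()].
#' @param roc_bin_s ROC bin width in seconds (see [make_response_bins()]).
#' @param rate_split spikes/s boundary between low and high evoked-rate
#'   groups (default 6).
#' @param ff_scope `"average"` over grating conditions or `"optimal"` only.
#' @return data.frame, one row per unit.
#' @export
unit_metrics <- function(rec, roc_bin_s = 0.1, rate_split = 6,
                         ff_scope = c("average", "optimal")) {
  ff_scope <- match.arg(ff_scope)
  if (!rec$protocol$has_blank)
    stop("spontaneous metrics need a blank condition")
  labs <- condition_labels(rec$protocol, blank = FALSE)
  rows <- lapply(rec$units$unit_id, function(u) {
    opt <- optimal_condition(rec, u)
    spont <- mean_rate(rec, u, BLANK)
    peak <- mean_rate(rec, u, opt)
    ev <- make_response_bins(rec, u, opt, roc_bin_s)
    sp <- make_response_bins(rec, u, BLANK, roc_bin_s)
    snr <- roc_snr(ev, sp)$auc
    cc <- if (ff_scope == "optimal") opt else labs
    cm <- unit_counts(rec, u)[cc, , drop = FALSE]
    ff <- tryCatch(fano_factor(stats::setNames(split(cm, row(cm)), cc))$ff,
                   error = function(e) NA_real_)
    data.frame(unit_id = u, spont_rate = spont, peak_rate = peak,
               evoked_minus_spont = peak - spont, snr_auc = snr, ff = ff,
               rate_group = if (peak - spont > rate_split) "high" else "low",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
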