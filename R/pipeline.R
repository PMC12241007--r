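#' Assemble a full-run configuration
#'
#' Collects every tunable of the pipeline with defaults equal to the
#' documented analysis choices: goodness-of-fit threshold 0.6, FS
#' boundaries 0.26 ms / 0.8 / negative slope, ROC bin 0.1 s, evoked-rate
#' split 6 spikes/s, standard bin edges, and the default protocol (12
#' directions + blank, 10 sweeps, 1 s trials).
#'
#' @param groups character vector of preset names (see [preset_params()])
#'   and/or named list mapping group name to a bundle directory (or vector
#'   of directories) to read instead of simulating.
#' @param n_animals simulated animals per preset group.
#' @param seed master seed; all stage seeds derive from it by fixed
#'   offsets.
#' @param sweeps sweeps per simulated recording.
#' @param gof_threshold tuning goodness filter.
#' @param roc_bin_s ROC bin width (s).
#' @param rate_split evoked-rate split (spikes/s).
#' @param mi_sizes,mi_bins,mi_subsets MI-curve parameters.
#' @param out optional output directory for report tables.
#' @return list of class `pn_run_config`.
#' @export
run_config <- function(groups = c("young", "aged", "met"), n_animals = 10,
                       seed = 1, sweeps = 10, gof_threshold = 0.6,
                       roc_bin_s = 0.1, rate_split = 6, mi_sizes = 1:5,
                       mi_bins = 2, mi_subsets = 10, out = NULL) {
  structure(as.list(environment()), class = "pn_run_config")
}

#' Analyse one recording end to end
#'
#' Runs tuning fits, waveform classification, single-unit metrics, pair
#' statistics and the MI curve for a single recording.
#'
#' @param rec a [pn_recording()].
#' @param config a [run_config()].
#' @param mi_seed seed for MI subset draws.
#' @return list: `units` (per-unit table incl. gof, osi, class), `pairs`,
#'   `mi` (`pn_mi_curve`), `mua_ff`, `n_excluded_gof`.
#' @export
analyze_recording <- function(rec, config = run_config(), mi_seed = 1) {
  fits <- fit_tuning(rec)
  classes <- classify_units(rec)
  um <- unit_metrics(rec, roc_bin_s = config$roc_bin_s,
                     rate_split = config$rate_split)
  tun <- data.frame(unit_id = names(fits),
                    theta1 = vapply(fits, `[[`, numeric(1), "theta1"),
                    gof = vapply(fits, `[[`, numeric(1), "gof"),
                    osi = vapply(fits, function(f)
                      f$osi %||% NA_real_, numeric(1)),
                    preferred_orientation = vapply(fits, `[[`, numeric(1),
                                                   "preferred_orientation"),
                    stringsAsFactors = FALSE)
  tun$osi_selected <- ifelse(is.finite(tun$gof) &
                               tun$gof > config$gof_threshold,
                             tun$osi, NA_real_)
  units <- merge(merge(um, tun, by = "unit_id"),
                 classes[c("unit_id", "class")], by = "unit_id")
  pairs <- pair_stats(rec, fits = fits, classes = classes,
                      gof_threshold = config$gof_threshold)
  sizes <- config$mi_sizes[config$mi_sizes <= n_units(rec)]
  mi <- mi_vs_population_size(rec, sizes = sizes,
                              n_subsets = config$mi_subsets,
                              n_bins = config$mi_bins, seed = mi_seed)
  list(units = units, pairs = pairs, mi = mi, mua_ff = mua_fano(rec)$ff,
       n_excluded_gof = sum(!(is.finite(tun$gof) &
                                tun$gof > config$gof_threshold)))
}

group_recordings <- function(config) {
  groups <- config$groups
  if (is.character(groups)) groups <- stats::setNames(as.list(groups), groups)
  protocol <- pn_protocol(n_sweeps = config$sweeps)
  out <- list()
  for (gi in seq_along(groups)) {
    gname <- names(groups)[gi]
    spec <- groups[[gi]]
    if (inherits(spec, "pn_population_params")) {
      recs <- simulate_cohort(spec, n_animals = config$n_animals,
                              seed = config$seed * 1000 + gi * 100,
                              protocol = protocol)
    } else if (is.character(spec) && all(dir.exists(spec))) {
      recs <- lapply(spec, read_recording)
    } else if (is.character(spec) && length(spec) == 1 &&
               spec %in% c("young", "aged", "met")) {
      recs <- simulate_cohort(spec, n_animals = config$n_animals,
                              seed = config$seed * 1000 + gi * 100,
                              protocol = protocol)
    } else {
      stop("group '", gname, "' is neither a known preset nor an existing ",
           "bundle directory")
    }
    out[[gname]] <- recs
  }
  out
}

#' Run the complete analysis pipeline
#'
#' simulate (or load) -> tuning -> single-unit metrics -> pairs -> MI ->
#' classification -> group comparisons, deterministically under the master
#' seed. Produces pooled per-group unit and pair tables, MI curves, binned
#' r_sc relations, and a comparisons table (Mann-Whitney + Cliff's delta
#' for unit/pair metrics; additive two-way ANOVA for binned r_sc and the
#' MI curve) for every ordered group pair, with a `direction` column
#' giving the sign of the median (or mean) contrast. When `config$out` is
#' set, all tables are written as TSV together with a JSON run manifest
#' and a data dictionary.
#'
#' @param config a [run_config()].
#' @return list of class `pn_run`: `units`, `pairs`, `mi_curves`,
#'   `mua` (per animal), `binned`, `comparisons`, `manifest`.
#' @export
run_full <- function(config = run_config()) {
  recs_by_group <- group_recordings(config)
  units <- pairs <- mi_curves <- mua <- NULL
  exclusions <- list()
  for (gname in names(recs_by_group)) {
    recs <- recs_by_group[[gname]]
    for (ai in seq_along(recs)) {
      res <- tryCatch(
        analyze_recording(recs[[ai]], config,
                          mi_seed = config$seed * 1000 + ai + 7919),
        error = function(e) stop("stage 'analyze' failed for group ", gname,
                                 " animal ", ai, ": ", conditionMessage(e)))
      res$units$group <- gname; res$units$animal <- ai
      res$pairs$group <- gname; res$pairs$animal <- ai
      mi_df <- data.frame(group = gname, animal = ai,
                          size = res$mi$population_sizes,
                          mi_mean_bits = res$mi$mi_mean_bits,
                          mi_sem_bits = res$mi$mi_sem_bits)
      units <- rbind(units, res$units)
      pairs <- rbind(pairs, res$pairs)
      mi_curves <- rbind(mi_curves, mi_df)
      mua <- rbind(mua, data.frame(group = gname, animal = ai,
                                   mua_ff = res$mua_ff))
      exclusions[[paste(gname, ai)]] <- res$n_excluded_gof
    }
    message(sprintf("[%s] %d animals, %d units, %d pairs, %d units excluded by GoF filter",
                    gname, length(recs), sum(units$group == gname),
                    sum(pairs$group == gname),
                    sum(unlist(exclusions[grep(paste0("^", gname, " "),
                                               names(exclusions))]))))
  }
  gnames <- names(recs_by_group)
  unit_metric_cols <- c(spont_rate = "spont_rate", peak_rate = "peak_rate",
                        osi = "osi_selected", snr = "snr_auc", ff = "ff")
  pair_metric_cols <- c(rsc = "rsc_evoked", cov = "covariance",
                        decorrelation = "decorrelation")
  comparisons <- NULL
  cmp_row <- function(metric, ga, gb, res, direction) {
    data.frame(metric = metric, group_a = ga, group_b = gb, test = res$test,
               statistic = res$statistic, p_value = res$p_value,
               effect = res$effect_size, effect_label = res$effect_label,
               n_a = res$n_a, n_b = res$n_b, direction = direction,
               stringsAsFactors = FALSE)
  }
  dir_label <- function(ga, gb, da, db) {
    if (is.na(da) || is.na(db) || da == db) paste0(ga, "=", gb)
    else if (da > db) paste0(ga, ">", gb)
    else paste0(ga, "<", gb)
  }
  if (length(gnames) >= 2) {
    for (i in seq_len(length(gnames) - 1)) for (j in (i + 1):length(gnames)) {
      ga <- gnames[i]; gb <- gnames[j]
      for (k in seq_along(unit_metric_cols)) {
        xa <- units[units$group == ga, unit_metric_cols[k]]
        xb <- units[units$group == gb, unit_metric_cols[k]]
        xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
        if (length(xa) < 2 || length(xb) < 2) next
        res <- compare_groups(xa, xb)
        comparisons <- rbind(comparisons, cmp_row(
          names(unit_metric_cols)[k], ga, gb, res,
          dir_label(ga, gb, stats::median(xa), stats::median(xb))))
      }
      for (k in seq_along(pair_metric_cols)) {
        xa <- pairs[pairs$group == ga, pair_metric_cols[k]]
        xb <- pairs[pairs$group == gb, pair_metric_cols[k]]
        xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
        if (length(xa) < 2 || length(xb) < 2) next
        res <- compare_groups(xa, xb)
        comparisons <- rbind(comparisons, cmp_row(
          names(pair_metric_cols)[k], ga, gb, res,
          dir_label(ga, gb, stats::median(xa), stats::median(xb))))
      }
      xa <- mua$mua_ff[mua$group == ga]; xb <- mua$mua_ff[mua$group == gb]
      if (length(xa) >= 2 && length(xb) >= 2) {
        res <- compare_groups(xa, xb)
        comparisons <- rbind(comparisons, cmp_row(
          "mua_ff", ga, gb, res,
          dir_label(ga, gb, stats::median(xa), stats::median(xb))))
      }
      sel <- mi_curves$group %in% c(ga, gb)
      if (sum(sel) >= 4 && length(unique(mi_curves$size[sel])) >= 2) {
        res <- anova2(mi_curves$mi_mean_bits[sel], mi_curves$group[sel],
                      mi_curves$size[sel])
        ma <- mean(mi_curves$mi_mean_bits[mi_curves$group == ga])
        mb <- mean(mi_curves$mi_mean_bits[mi_curves$group == gb])
        comparisons <- rbind(comparisons,
                             cmp_row("mi", ga, gb, res,
                                     dir_label(ga, gb, ma, mb)))
      }
    }
  }
  binned <- NULL
  for (gname in gnames) {
    gp <- pairs[pairs$group == gname, ]
    for (key in c("rate", "distance", "dpo")) {
      br <- bin_relation(gp, key)
      binned <- rbind(binned, data.frame(
        group = gname, key = key,
        bin_max = br$bin_edges[-1],
        mean_rsc = br$bin_means, sem_rsc = br$bin_sems, n = br$bin_ns))
    }
  }
  manifest <- list(seed = config$seed, groups = gnames,
                   n_animals = config$n_animals, sweeps = config$sweeps,
                   gof_threshold = config$gof_threshold,
                   roc_bin_s = config$roc_bin_s,
                   rate_split = config$rate_split,
                   mi_sizes = config$mi_sizes, mi_bins = config$mi_bins,
                   mi_subsets = config$mi_subsets,
                   gof_exclusions = exclusions,
                   timestamp = "deterministic")
  out <- structure(list(units = units, pairs = pairs, mi_curves = mi_curves,
                        mua = mua, binned = binned,
                        comparisons = comparisons, manifest = manifest),
                   class = "pn_run")
  if (!is.null(config$out)) write_run(out, config$out)
  out
}

#' Write pipeline report tables
#'
#' @param run a `pn_run` from [run_full()].
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(units = run$units, mi_curves = run$mi_curves,
               mua = run$mua, binned = run$binned,
               comparisons = run$comparisons)
  tabs$pairs <- run$pairs
  for (nm in names(tabs))
    write_tsv(tabs[[nm]], file.path(path, paste0(nm, ".tsv")))
  jsonlite::write_json(run$manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  dict <- data.frame(
    table = c("units", "units", "units", "units", "units", "units", "units",
              "pairs", "pairs", "pairs", "pairs", "pairs", "pairs",
              "mi_curves", "mua", "binned", "comparisons"),
    column = c("spont_rate", "peak_rate", "snr_auc", "ff", "gof",
               "osi_selected", "class",
               "distance_um", "delta_po_deg", "rsc_evoked", "rsc_spont",
               "covariance", "decorrelation",
               "mi_mean_bits", "mua_ff", "mean_rsc", "direction"),
    description = c(
      "blank-trial firing rate, spikes/s",
      "firing rate at the raw-argmax optimal condition, spikes/s",
      "ROC AUC, evoked (optimal condition) vs spontaneous bins",
      "single-unit Fano factor, averaged over grating conditions",
      "tuning-fit coefficient of determination (R^2)",
      "OSI fraction; NA unless gof strictly above the threshold",
      "waveform class, FS or RS",
      "absolute probe-depth difference, um",
      "preferred-orientation difference, deg (NA if a fit fails the filter)",
      "noise correlation pooled over grating conditions",
      "noise correlation from blank trials",
      "raw-count covariance pooled over grating conditions (signal+noise)",
      "min(0, rsc_evoked - rsc_spont), FS-RS pairs only (NA reason: pair type)",
      "Panzeri-Treves corrected MI, bits, mean over unit subsets",
      "multi-unit-activity Fano factor per animal",
      "mean evoked r_sc per covariate bin (NA reason: empty bin)",
      "sign of the group contrast on the tested metric"))
  write_tsv(dict, file.path(path, "data_dictionary.tsv"))
  invisible(path)
}
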