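entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Plugin (direct) mutual information between stimulus and response
#'
#' Empirical mutual information in bits between a discrete stimulus label
#' and a discrete response symbol: `MI(S;R) = H(R) - H(R|S)` with
#' `H(R) = -sum_r P(r) log2 P(r)` and
#' `H(R|S) = -sum_s P(s) sum_r P(r|s) log2 P(r|s)`, all probabilities
#' empirical, `0 * log 0 := 0`. The plugin estimator is upward biased at
#' limited trial counts; see [pt_corrected_mi()].
#'
#' @param stimuli vector of stimulus labels, one per trial.
#' @param responses vector of discrete response symbols, same length.
#' @return list of class `pn_mi`: `mi_bits`, `h_response_bits`,
#'   `h_noise_bits`, `correction`, `n_trials`, `n_stimuli`,
#'   `n_response_bins`.
#' @export
plugin_mi <- function(stimuli, responses) {
  if (length(stimuli) == 0) stop("empty input")
  if (length(stimuli) != length(responses))
    stop("stimuli and responses must have equal length")
  s <- as.character(stimuli)
  r <- as.character(responses)
  n <- length(s)
  tab <- table(s, r)
  ps <- rowSums(tab) / n
  pr <- colSums(tab) / n
  hr <- entropy_bits(pr)
  hrs <- sum(vapply(seq_along(ps), function(i) {
    prs <- tab[i, ] / sum(tab[i, ])
    ps[i] * entropy_bits(prs)
  }, numeric(1)))
  structure(list(mi_bits = hr - hrs, h_response_bits = hr,
                 h_noise_bits = hrs, correction = "none",
                 n_trials = n, n_stimuli = length(ps),
                 n_response_bins = length(pr)),
            class = "pn_mi")
}

# Bayesian-style estimate of the number of effectively occupied response
# bins: solve r_obs = R * (1 - (1 - 1/R)^n) for R >= r_obs. Falls back to
# the naive count when every observation is distinct.
estimate_occupied_bins <- function(r_obs, n) {
  if (r_obs <= 1 || r_obs >= n) return(r_obs)
  f <- function(R) R * (1 - (1 - 1 / R)^n) - r_obs
  upper <- r_obs
  while (f(upper) < 0 && upper < 1e8) upper <- upper * 2
  if (f(upper) < 0) return(r_obs)
  stats::uniroot(f, c(r_obs, upper), tol = 1e-9)$root
}

#' Panzeri-Treves bias-corrected mutual information
#'
#' Subtracts the analytic limited-sampling bias from the plugin estimate:
#' `bias = [sum_s (R~_s - 1) - (R~ - 1)] / (2 N ln 2)` bits, where `R~_s`
#' and `R~` estimate the number of effectively occupied response bins
#' within stimulus `s` and overall. The default uses naive occupancy
#' counts; `occupancy = "bayes"` instead solves the expected-occupancy
#' relation for the underlying bin count. The corrected value can be
#' slightly negative.
#'
#' @inheritParams plugin_mi
#' @param occupancy `"naive"` or `"bayes"`.
#' @return `pn_mi` with `correction = "panzeri_treves"` and extra fields
#'   `mi_plugin_bits`, `bias_bits`.
#' @export
pt_corrected_mi <- function(stimuli, responses,
                            occupancy = c("naive", "bayes")) {
  occupancy <- match.arg(occupancy)
  est <- plugin_mi(stimuli, responses)
  s <- as.character(stimuli)
  r <- as.character(responses)
  n <- length(s)
  occ <- function(x, ns) {
    k <- length(unique(x))
    if (occupancy == "bayes") estimate_occupied_bins(k, ns) else k
  }
  r_all <- occ(r, n)
  r_s <- vapply(split(r, s), function(x) occ(x, length(x)), numeric(1))
  bias <- (sum(r_s - 1) - (r_all - 1)) / (2 * n * log(2))
  est$mi_plugin_bits <- est$mi_bits
  est$bias_bits <- bias
  est$mi_bits <- est$mi_bits - bias
  est$correction <- "panzeri_treves"
  est
}

#' Quantise multi-unit count responses into discrete population symbols
#'
#' Per unit, trials are assigned to approximately equipopulated bins
#' (quantile edges over all trials); the population response symbol is the
#' tuple of per-unit bin indices. Units with fewer distinct values than
#' bins get merged (degenerate) edges; the achieved bin count is reported.
#'
#' @param counts numeric matrix `trials x units` (a vector is treated as
#'   one unit).
#' @param n_bins target bins per unit (>= 2).
#' @return character vector of population symbols with attribute
#'   `n_bins_actual` (per-unit achieved bin counts).
#' @export
quantize_responses <- function(counts, n_bins = 2) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1)
  bins <- matrix(1L, nrow = nrow(counts), ncol = ncol(counts))
  actual <- integer(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    x <- counts[, j]
    edges <- unique(stats::quantile(x, probs = seq(0, 1,
                                                   length.out = n_bins + 1),
                                    names = FALSE, type = 7))
    inner <- edges[-c(1, length(edges))]
    bins[, j] <- findInterval(x, inner, left.open = TRUE) + 1L
    actual[j] <- length(unique(bins[, j]))
  }
  sym <- apply(bins, 1, paste, collapse = "|")
  attr(sym, "n_bins_actual") <- actual
  sym
}

#' Mutual information as a function of population size
#'
#' For each population size `m`, draws `n_subsets` seeded random subsets of
#' units, quantises their joint responses ([quantize_responses()]) and
#' estimates the bias-corrected MI between trial stimulus labels and the
#' population symbol; reports mean and SEM per size. By default blank
#' trials enter as an additional stimulus.
#'
#' @param rec a [pn_recording()].
#' @param sizes population sizes (each <= number of units).
#' @param n_subsets random subsets per size.
#' @param n_bins quantisation bins per unit.
#' @param seed RNG seed for subset draws.
#' @param include_blank treat blank trials as a stimulus.
#' @param correction `"panzeri_treves"` or `"none"`.
#' @return list of class `pn_mi_curve`: `population_sizes`,
#'   `mi_mean_bits`, `mi_sem_bits`, `n_subsets`, `seed`.
#' @export
mi_vs_population_size <- function(rec, sizes = 1:5, n_subsets = 10,
                                  n_bins = 2, seed = 1,
                                  include_blank = TRUE,
                                  correction = c("panzeri_treves", "none")) {
  correction <- match.arg(correction)
  if (length(sizes) == 0) stop("sizes must be non-empty")
  if (max(sizes) > n_units(rec))
    stop("requested population size exceeds the number of units")
  conds <- condition_labels(rec$protocol, blank = include_blank)
  n_tr <- length(conds) * rec$protocol$n_sweeps
  if (n_bins^max(sizes) > n_tr / 2)
    warning("response-symbol space (", n_bins^max(sizes),
            ") is large relative to ", n_tr,
            " trials; estimates will be noisy even after correction")
  stim <- rep(conds, times = rec$protocol$n_sweeps)
  cmat <- sapply(rec$units$unit_id, function(u) {
    as.numeric(unit_counts(rec, u)[conds, ])  # (condition, sweep) order
  })
  est_one <- function(cols) {
    sym <- quantize_responses(cmat[, cols, drop = FALSE], n_bins)
    if (correction == "panzeri_treves") pt_corrected_mi(stim, sym)$mi_bits
    else plugin_mi(stim, sym)$mi_bits
  }
  mi_mean <- mi_sem <- numeric(length(sizes))
  with_seed(seed, {
    for (i in seq_along(sizes)) {
      m <- sizes[i]
      vals <- vapply(seq_len(n_subsets), function(k)
        est_one(sample.int(ncol(cmat), m)), numeric(1))
      mi_mean[i] <- mean(vals)
      mi_sem[i] <- if (n_subsets > 1) stats::sd(vals) / sqrt(n_subsets)
      else NA_real_
    }
  })
  structure(list(population_sizes = sizes, mi_mean_bits = mi_mean,
                 mi_sem_bits = mi_sem, n_subsets = n_subsets, seed = seed),
            class = "pn_mi_curve")
}

# Evaluate expr with a temporary RNG seed, restoring global state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
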