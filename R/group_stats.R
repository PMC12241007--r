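#' Three-sigma outlier exclusion
#'
#' Single (non-iterated) pass: values outside `mean +/- 3 * SD` (SD with
#' n-1) are dropped. With zero SD nothing is removed. Applied per metric
#' per group before testing.
#'
#' @param values numeric vector (length >= 2).
#' @return the retained values.
#' @export
exclude_outliers_3sigma <- function(values) {
  if (length(values) < 2) stop("need >= 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) return(values)
  values[values >= m - 3 * s & values <= m + 3 * s]
}

#' Mann-Whitney U test with exact small-sample enumeration
#'
#' Two-sided rank-sum test. For `max(n, m) <= 8` the exact permutation
#' null of the U statistic is enumerated over all arrangements of the
#' pooled values (handling ties without approximation); otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. Cliff's delta is attached as the effect size and descriptives are
#' the group medians and interquartile ranges.
#'
#' @param x,y numeric samples (non-empty).
#' @return list of class `pn_comparison`: `test`, `statistic` (U of `x`),
#'   `p_value`, `effect_size`, `effect_label = "cliffs_delta"`, `n_a`,
#'   `n_b`, `descriptives` (median and IQR per group), `method`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  n <- length(x); m <- length(y)
  u_stat <- function(xi, yi) {
    r <- rank(c(xi, yi))
    sum(r[seq_along(xi)]) - length(xi) * (length(xi) + 1) / 2
  }
  u <- u_stat(x, y)
  if (max(n, m) <= 8) {
    pooled <- c(x, y)
    combs <- utils::combn(n + m, n)
    us <- apply(combs, 2, function(ix)
      u_stat(pooled[ix], pooled[-ix]))
    mu <- n * m / 2
    # two-sided: arrangements at least as extreme (distance from the mean)
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    r <- rank(c(x, y))
    nties <- table(r)
    mu <- n * m / 2
    sigma2 <- (n * m / 12) *
      ((n + m + 1) - sum(nties^3 - nties) / ((n + m) * (n + m - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal approximation with tie correction"
  }
  structure(list(test = "mann_whitney", statistic = u, p_value = p,
                 effect_size = cliffs_delta(x, y),
                 effect_label = "cliffs_delta",
                 n_a = n, n_b = m,
                 descriptives = data.frame(
                   group = c("a", "b"),
                   median = c(stats::median(x), stats::median(y)),
                   iqr = c(stats::IQR(x), stats::IQR(y))),
                 method = method),
            class = "pn_comparison")
}

#' Cliff's delta effect size
#'
#' `(#\{x_i > y_j\} - #\{x_i < y_j\}) / (n m)`: the difference between the
#' probabilities that a value from `x` exceeds one from `y` and vice
#' versa. Equals `2 * AUC - 1` of the corresponding ROC comparison.
#'
#' @param x,y numeric samples (non-empty).
#' @return value in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  d <- outer(x, y, `-`)
  (sum(d > 0) - sum(d < 0)) / (length(x) * length(y))
}

#' Cohen's d effect size
#'
#' Standardised mean difference `(mean_x - mean_y) / s_pooled` with the
#' usual (n-1)-weighted pooled standard deviation.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return Cohen's d.
#' @export
cohens_d <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) stop("Cohen's d undefined: zero pooled standard deviation")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Additive two-way ANOVA (group + bin)
#'
#' Tests a group main effect while controlling for a binning factor (e.g.
#' firing-rate bin, distance bin, population size), the design used for
#' binned noise-correlation and MI-curve comparisons. The model is
#' additive (no interaction unless `interaction = TRUE`); sums of squares
#' are Type II, appropriate for unbalanced cells. Reports the group
#' main-effect F with `(1, residual df)` (or the group df when the group
#' factor has more than two levels).
#'
#' @param values numeric response.
#' @param factor_group grouping factor (>= 2 levels).
#' @param factor_bin binning factor (>= 2 levels).
#' @param interaction include a group:bin interaction term.
#' @return `pn_comparison` with `test = "anova2"`, `statistic` (F),
#'   `p_value`, `df` (numerator, denominator), `effect_size` (Cohen's d of
#'   the two groups when applicable) and mean/SEM descriptives.
#' @export
anova2 <- function(values, factor_group, factor_bin, interaction = FALSE) {
  g <- factor(factor_group)
  b <- factor(factor_bin)
  if (nlevels(g) < 2 || nlevels(b) < 2)
    stop("each factor needs >= 2 levels")
  df <- data.frame(y = as.numeric(values), g = g, b = b)
  full <- if (interaction) stats::lm(y ~ g + b + g:b, data = df)
  else stats::lm(y ~ g + b, data = df)
  nogroup <- if (interaction) stats::lm(y ~ b + g:b, data = df)
  else stats::lm(y ~ b, data = df)
  rss_full <- sum(stats::residuals(full)^2)
  rss_ng <- sum(stats::residuals(nogroup)^2)
  df_g <- nlevels(g) - 1
  df_res <- full$df.residual
  if (rss_full <= 1e-12 * max(1, rss_ng)) {
    f_stat <- Inf
    p <- 0
    degenerate <- TRUE
  } else {
    f_stat <- ((rss_ng - rss_full) / df_g) / (rss_full / df_res)
    p <- stats::pf(f_stat, df_g, df_res, lower.tail = FALSE)
    degenerate <- FALSE
  }
  eff <- if (nlevels(g) == 2) {
    sp <- split(df$y, df$g)
    tryCatch(cohens_d(sp[[1]], sp[[2]]), error = function(e) NA_real_)
  } else NA_real_
  desc <- do.call(rbind, lapply(split(df$y, df$g), function(v)
    data.frame(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
               n = length(v))))
  desc$group <- rownames(desc)
  structure(list(test = "anova2", statistic = f_stat, p_value = p,
                 df = c(df_g, df_res), degenerate = degenerate,
                 effect_size = eff, effect_label = "cohens_d",
                 n_a = sum(g == levels(g)[1]), n_b = sum(g == levels(g)[2]),
                 descriptives = desc),
            class = "pn_comparison")
}

#' @export
print.pn_comparison <- function(x, ...) {
  cat(sprintf("<pn_comparison> %s: statistic = %.4g, p = %.4g, %s = %.4g (n = %d, %d)\n",
              x$test, x$statistic, x$p_value, x$effect_label %||% "effect",
              x$effect_size, x$n_a, x$n_b))
  invisible(x)
}

#' Compare a metric between two groups
#'
#' Applies per-group 3-sigma outlier exclusion, then a two-sided
#' Mann-Whitney U test with Cliff's delta. Optionally returns
#' Benjamini-Hochberg adjusted p-values when used over several metrics via
#' [stats::p.adjust()] downstream (no correction by default).
#'
#' @param x,y numeric metric values for the two groups.
#' @param exclude_outliers apply [exclude_outliers_3sigma()] per group.
#' @return `pn_comparison`.
#' @export
compare_groups <- function(x, y, exclude_outliers = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (exclude_outliers) {
    if (length(x) >= 2) x <- exclude_outliers_3sigma(x)
    if (length(y) >= 2) y <- exclude_outliers_3sigma(y)
  }
  mann_whitney(x, y)
}
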