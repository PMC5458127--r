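#' Category discriminability (one-way ANOVA F) per feature unit
#'
#' For every unit, the ratio of between-category to within-category mean
#' squares of the feature values — an index of how well a unit separates
#' object categories. Units with zero within-category variance but positive
#' between-category variance are flagged `+Inf`; units with all values
#' identical get F = 0.
#'
#' @param features A [feature_table()] with >= 2 categories and >= 2 items
#'   in at least one category.
#' @return Named numeric vector of F statistics (may contain `Inf`).
#' @export
unit_f_statistic <- function(features) {
  stopifnot(inherits(features, "feature_table"))
  g <- factor(features$items$category_label)
  k <- nlevels(g)
  n <- nrow(features$values)
  if (k < 2) stop("need at least 2 categories")
  if (n - k < 1) stop("need at least 2 items in one category")
  v <- features$values
  gm <- rowsum(v, g) / as.vector(table(g))       # category means, k x units
  grand <- colMeans(v)
  cnt <- as.vector(table(g))
  ssb <- colSums(cnt * (gm - rep(grand, each = k))^2)
  ssw <- colSums((v - gm[g, , drop = FALSE])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- ifelse(msw > 0, msb / msw,
              ifelse(msb > 0, Inf, 0))
  # all values identical: ssb == ssw == 0 -> 0 (handled above); exact zeros
  stats::setNames(f, features$unit_ids)
}

#' Correlation between unit decodability and category discriminability
#'
#' Pearson correlation across feature units between per-unit decoding
#' accuracy and the per-unit category-discriminability F statistic
#' (log10-transformed by default, since F spans orders of magnitude).
#' Non-finite or undefined entries on either side are excluded and counted.
#'
#' @param unit_r Named/numeric vector of per-unit decoding accuracies.
#' @param unit_f Numeric vector of per-unit F statistics.
#' @param log10_f Correlate against `log10(F)` (default `TRUE`); both
#'   variants are available.
#' @return List with `r`, `n_used`, `n_excluded`.
#' @export
decodability_vs_discriminability <- function(unit_r, unit_f,
                                             log10_f = TRUE) {
  if (length(unit_r) != length(unit_f))
    stop("unit_r and unit_f must have equal length")
  f <- if (log10_f) log10(unit_f) else unit_f
  ok <- is.finite(unit_r) & is.finite(f)
  if (sum(ok) < 3) stop("fewer than 3 valid unit pairs")
  list(r = stats::cor(unit_r[ok], f[ok]),
       n_used = sum(ok), n_excluded = sum(!ok))
}

#' Fisher z-transform of correlation coefficients
#'
#' `atanh(r)` after clipping to within +/- (1 - 1e-12), so that perfect
#' correlations (which do occur on noiseless synthetic data) stay finite.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @return Numeric vector of z values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("correlations must lie in [-1, 1]")
  atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
}

#' One-sample one-sided t-test against a chance level
#'
#' Convenience wrapper around [stats::t.test()] used for testing mean
#' correlations (after [fisher_z()]) or identification accuracies against
#' their chance level. A Shapiro-Wilk normality check is attached as a
#' diagnostic (not a gate).
#'
#' @param values Numeric vector (>= 2 values with nonzero variance).
#' @param chance Chance level (0 for correlations, 50 for two-way accuracy).
#' @param side `"greater"` (default) or `"less"`.
#' @param normality_check Attach the Shapiro-Wilk diagnostic (default
#'   `TRUE`; disable in tight simulation loops).
#' @return List with `t`, `p`, `df`, `mean`, and `shapiro_p` (NA when the
#'   check is disabled or the sample is too small or degenerate).
#' @export
ttest_vs_chance <- function(values, chance = 0, side = c("greater", "less"),
                            normality_check = TRUE) {
  side <- match.arg(side)
  if (length(values) < 2 || stats::sd(values) == 0) {
    if (length(values) >= 2 && all(values == chance))
      return(list(t = 0, p = 0.5, df = length(values) - 1,
                  mean = chance, shapiro_p = NA_real_))
    stop("need >= 2 values with nonzero variance")
  }
  tt <- stats::t.test(values, mu = chance, alternative = side)
  sw <- if (normality_check && length(values) >= 3 && stats::sd(values) > 0)
    tryCatch(stats::shapiro.test(values)$p.value, error = function(e) NA_real_)
  else NA_real_
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean = mean(values), shapiro_p = sw)
}
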