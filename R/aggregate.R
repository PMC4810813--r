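#' Richness-weighted mean of per-stage values
#'
#' Weighted mean `sum(w * x) / sum(w)` with weights normally the estimated
#' per-stage richness, used to condense per-stage sampling rates or
#' probabilities into a whole-era figure. Pairs with missing values are
#' dropped; all-zero (or empty) weights are an error.
#'
#' @param values,weights Equal-length numeric vectors; `weights >= 0`.
#' @return A single number, inside `[min(values), max(values)]`.
#' @examples
#' richness_weighted_mean(c(0.2, 0.6), c(1, 3))  # 0.5
#' @export
richness_weighted_mean <- function(values, weights) {
  stopifnot(length(values) == length(weights))
  keep <- !is.na(values) & !is.na(weights)
  values <- values[keep]
  weights <- weights[keep]
  if (any(weights < 0)) abort("weights must be >= 0")
  if (length(weights) == 0 || sum(weights) == 0) {
    abort("weights are empty or all zero")
  }
  sum(weights * values) / sum(weights)
}

#' Era-total richness from mean sampling probability
#'
#' Binomial maximum-likelihood estimate of the number of taxa that lived
#' over a whole era, from the count of unique observed taxa and the
#' era-mean sampling probability with its confidence bounds (reusing the
#' per-stage richness machinery, including the interval construction).
#'
#' @param total_observed Unique taxa observed across the era.
#' @param p,p_lo,p_hi Era-mean sampling probability and its bounds.
#' @param conf Confidence level for the profile interval.
#' @param ci Interval construction, see [richness_interval()].
#' @return A one-row tibble: `total_observed`, `total_richness`, `n_lo`,
#'   `n_hi`.
#' @examples
#' era_total_richness(1124, 0.580, 0.474, 0.706)
#' @export
era_total_richness <- function(total_observed, p, p_lo, p_hi, conf = 0.95,
                               ci = c("profile", "plugin")) {
  ci <- match.arg(ci)
  est <- richness_mle(total_observed, p)
  iv <- richness_interval(total_observed, p_lo, p_hi, conf = conf,
                          method = ci)
  tibble::tibble(
    total_observed = as.integer(total_observed),
    total_richness = est, n_lo = iv$n_lo, n_hi = iv$n_hi
  )
}

#' Whole-era summary of a per-stage fit
#'
#' Condenses a `trips_fit` into era-level figures: mean sampling rate and
#' mean sampling probability weighted by estimated per-stage richness
#' (interval bounds weighted likewise), and the era-total richness from
#' the mean probability and the count of unique observed taxa.
#' Non-estimable stages carry no weight and are listed in a message.
#'
#' @param fit A `trips_fit`.
#' @param total_observed Unique taxa observed across the era (not
#'   derivable from the fit, which only has per-stage counts).
#' @inheritParams era_total_richness
#' @return A one-row tibble with `mean_rate`, `mean_rate_lo`,
#'   `mean_rate_hi`, `mean_p`, `mean_p_lo`, `mean_p_hi`,
#'   `total_observed`, `total_richness`, `total_lo`, `total_hi`.
#' @export
era_summary <- function(fit, total_observed, conf = 0.95,
                        ci = c("profile", "plugin")) {
  ci <- match.arg(ci)
  df <- tibble::as_tibble(fit)
  est <- df[df$estimable & !is.na(df$n_true), , drop = FALSE]
  skipped <- setdiff(df$stage, est$stage)
  if (length(skipped) > 0) {
    inform(paste0("stages without estimates carry no weight: ",
                  paste(skipped, collapse = ", ")))
  }
  w <- est$n_true
  tot <- era_total_richness(
    total_observed,
    richness_weighted_mean(est$p, w),
    richness_weighted_mean(est$p_lo, w),
    richness_weighted_mean(est$p_hi, w),
    conf = conf, ci = ci
  )
  tibble::tibble(
    mean_rate = richness_weighted_mean(est$lambda, w),
    mean_rate_lo = richness_weighted_mean(est$lambda_lo, w),
    mean_rate_hi = richness_weighted_mean(est$lambda_hi, w),
    mean_p = richness_weighted_mean(est$p, w),
    mean_p_lo = richness_weighted_mean(est$p_lo, w),
    mean_p_hi = richness_weighted_mean(est$p_hi, w),
    total_observed = tot$total_observed,
    total_richness = tot$total_richness,
    total_lo = tot$n_lo,
    total_hi = tot$n_hi
  )
}

#' Correlation of sampling probabilities with a detrended sampling proxy
#'
#' Diagnostic against collection-count proxies (e.g. dinosaur-bearing
#' collections): regresses `log10(counts)` on stage order by ordinary
#' least squares, takes the residuals as the detrended proxy, and returns
#' the Pearson correlation of the per-stage sampling probabilities with
#' those residuals together with its two-sided p-value. Detrending on rank
#' order makes the result invariant to rescaling all counts by a constant.
#'
#' @param probabilities Per-stage sampling probabilities (time-ordered).
#' @param collections Per-stage positive collection counts, same order.
#' @param index Detrending covariate; defaults to rank order
#'   `seq_along(collections)`, stage midpoint ages being the alternative.
#' @return A one-row tibble `r`, `p_value`, `n`, with the detrended series
#'   in `attr(, "detrended")`.
#' @export
detrended_correlation <- function(probabilities, collections,
                                  index = seq_along(collections)) {
  if (length(probabilities) != length(collections)) {
    abort("probabilities and collections must have equal length")
  }
  if (length(collections) < 3) abort("need at least 3 stages")
  if (any(collections <= 0)) abort("collection counts must be > 0")
  res <- residuals(lm(log10(collections) ~ index))
  if (stats::sd(res) < 1e-12 || stats::sd(probabilities) < 1e-12) {
    abort("correlation undefined: a series has zero variance after detrending")
  }
  ct <- cor.test(probabilities, res)
  out <- tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                        n = length(res))
  attr(out, "detrended") <- as.numeric(res)
  out
}
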