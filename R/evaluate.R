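#' Run the simulation study of estimator performance
#'
#' Draws `n_sims` parameter sets from `space`, simulates a clade for each,
#' runs the estimator on the sampled fossil counts (treating the whole
#' simulated window as one interval), and records truth against estimates.
#' Fully reproducible: simulation *i* uses a child seed derived from
#' `seed` and *i* only.
#'
#' A simulation with no sampled lineage cannot be analysed and is flagged
#' `sampled = FALSE`; one whose observed lineages are all singletons has a
#' rate MLE of exactly 0 and is flagged `estimable = FALSE`. Headline
#' success rates use all sampled simulations as denominator, counting
#' inestimable ones as failures; estimable-only rates are reported
#' alongside (see [glance.trips_study()]).
#'
#' @param n_sims Number of simulations (>= 1).
#' @param space A [param_space()]; defaults to the study ranges.
#' @param seed Master seed.
#' @param conf Confidence level for all intervals.
#' @return A `trips_study` tibble: one row per simulation with the drawn
#'   parameters, `true_richness`, `n_obs`, the rate and richness estimates
#'   with intervals, and logical `sampled`, `estimable`,
#'   `covered_richness`, `covered_lambda` (coverage of the true richness
#'   and of the true clade-mean sampling rate).
#' @export
run_study <- function(n_sims, space = param_space(), seed = NULL,
                      conf = 0.95) {
  stopifnot(n_sims >= 1)
  seed <- seed %||% sample.int(2^31 - 2, 1)
  pars <- draw_params(space, n = n_sims, seed = child_seed(seed, 0))
  res <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    pp <- lapply(pars, `[[`, i)
    cl <- simulate_clade(pp, seed = child_seed(seed, i))
    est <- trips_stage(sim_counts(cl), d = pp$duration, conf = conf)
    res[[i]] <- tibble::tibble(
      sim = i,
      true_richness = cl$true_richness,
      n_obs = est$n_obs,
      sampled = est$n_obs > 0,
      estimable = est$estimable,
      lambda = est$lambda, lambda_lo = est$lambda_lo,
      lambda_hi = est$lambda_hi,
      p_binom = est$p, p_lo = est$p_lo, p_hi = est$p_hi,
      n_true = est$n_true, n_lo = est$n_lo, n_hi = est$n_hi,
      covered_richness = est$estimable &&
        !is.na(est$n_lo) && est$n_lo <= cl$true_richness &&
        cl$true_richness <= est$n_hi,
      covered_lambda = est$estimable &&
        est$lambda_lo <= pp$mean_sampling &&
        pp$mean_sampling <= est$lambda_hi
    )
  }
  out <- dplyr::bind_cols(pars, dplyr::bind_rows(res))
  structure(out, conf = conf, seed = seed,
            class = c("trips_study", class(tibble::tibble())))
}

#' Mean scaled error of richness estimates
#'
#' Signed relative bias: the mean over simulations of
#' `(estimate - truth) / truth`. Negative values mean the estimator runs
#' low on average. Pairs with zero truth are excluded with a warning.
#'
#' @param estimates,truths Equal-length numeric vectors.
#' @return A single number.
#' @examples
#' mean_scaled_error(c(110), c(100))  # 0.10
#' @export
mean_scaled_error <- function(estimates, truths) {
  stopifnot(length(estimates) == length(truths))
  bad <- truths == 0
  if (any(bad)) {
    warn(paste0(sum(bad), " pair(s) with zero truth excluded"))
    estimates <- estimates[!bad]
    truths <- truths[!bad]
  }
  mean((estimates - truths) / truths)
}

#' Fraction of simulations whose interval covers the truth
#'
#' @param flags Logical vector, `TRUE` when the truth fell inside the
#'   estimated confidence interval.
#' @return Fraction in `[0, 1]`.
#' @export
coverage <- function(flags) {
  stopifnot(length(flags) > 0)
  mean(flags)
}

#' Summary metrics of a simulation study
#'
#' One-row tibble with the headline metrics: `success_rate_richness` and
#' `success_rate_lambda` (coverage over all sampled simulations, counting
#' inestimable ones as failures), their estimable-only counterparts,
#' `mean_scaled_error` (signed, over estimable simulations) and
#' `pearson_rho` between true and estimated richness (estimable
#' simulations). `n_sims`, `n_sampled`, `n_estimable` give the
#' denominators.
#'
#' @param x A `trips_study`.
#' @param ... Unused.
#' @method glance trips_study
#' @export
glance.trips_study <- function(x, ...) {
  smp <- x[x$sampled, , drop = FALSE]
  est <- x[x$estimable, , drop = FALSE]
  tibble::tibble(
    n_sims = nrow(x),
    n_sampled = nrow(smp),
    n_estimable = nrow(est),
    success_rate_richness = coverage(smp$covered_richness),
    success_rate_lambda = coverage(smp$covered_lambda),
    success_rate_richness_estimable = coverage(est$covered_richness),
    success_rate_lambda_estimable = coverage(est$covered_lambda),
    mean_scaled_error = mean_scaled_error(est$n_true, est$true_richness),
    pearson_rho = stats::cor(est$true_richness, est$n_true)
  )
}

#' @method tidy trips_study
#' @export
tidy.trips_study <- function(x, ...) tibble::as_tibble(x)

#' @method print trips_study
#' @export
print.trips_study <- function(x, ...) {
  cat("<trips_study> ", nrow(x), " birth-death-fossilize simulations\n",
      sep = "")
  NextMethod()
}

#' Success rate binned over duration and sampling rate
#'
#' Mean richness-interval coverage per (duration x mean sampling rate)
#' cell, for mapping where the estimator works: short intervals and low
#' sampling rates leave less room for within-interval turnover and so give
#' higher coverage. Inestimable simulations count as failures; unsampled
#' ones are excluded. Empty cells carry `NA` and `n = 0`.
#'
#' @param study A `trips_study`.
#' @param duration_breaks,rate_breaks Bin edges passed to [cut()]; defaults
#'   give 6 x 6 cells over the default space.
#' @return A tibble with `duration_bin`, `rate_bin`, `n`, `success_rate`.
#' @export
success_surface <- function(study, duration_breaks = seq(2, 20, length.out = 7),
                            rate_breaks = seq(0, 1.5, length.out = 7)) {
  smp <- tibble::as_tibble(study)
  smp <- smp[smp$sampled, , drop = FALSE]
  smp$duration_bin <- cut(smp$duration, duration_breaks, include.lowest = TRUE)
  smp$rate_bin <- cut(smp$mean_sampling, rate_breaks, include.lowest = TRUE)
  out <- smp |>
    dplyr::group_by(.data$duration_bin, .data$rate_bin, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      success_rate = if (dplyr::n() > 0) mean(.data$covered_richness) else NA_real_,
      .groups = "drop"
    )
  out$success_rate[out$n == 0] <- NA_real_
  out
}

#' @rdname success_surface
#' @param object A `trips_study`.
#' @param ... Passed to `success_surface()`.
#' @method autoplot trips_study
#' @export
autoplot.trips_study <- function(object, ...) {
  surf <- success_surface(object, ...)
  ggplot2::ggplot(surf, ggplot2::aes(x = .data$duration_bin,
                                     y = .data$rate_bin,
                                     fill = .data$success_rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 na.value = "grey80", limits = c(0, 1)) +
    ggplot2::labs(x = "interval duration (Myr)",
                  y = "mean sampling rate (obs / lineage / Myr)",
                  fill = "success\nrate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
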