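#' Estimate sampling and richness for every stage of a timescale
#'
#' Runs the full estimator on a long-form observation count matrix (one row
#' per taxon per stage, as produced by [count_matrix()]): per stage, the
#' zero-truncated Poisson sampling-rate MLE with profile-likelihood
#' interval, the binomial sampling probability, and the binomial
#' maximum-likelihood true richness with confidence interval. Stages with
#' no observations appear as zero rows; stages whose observed taxa are all
#' singletons are flagged not estimable.
#'
#' @param counts Tibble with columns `taxon`, `stage`, `n` (positive
#'   counts).
#' @param ts Timescale tibble (provides stage order and durations).
#' @param conf Confidence level (default 0.95).
#' @param ci Richness-interval construction, see [richness_interval()].
#' @return A `trips_fit` tibble: one row per stage (old to young) with the
#'   columns of [trips_stage()].
#' @examples
#' ts <- mesozoic_timescale()
#' counts <- tibble::tibble(
#'   taxon = c("A", "B", "C"), stage = "Maastrichtian", n = c(2, 3, 1)
#' )
#' trips(counts, ts)
#' @export
trips <- function(counts, ts, conf = 0.95, ci = c("profile", "plugin")) {
  ci <- match.arg(ci)
  unknown <- setdiff(unique(counts$stage), ts$stage)
  if (length(unknown) > 0) {
    abort(paste0("counts contain stage(s) not in the timescale: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  rows <- purrr::map2_dfr(ts$stage, ts$duration, function(s, d) {
    trips_stage(counts$n[counts$stage == s], d, stage = s, conf = conf,
                ci = ci)
  })
  new_trips_fit(rows, conf = conf, ci = ci)
}

new_trips_fit <- function(x, conf, ci, replicates = NULL) {
  structure(
    x,
    conf = conf, ci = ci, replicates = replicates,
    class = c("trips_fit", class(tibble::tibble()))
  )
}

#' Estimate from replicated count matrices
#'
#' Probabilistic stage assignment makes each count matrix a random draw, so
#' the estimator is run on every replicate and the per-stage sampling-rate
#' estimates are combined as medians across replicates (point estimate and
#' both interval bounds), as is the observed richness (rounded half up).
#' Sampling probabilities and richness are then derived from those medians,
#' keeping the chain self-consistent. Per-replicate fits are retained in
#' `attr(, "replicates")`.
#'
#' @param counts Tibble with columns `replicate`, `taxon`, `stage`, `n`,
#'   as from [replicate_count_matrices()].
#' @inheritParams trips
#' @return A `trips_fit` tibble, one row per stage.
#' @export
trips_replicated <- function(counts, ts, conf = 0.95,
                             ci = c("profile", "plugin")) {
  ci <- match.arg(ci)
  stopifnot("replicate" %in% names(counts))
  reps <- purrr::map_dfr(sort(unique(counts$replicate)), function(r) {
    fit <- trips(counts[counts$replicate == r, , drop = FALSE], ts,
                 conf = conf, ci = ci)
    dplyr::mutate(tibble::as_tibble(fit), replicate = r, .before = 1L)
  })
  med <- reps |>
    dplyr::group_by(.data$stage, .data$d) |>
    dplyr::summarise(
      n_obs = floor(median(.data$n_obs) + 0.5),
      lambda = median(.data$lambda, na.rm = TRUE),
      lambda_lo = median(.data$lambda_lo, na.rm = TRUE),
      lambda_hi = median(.data$lambda_hi, na.rm = TRUE),
      .groups = "drop"
    )
  rows <- purrr::pmap_dfr(med, function(stage, d, n_obs, lambda, lambda_lo,
                                        lambda_hi) {
    if (n_obs == 0 || is.na(lambda)) {
      return(trips_stage(integer(0), d, stage = stage, conf = conf, ci = ci))
    }
    pv <- sampling_probability(c(lambda, lambda_lo, lambda_hi), d)
    estimable <- lambda > 0
    if (estimable && pv[2] > 0) {
      n_true <- richness_mle(n_obs, pv[1])
      iv <- richness_interval(n_obs, pv[2], pv[3], conf = conf, method = ci)
    } else {
      n_true <- NA_integer_
      iv <- list(n_lo = NA_integer_, n_hi = NA_integer_)
    }
    tibble::tibble(
      stage = stage, d = d, n_obs = as.integer(n_obs),
      lambda = lambda, lambda_lo = lambda_lo, lambda_hi = lambda_hi,
      p = pv[1], p_lo = pv[2], p_hi = pv[3],
      n_true = n_true, n_lo = iv$n_lo, n_hi = iv$n_hi,
      estimable = estimable
    )
  })
  rows <- rows[match(ts$stage, rows$stage), , drop = FALSE]
  new_trips_fit(rows, conf = conf, ci = ci, replicates = reps)
}

#' @method tidy trips_fit
#' @export
tidy.trips_fit <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance trips_fit
#' @export
glance.trips_fit <- function(x, ...) {
  est <- x[x$estimable, , drop = FALSE]
  tibble::tibble(
    n_stages = nrow(x),
    n_estimable = nrow(est),
    total_observed_rows = sum(x$n_obs),
    total_estimated = sum(est$n_true),
    conf = attr(x, "conf")
  )
}

#' @method print trips_fit
#' @export
print.trips_fit <- function(x, ...) {
  cat("<trips_fit> per-stage sampling and richness estimates (conf = ",
      attr(x, "conf"), ", ci = ", attr(x, "ci"), ")\n", sep = "")
  NextMethod()
}

#' Plot per-stage richness or sampling estimates
#'
#' `autoplot()` on a `trips_fit` draws the estimates against stage midpoint
#' age (time flowing left to right toward the present), with a ribbon for
#' the confidence interval. `what = "richness"` shows observed and
#' estimated true richness; `"rate"` the sampling rate; `"probability"`
#' the binomial sampling probability.
#'
#' @param object A `trips_fit`.
#' @param ts Timescale tibble used for the fit (for stage midpoints); if
#'   `NULL`, stages are plotted in row order.
#' @param what One of `"richness"`, `"rate"`, `"probability"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trips_fit
#' @export
autoplot.trips_fit <- function(object, ts = NULL, what = c("richness", "rate",
                                                           "probability"),
                               ...) {
  what <- match.arg(what)
  df <- tibble::as_tibble(object)
  df$x <- if (!is.null(ts)) {
    -(ts$early[match(df$stage, ts$stage)] +
        ts$late[match(df$stage, ts$stage)]) / 2
  } else {
    seq_len(nrow(df))
  }
  xlab <- if (!is.null(ts)) "age (Ma, negated)" else "stage index"
  cols <- switch(what,
    richness = c("n_true", "n_lo", "n_hi"),
    rate = c("lambda", "lambda_lo", "lambda_hi"),
    probability = c("p", "p_lo", "p_hi")
  )
  ylab <- switch(what,
    richness = "richness (taxa)",
    rate = "sampling rate (obs / lineage / Myr)",
    probability = "sampling probability"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data[[cols[2]]], ymax = .data[[cols[3]]]),
      fill = "steelblue", alpha = 0.3, na.rm = TRUE
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[cols[1]]]), colour = "steelblue",
                       na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data[[cols[1]]]), colour = "steelblue",
                        na.rm = TRUE) +
    ggplot2::labs(x = xlab, y = ylab)
  if (what == "richness") {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$n_obs), shape = 1,
                                 na.rm = TRUE)
  }
  p
}

#' Write per-stage estimates to CSV (with a JSON mirror)
#'
#' @param x A `trips_fit`.
#' @param path Output CSV path; a `.json` mirror is written alongside.
#' @return `path`, invisibly.
#' @export
write_trips_fit <- function(x, path) {
  df <- tibble::as_tibble(x)
  readr::write_csv(df, path)
  jsonlite::write_json(df, sub("\\.csv$", ".json", path), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
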