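#' Geological timescales
#'
#' A timescale is a tibble of contiguous, non-overlapping geological stages
#' ordered from oldest to youngest, with one row per stage and columns
#' `stage` (name), `early` and `late` (interval boundaries in Ma before
#' present, `early > late`) and `duration` (Myr, `early - late`). Interval
#' durations enter the sampling model directly (the expected number of
#' fossil observations of a lineage in stage *t* is `lambda_t * duration_t`),
#' so a validated stage table is required before anything else.
#'
#' `read_timescale()` reads a CSV with columns `name,early_bound,late_bound`
#' (lines starting with `#` are ignored) and validates it.
#' `mesozoic_timescale()` returns the stage table shipped with the package
#' (Induan through Maastrichtian; see the file header in
#' `system.file("extdata", "mesozoic_stages.csv", package = "trips")` for
#' boundary sources).
#'
#' @param path Path to a timescale CSV with header `name,early_bound,late_bound`.
#' @param tol Numeric tolerance (Ma) for the contiguity check between
#'   adjacent stages.
#' @return A tibble with columns `stage`, `early`, `late`, `duration`,
#'   ordered old to young.
#' @examples
#' ts <- mesozoic_timescale()
#' ts[ts$stage == "Hettangian", ]   # 201.3-199.3 Ma, 2 Myr
#' @export
read_timescale <- function(path, tol = 1e-6) {
  if (!file.exists(path)) abort(paste0("timescale file not found: ", path))
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("name", "early_bound", "late_bound")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("timescale file lacks column(s): ", paste(miss, collapse = ", ")))
  }
  new_timescale(raw$name, raw$early_bound, raw$late_bound, tol = tol)
}

#' @rdname read_timescale
#' @export
mesozoic_timescale <- function() {
  read_timescale(system.file("extdata", "mesozoic_stages.csv",
                             package = "trips", mustWork = TRUE))
}

# Construct and validate a timescale tibble from parallel vectors.
new_timescale <- function(stage, early, late, tol = 1e-6) {
  ord <- order(early, decreasing = TRUE)
  ts <- tibble::tibble(
    stage = as.character(stage)[ord],
    early = as.numeric(early)[ord],
    late = as.numeric(late)[ord]
  )
  ts$duration <- ts$early - ts$late
  validate_timescale(ts, tol = tol)
  ts
}

#' Validate a timescale tibble
#'
#' Checks that every stage has positive duration and that adjacent stages
#' share a boundary (no gaps, no overlaps) within `tol`.
#'
#' @param ts A timescale tibble (`stage`, `early`, `late`, `duration`).
#' @inheritParams read_timescale
#' @return `ts`, invisibly, if valid; otherwise an error naming the
#'   offending stage or pair of stages.
#' @export
validate_timescale <- function(ts, tol = 1e-6) {
  need <- c("stage", "early", "late", "duration")
  miss <- setdiff(need, names(ts))
  if (length(miss) > 0) {
    abort(paste0("timescale lacks column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- which(ts$early - ts$late <= 0)
  if (length(bad) > 0) {
    abort(paste0("stage with non-positive duration: ", ts$stage[bad[1]]))
  }
  if (nrow(ts) > 1) {
    gap <- abs(ts$late[-nrow(ts)] - ts$early[-1])
    bad <- which(gap > tol)
    if (length(bad) > 0) {
      abort(paste0(
        "stages not contiguous: ", ts$stage[bad[1]], " (late ",
        ts$late[bad[1]], ") vs ", ts$stage[bad[1] + 1], " (early ",
        ts$early[bad[1] + 1], ")"
      ))
    }
  }
  invisible(ts)
}

#' Overlap of an age range with each stage
#'
#' Length (Myr) of the intersection of the closed age range `[late, early]`
#' with each stage of a timescale. This is the measure used to assign
#' occurrence records whose reported age range spans several stages: a stage
#' is drawn with probability proportional to its overlap with the range.
#'
#' @param early,late Age range bounds in Ma (`early >= late`). Vectorised:
#'   both may be vectors of the same length.
#' @param ts A timescale tibble.
#' @return A numeric matrix with one row per (early, late) pair and one
#'   column per stage, column names the stage names.
#' @examples
#' stage_overlap(200, 199, mesozoic_timescale())[, "Hettangian"]  # 0.7
#' @export
stage_overlap <- function(early, late, ts) {
  if (length(early) != length(late)) abort("early and late must have equal length")
  if (any(early < late)) abort("age range must have early >= late")
  ov <- outer(early, ts$early, pmin) - outer(late, ts$late, pmax)
  ov[ov < 0] <- 0
  colnames(ov) <- ts$stage
  ov
}
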