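#' Generate a synthetic occurrence table with known truth
#'
#' Builds a PaleoDB-style occurrence table by planting a known true
#' richness in each requested stage and sampling every planted taxon with
#' a Poisson number of observations (`Poisson(lambda * d)`); taxa drawing
#' zero observations are simply absent, exactly the censoring the
#' estimator models. Age ranges default to the stage bounds; a fraction of
#' records can be widened into a neighbouring stage to exercise the
#' probabilistic stage assignment.
#'
#' @param ts Timescale tibble.
#' @param richness Named integer vector: planted true richness per stage
#'   (names must be stages of `ts`).
#' @param lambda Sampling rate(s), observations per lineage per Myr;
#'   scalar or named like `richness`.
#' @param widen_frac Fraction of records whose age range is widened to
#'   also span an adjacent stage (default 0).
#' @param seed Optional seed.
#' @return An occurrence tibble as from [read_occurrences()] (columns
#'   `taxon`, `rank`, `genus`, `early`, `late`, `collection`), with the
#'   planted truth in `attr(, "true_richness")`.
#' @examples
#' ts <- mesozoic_timescale()
#' occ <- synthetic_occurrences(ts, c(Maastrichtian = 30), lambda = 0.5,
#'                              seed = 1)
#' @export
synthetic_occurrences <- function(ts, richness, lambda, widen_frac = 0,
                                  seed = NULL) {
  stopifnot(!is.null(names(richness)), all(names(richness) %in% ts$stage),
            widen_frac >= 0, widen_frac <= 1)
  if (is.null(names(lambda))) {
    lambda <- stats::setNames(rep_len(lambda, length(richness)),
                              names(richness))
  }
  with_seed_(seed, {
    rows <- purrr::map_dfr(names(richness), function(s) {
      k <- ts$stage == s
      d <- ts$duration[k]
      n_true <- richness[[s]]
      counts <- rpois(n_true, lambda[[s]] * d)
      obs <- which(counts > 0)
      if (length(obs) == 0) return(tibble::tibble())
      taxon <- sprintf("Synthetus %s_%03d", tolower(s), obs)
      tibble::tibble(
        taxon = rep(taxon, counts[obs]),
        rank = "species",
        genus = "Synthetus",
        early = ts$early[k],
        late = ts$late[k],
        collection = NA_character_,
        stage_planted = s
      )
    })
    if (nrow(rows) > 0 && widen_frac > 0) {
      widen <- runif(nrow(rows)) < widen_frac
      for (i in which(widen)) {
        k <- which(ts$stage == rows$stage_planted[i])
        if (runif(1) < 0.5 && k > 1) {
          rows$early[i] <- ts$early[k - 1]
        } else if (k < nrow(ts)) {
          rows$late[i] <- ts$late[k + 1]
        }
      }
    }
    out <- rows[setdiff(names(rows), "stage_planted")]
    attr(out, "true_richness") <- richness
    out
  })
}

#' Write an occurrence tibble as a PaleoDB-style CSV
#'
#' Columns are renamed to the PaleoDB download dialect (see
#' [paleodb_columns()]) so the file round-trips through
#' [read_occurrences()] with default settings.
#'
#' @param occ Occurrence tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  cols <- paleodb_columns()
  df <- tibble::tibble(occ[[ "taxon" ]], occ[["rank"]], occ[["early"]],
                       occ[["late"]], occ[["collection"]])
  names(df) <- cols[c("taxon", "rank", "early", "late", "collection")]
  readr::write_csv(df, path)
  invisible(path)
}
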