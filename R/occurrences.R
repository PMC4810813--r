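#' Read a fossil occurrence table
#'
#' Reads a Paleobiology-Database-style occurrence download: one row per
#' fossil occurrence with a taxon name, the rank the name was matched at,
#' the early/late bounds of the reported age range (Ma), and a collection
#' identifier. Column names are configurable through `cols`; the defaults
#' match the PaleoDB download dialect. Unknown extra columns are ignored.
#'
#' Rows failing validation (empty taxon name, `late_age > early_age`,
#' non-numeric ages) are reported with their line numbers and rejected.
#'
#' @param path Path to an occurrence CSV.
#' @param cols Named character vector mapping the roles `taxon`, `rank`,
#'   `early`, `late`, `collection` to column names in the file; see
#'   [paleodb_columns()].
#' @return A tibble with columns `taxon`, `rank`, `genus`, `early`, `late`,
#'   `collection` (one row per occurrence). `genus` is the first word of the
#'   taxon name.
#' @export
read_occurrences <- function(path, cols = paleodb_columns()) {
  if (!file.exists(path)) abort(paste0("occurrence file not found: ", path))
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         guess_max = 1e5)
  need <- cols[c("taxon", "rank", "early", "late")]
  miss <- setdiff(unname(need), names(raw))
  if (length(miss) > 0) {
    abort(paste0("occurrence file lacks column(s): ", paste(miss, collapse = ", ")))
  }
  occ <- tibble::tibble(
    taxon = normalize_name(raw[[cols[["taxon"]]]]),
    rank = tolower(trimws(as.character(raw[[cols[["rank"]]]]))),
    early = as.numeric(raw[[cols[["early"]]]]),
    late = as.numeric(raw[[cols[["late"]]]]),
    collection = if (cols[["collection"]] %in% names(raw)) {
      as.character(raw[[cols[["collection"]]]])
    } else {
      NA_character_
    }
  )
  occ$genus <- vapply(strsplit(occ$taxon, " ", fixed = TRUE), `[[`, "", 1L)
  bad <- which(is.na(occ$early) | is.na(occ$late) | occ$late > occ$early |
                 occ$taxon == "")
  if (length(bad) > 0) {
    abort(paste0(
      "invalid occurrence row(s) at line(s): ",
      paste(head(bad + 1L, 20), collapse = ", "),
      " (empty taxon, non-numeric age, or late_age > early_age)"
    ))
  }
  occ[, c("taxon", "rank", "genus", "early", "late", "collection")]
}

#' @rdname read_occurrences
#' @export
paleodb_columns <- function() {
  c(taxon = "matched_name", rank = "matched_rank",
    early = "early_age", late = "late_age", collection = "cid")
}

# case/whitespace normalization used for all name matching
normalize_name <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  x
}

name_key <- function(x) tolower(normalize_name(x))

#' Exclusion lists for occurrence filtering
#'
#' Holds the sets of taxon names to drop before analysis: invalid names
#' (nomina dubia and nomina nuda), ichnotaxa (trace fossils) and ootaxa
#' (fossil eggs), plus genus names that are entirely ichnotaxic. Matching is
#' case- and whitespace-insensitive. `read_exclusion_list()` reads a
#' plain-text file with one name per line (blank lines and `#` comments
#' ignored).
#'
#' @param invalid_taxa,ichnotaxa,ootaxa Character vectors of taxon names.
#' @param ichno_genera Character vector of genus names.
#' @return An object of class `trips_exclusions`.
#' @export
exclusion_lists <- function(invalid_taxa = character(), ichnotaxa = character(),
                            ootaxa = character(), ichno_genera = character()) {
  structure(
    list(
      invalid_taxa = unique(name_key(invalid_taxa)),
      ichnotaxa = unique(name_key(ichnotaxa)),
      ootaxa = unique(name_key(ootaxa)),
      ichno_genera = unique(name_key(ichno_genera))
    ),
    class = "trips_exclusions"
  )
}

#' @rdname exclusion_lists
#' @param path Path to a plain-text list, one name per line.
#' @export
read_exclusion_list <- function(path) {
  if (!file.exists(path)) abort(paste0("exclusion list not found: ", path))
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

#' Filter occurrence records by rank and exclusion lists
#'
#' Keeps records whose matched rank equals `rank` and whose taxon does not
#' appear in any exclusion set (nor its genus in the ichno-genus set).
#' Record order is preserved; an empty result is allowed.
#'
#' @param occ Occurrence tibble from [read_occurrences()].
#' @param rank `"species"` or `"genus"`.
#' @param exclusions A [exclusion_lists()] object, or `NULL` for none.
#' @return The filtered occurrence tibble.
#' @export
filter_occurrences <- function(occ, rank = c("species", "genus"),
                               exclusions = NULL) {
  rank <- match.arg(rank)
  keep <- occ$rank == rank
  if (!is.null(exclusions)) {
    stopifnot(inherits(exclusions, "trips_exclusions"))
    key <- name_key(occ$taxon)
    gkey <- name_key(occ$genus)
    drop <- key %in% exclusions$invalid_taxa |
      key %in% exclusions$ichnotaxa |
      key %in% exclusions$ootaxa |
      gkey %in% exclusions$ichno_genera
    keep <- keep & !drop
  }
  occ[keep, , drop = FALSE]
}

#' Assign occurrence records to geological stages
#'
#' Each record is assigned one stage drawn with probability proportional to
#' the overlap (Myr) of the record's reported age range with each stage. A
#' record wholly inside one stage is assigned deterministically. A record
#' whose range is a single point on a shared stage boundary (zero overlap
#' with both neighbours) goes to the older stage. Records whose range lies
#' entirely outside the timescale are dropped with a warning.
#'
#' @param occ Occurrence tibble (needs `early` and `late` columns).
#' @param ts Timescale tibble.
#' @param seed Optional integer seed making the draw reproducible.
#' @return `occ` with an added `stage` column (records outside the
#'   timescale removed).
#' @export
assign_stages <- function(occ, ts, seed = NULL) {
  with_seed_(seed, {
    n <- nrow(occ)
    if (n == 0) {
      occ$stage <- character(0)
      return(occ)
    }
    ov <- stage_overlap(occ$early, occ$late, ts)
    tot <- rowSums(ov)
    idx <- integer(n)

    pos <- tot > 0
    if (any(pos)) {
      # inverse-CDF draw per row, vectorised across records
      cw <- ov[pos, , drop = FALSE]
      if (ncol(cw) == 1L) {
        idx[pos] <- 1L
      } else {
        cw <- t(apply(cw, 1L, cumsum))
        u <- runif(sum(pos)) * tot[pos]
        idx[pos] <- rowSums(cw < u) + 1L
      }
    }
    if (any(!pos)) {
      # zero overlap everywhere: either a point range on a boundary (assign
      # the older stage containing the point) or outside the timescale
      for (i in which(!pos)) {
        hit <- which(ts$late <= occ$late[i] & occ$early[i] <= ts$early)
        idx[i] <- if (length(hit) > 0) min(hit) else NA_integer_
      }
    }
    if (anyNA(idx)) {
      warn(paste0(sum(is.na(idx)),
                  " record(s) outside the timescale were dropped"))
    }
    occ$stage <- ts$stage[idx]
    occ[!is.na(idx), , drop = FALSE]
  })
}

#' Build an observation count matrix
#'
#' Tallies fossil observations per taxon per stage after one probabilistic
#' stage assignment, in long form: one row per (taxon, stage) with a
#' positive count `n`. Taxa with no assigned record never appear, so the
#' observed richness of stage *t* is the number of rows with `stage == t`.
#'
#' @inheritParams assign_stages
#' @return A tibble with columns `taxon`, `stage`, `n` (counts >= 1).
#' @examples
#' ts <- mesozoic_timescale()
#' occ <- tibble::tibble(
#'   taxon = c("A a", "A a", "B b"), rank = "species",
#'   genus = c("A", "A", "B"), early = 70, late = 68, collection = NA
#' )
#' count_matrix(occ, ts)
#' @export
count_matrix <- function(occ, ts, seed = NULL) {
  assigned <- assign_stages(occ, ts, seed = seed)
  out <- dplyr::count(assigned, .data$taxon, .data$stage, name = "n")
  tibble::as_tibble(out)
}

#' Replicated count matrices under repeated stage assignment
#'
#' Because multi-stage age ranges are assigned probabilistically, the count
#' matrix is itself a random draw. This repeats the assignment `n_reps`
#' times (default 100) under independent child seeds spawned from `seed`,
#' so replicate *r* is reproducible regardless of `n_reps`.
#'
#' @inheritParams assign_stages
#' @param n_reps Number of replicate assignments (>= 1).
#' @param seed Master seed.
#' @return A tibble with columns `replicate`, `taxon`, `stage`, `n`.
#' @export
replicate_count_matrices <- function(occ, ts, n_reps = 100, seed = NULL) {
  stopifnot(n_reps >= 1)
  seed <- seed %||% sample.int(2^31 - 2, 1)
  purrr::map_dfr(seq_len(n_reps), function(r) {
    m <- count_matrix(occ, ts, seed = child_seed(seed, r))
    dplyr::mutate(m, replicate = r, .before = 1L)
  })
}
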