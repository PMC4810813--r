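occ_csv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c("matched_name,matched_rank,early_age,late_age,cid", lines), f)
  f
}

test_that("occurrence files parse, ignore extras, and report bad rows", {
  f <- occ_csv(c("Tyrannosaurus rex,species,68,66,c1",
                 "Triceratops horridus,species,68,66,c1",
                 "Allosaurus,genus,155,150,c2"))
  occ <- read_occurrences(f)
  expect_equal(nrow(occ), 3)
  expect_equal(occ$genus, c("Tyrannosaurus", "Triceratops", "Allosaurus"))

  # extra unknown columns are ignored
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("matched_name,matched_rank,early_age,late_age,cid,phylum",
               "Tyrannosaurus rex,species,68,66,c1,Chordata"), f2)
  expect_equal(nrow(read_occurrences(f2)), 1)

  # missing required column
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("matched_name,early_age,late_age", "X y,68,66"), f3)
  expect_error(read_occurrences(f3), "lacks column")

  # row-level validation with line number
  f4 <- occ_csv(c("Good taxon,species,68,66,c1", "Bad taxon,species,66,68,c1"))
  expect_error(read_occurrences(f4), "line\\(s\\): 3")
})

test_that("rank and exclusion filtering keep the right records", {
  occ <- tibble::tibble(
    taxon = c("Aa bb", "Cc dd", "Ee ff", "Saurichnium tetractis", "Gg"),
    rank = c("species", "species", "species", "species", "genus"),
    genus = c("Aa", "Cc", "Ee", "Saurichnium", "Gg"),
    early = 70, late = 68, collection = NA_character_
  )
  expect_equal(nrow(filter_occurrences(occ, "species")), 4)
  expect_equal(nrow(filter_occurrences(occ, "genus")), 1)

  excl <- exclusion_lists(invalid_taxa = "cc DD",
                          ichno_genera = "Saurichnium")
  kept <- filter_occurrences(occ, "species", excl)
  expect_equal(kept$taxon, c("Aa bb", "Ee ff"))
  # order preserved, empty result allowed
  none <- exclusion_lists(invalid_taxa = c("aa bb", "cc dd", "ee ff"),
                          ichno_genera = "Saurichnium")
  expect_equal(nrow(filter_occurrences(occ, "species", none)), 0)
})

test_that("stage assignment is overlap-proportional", {
  ts <- toy_timescale()  # Old 10-8 (2 Myr), Young 8-2 (6 Myr)
  # deterministic containment
  one <- tibble::tibble(taxon = "X", early = 9.5, late = 8.5)
  expect_equal(assign_stages(one, ts, seed = 1)$stage, "Old")
  # record spanning both stages: overlaps 2 and 6 -> probabilities 1/4, 3/4
  n <- 1e5
  many <- tibble::tibble(taxon = "X", early = 10, late = 2)[rep(1, n), ]
  freq <- mean(assign_stages(many, ts, seed = 42)$stage == "Old")
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(freq - 0.25), 3 * se)
})

test_that("boundary-point records go to the older stage; outside records drop", {
  ts <- toy_timescale()
  pt <- tibble::tibble(taxon = "X", early = 8, late = 8)
  expect_equal(assign_stages(pt, ts, seed = 1)$stage, "Old")
  out <- tibble::tibble(taxon = c("X", "Y"), early = c(30, 9), late = c(25, 9))
  expect_warning(res <- assign_stages(out, ts, seed = 1), "outside the timescale")
  expect_equal(res$taxon, "Y")
})

test_that("count matrices conserve records and are seed-reproducible", {
  ts <- toy_timescale()
  occ <- tibble::tibble(
    taxon = rep(c("A a", "B b"), c(4, 3)),
    early = c(rep(9, 4), rep(10, 3)), late = c(rep(8.5, 4), rep(2, 3))
  )
  m1 <- count_matrix(occ, ts, seed = 5)
  expect_equal(sum(m1$n), nrow(occ))
  expect_identical(m1, count_matrix(occ, ts, seed = 5))
  # single-stage records: all four land in Old as one row
  expect_equal(m1$n[m1$taxon == "A a" & m1$stage == "Old"], 4)
  expect_equal(nrow(count_matrix(occ[0, ], ts, seed = 1)), 0)
})

test_that("replicates vary placement but never a taxon row sum", {
  ts <- toy_timescale()
  occ <- tibble::tibble(
    taxon = rep(c("A a", "B b"), each = 10),
    early = 10, late = 2
  )
  reps <- replicate_count_matrices(occ, ts, n_reps = 20, seed = 9)
  sums <- reps |>
    dplyr::group_by(replicate, taxon) |>
    dplyr::summarise(total = sum(n), .groups = "drop")
  expect_true(all(sums$total == 10))
  per_rep <- reps |>
    dplyr::group_by(replicate) |>
    dplyr::summarise(total = sum(n), .groups = "drop")
  expect_true(all(per_rep$total == nrow(occ)))
  # multi-stage ranges: different seeds give different matrices
  r1 <- replicate_count_matrices(occ, ts, n_reps = 1, seed = 1)
  r2 <- replicate_count_matrices(occ, ts, n_reps = 1, seed = 2)
  expect_false(identical(r1$n, r2$n) && identical(r1$stage, r2$stage))
  # no multi-stage ranges: all replicates identical
  occ1 <- tibble::tibble(taxon = "A a", early = 9.5, late = 8.5)[rep(1, 5), ]
  u <- replicate_count_matrices(occ1, ts, n_reps = 5, seed = 3) |>
    dplyr::distinct(taxon, stage, n)
  expect_equal(nrow(u), 1)
  # replicate r is reproducible independently of n_reps
  a <- replicate_count_matrices(occ, ts, n_reps = 3, seed = 7)
  b <- replicate_count_matrices(occ, ts, n_reps = 5, seed = 7)
  expect_identical(a, b[b$replicate <= 3, ])
})
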