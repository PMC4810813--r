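test_that("zero-truncated Poisson log-likelihood matches the conditional pmf", {
  # frozen from the dpois-based oracle: log[e^-1 / (1 - e^-1)] = -0.5413249
  expect_equal(ztpois_loglik(1, d = 1, lambda = 1), -0.54132485, tolerance = 1e-7)
  expect_equal(ztpois_loglik(1, d = 1, lambda = 1),
               oracle_ztp_loglik(1, 1, 1), tolerance = 1e-12)
  # additivity over lineages
  expect_equal(ztpois_loglik(c(2, 2), 1, 2), 2 * ztpois_loglik(2, 1, 2))
  # tails: huge rate kills the likelihood; lambda = 0 is the limit value
  expect_lt(ztpois_loglik(2, 1, 1e4), -9000)
  expect_identical(ztpois_loglik(c(1, 2), 1, 0), -Inf)
  expect_identical(ztpois_loglik(c(1, 1), 1, 0), 0)
  expect_error(ztpois_loglik(c(0, 1), 1, 1), ">= 1")
})

test_that("sampling-rate MLE solves the likelihood and scales with duration", {
  # all singletons: boundary MLE at exactly 0, flagged not estimable
  f <- fit_sampling_rate(c(1, 1, 1), d = 4)
  expect_identical(f$lambda, 0)
  expect_false(f$estimable)
  expect_gt(f$lambda_hi, 0)

  # frozen oracle values: mean 2 -> lambda d = 1.5936 (grid search)
  f <- fit_sampling_rate(c(1, 2, 3), d = 1)
  expect_equal(f$lambda, 1.59362, tolerance = 1e-4)
  expect_equal(f$lambda, oracle_lambda_grid(c(1, 2, 3), 1), tolerance = 1e-4)
  # same mean at d = 5 scales the rate down five-fold
  expect_equal(fit_sampling_rate(2, d = 5)$lambda, 1.59362 / 5, tolerance = 1e-4)
})

test_that("moment identity and profile-CI drop hold across random inputs", {
  set.seed(101)
  q <- qchisq(0.95, 1) / 2  # 1.9207 log-likelihood units
  for (i in 1:25) {
    counts <- sample(1:6, sample(2:10, 1), replace = TRUE)
    if (all(counts == 1)) counts[1] <- 2L
    d <- runif(1, 0.5, 20)
    f <- fit_sampling_rate(counts, d)
    x <- f$lambda * d
    expect_equal(x / (1 - exp(-x)), mean(counts), tolerance = 1e-7)
    expect_equal(ztpois_loglik(counts, d, f$lambda) -
                   ztpois_loglik(counts, d, f$lambda_lo), q, tolerance = 1e-4)
    expect_equal(ztpois_loglik(counts, d, f$lambda) -
                   ztpois_loglik(counts, d, f$lambda_hi), q, tolerance = 1e-4)
    expect_true(f$lambda_lo <= f$lambda && f$lambda <= f$lambda_hi)
  }
})

test_that("sampling probability is the Poisson detection probability", {
  expect_equal(sampling_probability(0, 5), 0)
  expect_equal(sampling_probability(log(2), 1), 0.5)
  expect_equal(sampling_probability(0.2, 5), 1 - exp(-1))
  expect_error(sampling_probability(-0.1, 1), ">= 0")
})

test_that("richness MLE is the exact integer binomial maximiser", {
  expect_identical(richness_mle(10, 1), 10L)
  expect_identical(richness_mle(10, 0.3), 33L)
  expect_identical(richness_mle(10, 0.3), oracle_richness_brute(10, 0.3))
  # tie at 19/20 broken to the larger
  expect_identical(richness_mle(10, 0.5), 20L)
  expect_identical(oracle_richness_brute(10, 0.5), 20L)
  expect_identical(richness_mle(0, 0.4), 0L)
  expect_error(richness_mle(10, 0), "p = 0")
  # monotone: non-increasing in p, non-decreasing in n_obs
  ps <- seq(0.05, 1, by = 0.05)
  est <- vapply(ps, function(p) richness_mle(37, p), 0L)
  expect_true(all(diff(est) <= 0))
  ns <- 1:40
  est <- vapply(ns, function(n) richness_mle(n, 0.37), 0L)
  expect_true(all(diff(est) >= 0))
})

test_that("richness intervals propagate the probability bounds", {
  expect_identical(richness_interval(10, 1, 1), list(n_lo = 10L, n_hi = 10L))
  expect_identical(richness_interval(0, 0.2, 0.8), list(n_lo = 0L, n_hi = 0L))
  # plug-in construction: MLE at each bound
  iv <- richness_interval(10, 0.2, 0.8, method = "plugin")
  expect_identical(iv, list(n_lo = 12L, n_hi = 50L))
  expect_identical(iv$n_hi, oracle_richness_brute(10, 0.2))
  expect_identical(iv$n_lo, oracle_richness_brute(10, 0.8))
  # profile construction contains the plug-in interval
  pr <- richness_interval(10, 0.2, 0.8, method = "profile")
  expect_lte(pr$n_lo, iv$n_lo)
  expect_gte(pr$n_hi, iv$n_hi)
  # profile bounds satisfy the likelihood-ratio cutoff at the p bounds
  q <- qchisq(0.95, 1) / 2
  expect_gte(dbinom(10, pr$n_hi, 0.2, log = TRUE),
             dbinom(10, 50, 0.2, log = TRUE) - q)
  expect_lt(dbinom(10, pr$n_hi + 1, 0.2, log = TRUE),
            dbinom(10, 50, 0.2, log = TRUE) - q)
  expect_error(richness_interval(10, 0, 0.5), "unbounded")
})

test_that("per-stage chain composes rate, probability and richness", {
  # all singletons: not estimable, no richness estimate
  row <- trips_stage(c(1, 1, 1), d = 3)
  expect_false(row$estimable)
  expect_true(is.na(row$n_true))

  # frozen oracle chain for counts [3,3,3], d = 2
  row <- trips_stage(c(3, 3, 3), d = 2)
  lam <- oracle_lambda_grid(c(3, 3, 3), 2)
  expect_equal(row$lambda, lam, tolerance = 1e-4)
  expect_equal(row$p, 1 - exp(-row$lambda * 2), tolerance = 1e-10)
  expect_identical(row$n_true, oracle_richness_brute(3, row$p))
  expect_true(row$n_lo <= row$n_true && row$n_true <= row$n_hi)

  # empty column: zero-observation record
  row <- trips_stage(integer(0), d = 2, stage = "Empty")
  expect_identical(row$n_obs, 0L)
  expect_false(row$estimable)
})

test_that("whole-timescale fit equals direct per-stage calls", {
  ts <- mesozoic_timescale()
  counts <- tibble::tibble(
    taxon = c("A", "B", "C", "D"),
    stage = c(rep("Maastrichtian", 3), "Campanian"),
    n = c(2, 3, 1, 4)
  )
  fit <- trips(counts, ts)
  expect_equal(nrow(fit), nrow(ts))
  direct <- trips_stage(c(2, 3, 1), d = 6.1, stage = "Maastrichtian")
  expect_equal(fit[fit$stage == "Maastrichtian", ]$lambda, direct$lambda)
  expect_equal(fit[fit$stage == "Maastrichtian", ]$n_true, direct$n_true)
  # Campanian: a lone taxon with 4 observations is estimable
  expect_true(fit[fit$stage == "Campanian", ]$estimable)
  expect_error(trips(dplyr::mutate(counts, stage = "Nowhere"), ts),
               "not in the timescale")
})

test_that("replicate aggregation medians the rate estimates", {
  ts <- toy_timescale()
  # identical replicates: medians equal the common single-replicate values
  counts1 <- tibble::tibble(taxon = c("A", "B"), stage = "Old", n = c(2, 4))
  reps <- dplyr::bind_rows(
    dplyr::mutate(counts1, replicate = 1),
    dplyr::mutate(counts1, replicate = 2),
    dplyr::mutate(counts1, replicate = 3)
  )
  fit <- trips_replicated(reps, ts)
  single <- trips(counts1, ts)
  expect_equal(fit$lambda, single$lambda)
  expect_equal(fit$n_true, single$n_true)

  # differing replicates: lambda is the median of per-replicate MLEs
  reps2 <- dplyr::bind_rows(
    tibble::tibble(replicate = 1, taxon = c("A", "B"), stage = "Old", n = c(1, 3)),
    tibble::tibble(replicate = 2, taxon = c("A", "B"), stage = "Old", n = c(2, 4)),
    tibble::tibble(replicate = 3, taxon = c("A", "B"), stage = "Old", n = c(5, 7))
  )
  fit2 <- trips_replicated(reps2, ts)
  lams <- vapply(list(c(1, 3), c(2, 4), c(5, 7)),
                 function(k) fit_sampling_rate(k, d = 2)$lambda, 0)
  expect_equal(fit2$lambda[fit2$stage == "Old"], median(lams))
  per_rep <- attr(fit2, "replicates")
  expect_equal(nrow(per_rep), 6)  # 3 replicates x 2 stages
})
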