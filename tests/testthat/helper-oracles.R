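# Independent oracles used to freeze expected values. They share no code
# with the estimator: likelihoods are built from dpois()/dbinom() and
# maximised by exhaustive search.

# log-likelihood of a sampling rate under the zero-truncated Poisson,
# straight from the conditional pmf P(O = k | O > 0)
oracle_ztp_loglik <- function(counts, d, lambda) {
  mu <- lambda * d
  sum(log(dpois(counts, mu) / (1 - dpois(0, mu))))
}

# grid-search maximiser of the truncated-Poisson likelihood: coarse pass
# then fine refinement around the coarse argmax (step 1e-5)
oracle_lambda_grid <- function(counts, d, lam_max = 20) {
  coarse <- seq(1e-3, lam_max, by = 1e-2)
  ll <- vapply(coarse, function(l) oracle_ztp_loglik(counts, d, l), 0)
  best <- coarse[which.max(ll)]
  fine <- seq(max(best - 0.02, 1e-6), best + 0.02, by = 1e-5)
  llf <- vapply(fine, function(l) oracle_ztp_loglik(counts, d, l), 0)
  fine[which.max(llf)]
}

# exhaustive binomial-likelihood search for the richness MLE; ties broken
# to the larger N
oracle_richness_brute <- function(n_obs, p, n_max = NULL) {
  if (n_obs == 0) return(0L)
  n_max <- n_max %||% max(1000L, ceiling(10 * n_obs / p))
  N <- n_obs:n_max
  ll <- dbinom(n_obs, N, p, log = TRUE)
  as.integer(max(N[ll >= max(ll) - 1e-10]))
}

# small two-stage timescale used in assignment tests
toy_timescale <- function() {
  trips:::new_timescale(c("Old", "Young"), early = c(10, 8), late = c(8, 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
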