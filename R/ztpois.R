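#' Zero-truncated Poisson log-likelihood of a sampling rate
#'
#' Fossil sampling within a stage is modelled as a homogeneous Poisson
#' process: a lineage extant through a stage of duration `d` leaves
#' `O ~ Poisson(lambda * d)` observations. Only lineages with at least one
#' observation enter the data, so the likelihood is conditioned on `O > 0`
#' (zero truncation). For observed counts `O_i >= 1` this returns
#' `sum_i [ O_i log(lambda d) - lambda d - log(O_i!) - log(1 - exp(-lambda d)) ]`.
#'
#' At `lambda = 0` the limit value is returned: `0` when every count is 1
#' (the supremum of the all-singleton likelihood) and `-Inf` otherwise.
#'
#' @param counts Integer vector of per-lineage observation counts, all >= 1.
#' @param d Interval duration in Myr (> 0).
#' @param lambda Sampling rate, observations per lineage per Myr (>= 0).
#' @return The log-likelihood (scalar).
#' @examples
#' ztpois_loglik(c(1, 2, 3), d = 1, lambda = 1.59)
#' @export
ztpois_loglik <- function(counts, d, lambda) {
  if (any(counts < 1)) abort("all counts must be >= 1 (zero-truncated model)")
  if (d <= 0) abort("duration d must be > 0")
  if (lambda < 0) abort("lambda must be >= 0")
  if (lambda == 0) {
    return(if (all(counts == 1)) 0 else -Inf)
  }
  mu <- lambda * d
  sum(counts * log(mu) - mu - lgamma(counts + 1) - log1p(-exp(-mu)))
}

#' Maximum-likelihood sampling rate with profile-likelihood interval
#'
#' Maximises the zero-truncated Poisson likelihood over the sampling rate
#' `lambda` for one stage. The maximiser solves the moment identity
#' `lambda*d / (1 - exp(-lambda*d)) = mean(counts)`, located by bracketed
#' root-finding (absolute tolerance 1e-8 on `lambda*d`). The confidence
#' interval is the profile-likelihood set
#' `{lambda : logL(lambda) >= logL(lambda_hat) - qchisq(conf, 1)/2}`,
#' with each endpoint found by bracketed root-finding.
#'
#' When every observed lineage is a singleton (all counts equal 1) the MLE
#' is exactly 0 and the stage is flagged not estimable: the data cannot
#' separate a low rate from high unseen richness. The upper confidence
#' bound is still reported (the lower is 0).
#'
#' @inheritParams ztpois_loglik
#' @param conf Confidence level for the profile interval (default 0.95).
#' @return A list with elements `lambda`, `lambda_lo`, `lambda_hi`,
#'   `n_obs`, `estimable`, `loglik`.
#' @examples
#' fit_sampling_rate(c(1, 2, 3), d = 1)$lambda  # ~1.594
#' fit_sampling_rate(c(1, 1, 1), d = 2)$lambda  # exactly 0
#' @export
fit_sampling_rate <- function(counts, d, conf = 0.95) {
  if (length(counts) == 0) abort("counts must be nonempty")
  if (any(counts < 1)) abort("all counts must be >= 1")
  if (d <= 0) abort("duration d must be > 0")
  n <- length(counts)
  m <- mean(counts)
  q <- qchisq(conf, df = 1) / 2

  if (m == 1) {
    # all singletons: MLE at the boundary, sup logL = 0
    f <- function(lam) ztpois_loglik(counts, d, lam) + q
    hi <- 1 / d
    while (f(hi) > 0) hi <- hi * 2
    lam_hi <- uniroot(f, c(1e-12, hi), tol = 1e-10)$root
    return(list(lambda = 0, lambda_lo = 0, lambda_hi = lam_hi,
                n_obs = n, estimable = FALSE, loglik = 0))
  }

  # moment equation x/(1-exp(-x)) = m for x = lambda*d; LHS increases from 1
  g <- function(x) x / (-expm1(-x)) - m
  x_hi <- max(m, 1)
  while (g(x_hi) < 0) x_hi <- x_hi * 2
  x <- uniroot(g, c(1e-12, x_hi), tol = 1e-12)$root
  lam <- x / d
  ll_max <- ztpois_loglik(counts, d, lam)
  f <- function(l) ztpois_loglik(counts, d, l) - (ll_max - q)

  lo_br <- lam / 2
  while (f(lo_br) > 0) lo_br <- lo_br / 2
  lam_lo <- uniroot(f, c(lo_br, lam), tol = 1e-10)$root
  hi_br <- lam * 2
  while (f(hi_br) > 0) hi_br <- hi_br * 2
  lam_hi <- uniroot(f, c(lam, hi_br), tol = 1e-10)$root

  list(lambda = lam, lambda_lo = lam_lo, lambda_hi = lam_hi,
       n_obs = n, estimable = TRUE, loglik = ll_max)
}

#' Binomial sampling probability of a lineage
#'
#' Probability that a lineage extant through a whole interval of duration
#' `d` is observed at least once under sampling rate `lambda`:
#' `1 - exp(-lambda * d)`. Unlike the rate, this probability is
#' stage-specific (it absorbs the interval duration), which is what makes
#' estimates comparable across stages of unequal length.
#'
#' @inheritParams ztpois_loglik
#' @return Probability in `[0, 1)`. Vectorised over `lambda`.
#' @examples
#' sampling_probability(log(2), 1)  # 0.5
#' @export
sampling_probability <- function(lambda, d) {
  if (any(lambda < 0)) abort("lambda must be >= 0")
  if (any(d <= 0)) abort("duration d must be > 0")
  -expm1(-lambda * d)
}

#' Maximum-likelihood true richness from observed richness
#'
#' Given `n_obs` taxa observed and detection probability `p` per extant
#' taxon, the true richness `N` maximising the binomial likelihood
#' `choose(N, n_obs) p^n_obs (1-p)^(N - n_obs)` is `floor(n_obs / p)`; when
#' `n_obs / p` is an integer the likelihood ties at `N - 1` and `N` and the
#' larger value (equal to the expectation `n_obs / p`) is returned. The
#' search is exact over integers (likelihood-ratio walk), not a continuous
#' approximation.
#'
#' @param n_obs Observed taxon count (>= 0).
#' @param p Detection probability in `(0, 1]`.
#' @return Integer richness estimate `>= n_obs`.
#' @examples
#' richness_mle(10, 0.3)  # 33
#' richness_mle(10, 0.5)  # 20 (tie with 19 broken upward)
#' @export
richness_mle <- function(n_obs, p) {
  stopifnot(length(n_obs) == 1, length(p) == 1)
  if (n_obs < 0) abort("n_obs must be >= 0")
  if (p <= 0) abort("richness is not estimable at p = 0")
  if (p > 1) abort("p must be <= 1")
  if (n_obs == 0) return(0L)
  if (p == 1) return(as.integer(n_obs))
  # L(N+1)/L(N) = (1-p)(N+1)/(N+1-n_obs); step up while the ratio >= 1
  cand <- max(n_obs, floor(n_obs / p) - 2)
  while ((1 - p) * (cand + 1) >= (cand + 1) - n_obs) cand <- cand + 1
  as.integer(cand)
}

# continuous log binomial likelihood in N (via log-gamma), for profile CIs
binom_loglik_n <- function(N, n_obs, p) {
  lgamma(N + 1) - lgamma(N - n_obs + 1) - lgamma(n_obs + 1) +
    n_obs * log(p) + (N - n_obs) * log1p(-p)
}

#' Confidence interval for true richness
#'
#' Propagates the uncertainty in the sampling probability into the richness
#' estimate. Two constructions are available:
#'
#' * `"profile"` (default): at each probability bound, take the
#'   chi-square(1) profile-likelihood interval of `N` under the binomial
#'   likelihood, and report the outer envelope — the smallest integer `N`
#'   satisfying the likelihood-ratio cutoff at `p_hi` (lower bound) and the
#'   largest at `p_lo` (upper bound). This combines the sampling-rate
#'   uncertainty with the binomial counting uncertainty at fixed `p`.
#' * `"plugin"`: simply `richness_mle(n_obs, p_hi)` and
#'   `richness_mle(n_obs, p_lo)`; rate uncertainty only.
#'
#' @param n_obs Observed taxon count (>= 0).
#' @param p_lo,p_hi Lower/upper confidence bounds on the sampling
#'   probability, `0 < p_lo <= p_hi <= 1`.
#' @param conf Confidence level of the profile cutoff (default 0.95).
#' @param method `"profile"` or `"plugin"`.
#' @return A list with integer elements `n_lo`, `n_hi`
#'   (`n_lo <= n_hi`, `n_lo >= n_obs` is not enforced for `n_lo` beyond the
#'   observed count floor; both are `>= 0`).
#' @examples
#' richness_interval(10, 0.2, 0.8, method = "plugin")  # 12, 50
#' @export
richness_interval <- function(n_obs, p_lo, p_hi, conf = 0.95,
                              method = c("profile", "plugin")) {
  method <- match.arg(method)
  if (n_obs < 0) abort("n_obs must be >= 0")
  if (p_lo <= 0) abort("upper richness bound is unbounded at p_lo = 0")
  if (p_lo > p_hi || p_hi > 1) abort("need 0 < p_lo <= p_hi <= 1")
  if (n_obs == 0) return(list(n_lo = 0L, n_hi = 0L))

  if (method == "plugin") {
    return(list(n_lo = richness_mle(n_obs, p_hi),
                n_hi = richness_mle(n_obs, p_lo)))
  }
  q <- qchisq(conf, df = 1) / 2

  # upper: largest integer N with logL(N; p_lo) >= max - q
  # (at p_lo = 1 the likelihood is zero except at N = n_obs)
  if (p_lo == 1) {
    n_hi <- as.integer(n_obs)
  } else {
    n_hat_lo <- richness_mle(n_obs, p_lo)
    cut <- binom_loglik_n(n_hat_lo, n_obs, p_lo) - q
    hi_br <- max(2 * n_hat_lo, n_obs + 10)
    while (binom_loglik_n(hi_br, n_obs, p_lo) > cut) hi_br <- hi_br * 2
    root <- uniroot(function(N) binom_loglik_n(N, n_obs, p_lo) - cut,
                    c(n_hat_lo, hi_br), tol = 1e-8)$root
    n_hi <- as.integer(floor(root + 1e-9))
  }

  # lower: smallest integer N with logL(N; p_hi) >= max - q (never < n_obs)
  if (p_hi == 1) {
    n_lo <- as.integer(n_obs)
  } else {
    n_hat_hi <- richness_mle(n_obs, p_hi)
    cut <- binom_loglik_n(n_hat_hi, n_obs, p_hi) - q
    if (binom_loglik_n(n_obs, n_obs, p_hi) >= cut) {
      n_lo <- as.integer(n_obs)
    } else {
      root <- uniroot(function(N) binom_loglik_n(N, n_obs, p_hi) - cut,
                      c(n_obs, n_hat_hi), tol = 1e-8)$root
      n_lo <- as.integer(ceiling(root - 1e-9))
    }
  }
  list(n_lo = n_lo, n_hi = n_hi)
}

#' TRiPS estimates for a single stage
#'
#' Chains the full estimator for one stage: sampling-rate MLE and profile
#' interval from the positive observation counts, transformation to a
#' binomial sampling probability, and binomial maximum-likelihood true
#' richness with its confidence interval. A stage whose counts are all
#' singletons is flagged not estimable (rate MLE 0) and gets no richness
#' estimate; an empty stage yields a zero-observation row.
#'
#' @param counts Positive observation counts for the stage (one per
#'   observed taxon); may be empty.
#' @param d Stage duration in Myr.
#' @param stage Optional stage label carried into the output.
#' @param conf Confidence level (default 0.95).
#' @param ci Richness-interval construction, see [richness_interval()].
#' @return A one-row tibble with columns `stage`, `d`, `n_obs`, `lambda`,
#'   `lambda_lo`, `lambda_hi`, `p`, `p_lo`, `p_hi`, `n_true`, `n_lo`,
#'   `n_hi`, `estimable`.
#' @examples
#' trips_stage(c(3, 3, 3), d = 2)
#' @export
trips_stage <- function(counts, d, stage = NA_character_, conf = 0.95,
                        ci = c("profile", "plugin")) {
  ci <- match.arg(ci)
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0) {
    return(tibble::tibble(
      stage = stage, d = d, n_obs = 0L,
      lambda = NA_real_, lambda_lo = NA_real_, lambda_hi = NA_real_,
      p = NA_real_, p_lo = NA_real_, p_hi = NA_real_,
      n_true = NA_integer_, n_lo = NA_integer_, n_hi = NA_integer_,
      estimable = FALSE
    ))
  }
  fit <- fit_sampling_rate(counts, d, conf = conf)
  pv <- sampling_probability(c(fit$lambda, fit$lambda_lo, fit$lambda_hi), d)
  if (fit$estimable) {
    n_true <- richness_mle(fit$n_obs, pv[1])
    iv <- richness_interval(fit$n_obs, pv[2], pv[3], conf = conf, method = ci)
  } else {
    n_true <- NA_integer_
    iv <- list(n_lo = NA_integer_, n_hi = NA_integer_)
  }
  tibble::tibble(
    stage = stage, d = d, n_obs = fit$n_obs,
    lambda = fit$lambda, lambda_lo = fit$lambda_lo, lambda_hi = fit$lambda_hi,
    p = pv[1], p_lo = pv[2], p_hi = pv[3],
    n_true = n_true, n_lo = iv$n_lo, n_hi = iv$n_hi,
    estimable = fit$estimable
  )
}
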