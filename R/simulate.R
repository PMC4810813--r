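#' Birth-death-fossilize simulation parameters
#'
#' Bundles the six parameters of the clade simulator: per-lineage
#' speciation and extinction rates (per species per time unit), the number
#' of species alive at time 0, the interval duration (time units, read as
#' Myr), the clade-mean fossil sampling rate (fossils per species per time
#' unit) and the half-width `sampling_var` of the relative spread of
#' per-lineage sampling rates: each lineage samples at
#' `mean_sampling * Uniform(1 - v, 1 + v)`, so `v = 0.3` spans 0.7 to 1.3
#' times the clade mean.
#'
#' @param speciation,extinction Rates per species per time unit (>= 0).
#' @param n0 Initial species count (>= 1).
#' @param duration Interval length in time units (> 0).
#' @param mean_sampling Clade-mean sampling rate (>= 0).
#' @param sampling_var Relative half-width `v` in `[0, 1)`.
#' @return A `sim_params` list.
#' @export
sim_params <- function(speciation, extinction, n0, duration, mean_sampling,
                       sampling_var = 0) {
  stopifnot(speciation >= 0, extinction >= 0, n0 >= 1, duration > 0,
            mean_sampling >= 0, sampling_var >= 0, sampling_var < 1)
  structure(
    list(speciation = speciation, extinction = extinction,
         n0 = as.integer(n0), duration = duration,
         mean_sampling = mean_sampling, sampling_var = sampling_var),
    class = "sim_params"
  )
}

#' Parameter space of the simulation study
#'
#' Default ranges for drawing simulation parameters: speciation and
#' extinction log-uniform on 0.001-0.15 per species per time unit, initial
#' species count integer-uniform on 10-250, duration uniform on 2-20 time
#' units (mimicking Mesozoic stage lengths, 2 Myr Hettangian to 19.5 Myr
#' Norian), mean sampling rate uniform on 0.001-1.5 fossils per species per
#' time unit, and the sampling-rate spread uniform on 0-0.3.
#'
#' @param speciation,extinction Length-2 numeric ranges (log-uniform draws).
#' @param n0 Length-2 integer range (uniform integer draws).
#' @param duration,mean_sampling,sampling_var Length-2 numeric ranges
#'   (uniform draws).
#' @return A `param_space` list of ranges.
#' @export
param_space <- function(speciation = c(0.001, 0.15),
                        extinction = c(0.001, 0.15),
                        n0 = c(10, 250),
                        duration = c(2, 20),
                        mean_sampling = c(0.001, 1.5),
                        sampling_var = c(0, 0.3)) {
  chk <- function(x) length(x) == 2 && x[1] <= x[2]
  stopifnot(chk(speciation), chk(extinction), chk(n0), chk(duration),
            chk(mean_sampling), chk(sampling_var))
  structure(
    list(speciation = speciation, extinction = extinction, n0 = n0,
         duration = duration, mean_sampling = mean_sampling,
         sampling_var = sampling_var),
    class = "param_space"
  )
}

#' Draw simulation parameters from a parameter space
#'
#' Independent draws per field: log-uniform for the speciation and
#' extinction rates, integer-uniform for `n0`, uniform otherwise.
#'
#' @param space A [param_space()].
#' @param n Number of parameter sets to draw.
#' @param seed Optional seed.
#' @return A tibble with one row per draw and one column per parameter.
#' @export
draw_params <- function(space, n = 1, seed = NULL) {
  stopifnot(inherits(space, "param_space"), n >= 1)
  with_seed_(seed, {
    logu <- function(r) {
      if (r[1] == r[2]) return(rep(r[1], n)) # degenerate (incl. exactly 0)
      10^runif(n, log10(r[1]), log10(r[2]))
    }
    tibble::tibble(
      speciation = logu(space$speciation),
      extinction = logu(space$extinction),
      n0 = sample.int(space$n0[2] - space$n0[1] + 1L, n, replace = TRUE) +
        space$n0[1] - 1L,
      duration = runif(n, space$duration[1], space$duration[2]),
      mean_sampling = runif(n, space$mean_sampling[1], space$mean_sampling[2]),
      sampling_var = runif(n, space$sampling_var[1], space$sampling_var[2])
    )
  })
}

#' Simulate one clade under the birth-death-fossilize process
#'
#' Exact stochastic simulation in continuous time: each extant lineage
#' independently speciates (rate `speciation`), goes extinct (rate
#' `extinction`) or leaves a fossil (its own rate
#' `mean_sampling * Uniform(1 - v, 1 + v)`) as competing exponential
#' events. Speciation follows the budding convention (the parent persists
#' and one daughter is founded); daughters draw a fresh sampling rate.
#' Fossilization does not affect demography, so lifespans are simulated
#' first and per-lineage fossil counts are then Poisson with mean
#' `rate * time alive within [0, duration]` — an exact shortcut for the
#' competing-events scheme.
#'
#' True richness is the number of distinct lineages alive at any time
#' within `[0, duration]` (every lineage ever created in the window, plus
#' the founders); the observed lineages (>= 1 fossil) are a subset.
#'
#' @param params A [sim_params()] list, or a one-row tibble/list with the
#'   same fields (as from [draw_params()]).
#' @param seed Optional seed.
#' @param max_lineages Guard against population explosion; exceeding it is
#'   an error flagged as truncation.
#' @return A `clade_sim` list: `lineages` tibble (`origin`, `death` —
#'   may exceed `duration` for survivors or be `Inf` when extinction is 0 —
#'   `span` alive within the window, `rate`, `fossils`), `true_richness`,
#'   `params`.
#' @examples
#' sim <- simulate_clade(sim_params(0, 0, 50, 5, 0.4), seed = 1)
#' sim$true_richness  # 50: no turnover
#' @export
simulate_clade <- function(params, seed = NULL, max_lineages = 1e5) {
  b <- params$speciation
  d <- params$extinction
  n0 <- params$n0
  T <- params$duration
  s <- params$mean_sampling
  v <- params$sampling_var
  stopifnot(b >= 0, d >= 0, n0 >= 1, T > 0, s >= 0, v >= 0, v < 1)

  with_seed_(seed, {
    origin <- numeric(0)
    death <- numeric(0)
    pending <- rep(0, n0)
    while (length(pending) > 0) {
      n <- length(pending)
      if (length(origin) + n > max_lineages) {
        abort("lineage cap exceeded; simulation truncated (raise max_lineages)")
      }
      life <- if (d > 0) rexp(n, d) else rep(Inf, n)
      dth <- pending + life
      span <- pmin(dth, T) - pending
      origin <- c(origin, pending)
      death <- c(death, dth)
      nb <- if (b > 0) rpois(n, b * span) else integer(n)
      tot <- sum(nb)
      pending <- if (tot > 0) {
        rep(pending, nb) + runif(tot) * rep(span, nb)
      } else {
        numeric(0)
      }
    }
    span <- pmin(death, T) - origin
    ntot <- length(origin)
    rate <- s * runif(ntot, 1 - v, 1 + v)
    fossils <- rpois(ntot, rate * span)
    structure(
      list(
        lineages = tibble::tibble(origin = origin, death = death,
                                  span = span, rate = rate,
                                  fossils = as.integer(fossils)),
        true_richness = ntot,
        params = params
      ),
      class = "clade_sim"
    )
  })
}

#' Observation counts of the sampled lineages
#'
#' Extracts the fossil counts of lineages observed at least once, as the
#' single-interval count column the estimator consumes. The sum equals the
#' total number of fossil events; unsampled lineages are absent.
#'
#' @param sim A `clade_sim` from [simulate_clade()].
#' @return Integer vector of positive counts (possibly empty).
#' @export
sim_counts <- function(sim) {
  stopifnot(inherits(sim, "clade_sim"))
  f <- sim$lineages$fossils
  f[f > 0]
}
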