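# Synthetic-data generators.
#
# Every generator is a deterministic function of (parameters, seed): the
# caller's RNG state is never consumed or disturbed. Noise is additive
# Gaussian with a user-set sigma (sigma = 0 gives the exact model values).

#' Simulate a light-response curve
#'
#' Evaluates [nrh_pn()] on a PPFD ladder and adds seeded Gaussian noise.
#' The default ladder is the standard 14-level measurement descent
#' ([ppfd_ladder()]).
#'
#' @param params A [light_params()] object.
#' @param ladder PPFD levels (umol m-2 s-1), in measurement order.
#' @param sigma Gaussian noise sd (umol CO2 m-2 s-1); 0 for noise-free.
#' @param seed Integer seed; identical seed gives identical output.
#' @param cultivar,stage,date Metadata carried on the curve.
#' @return A [gas_exchange_curve()] with PPFD driver.
#' @export
#' @examples
#' gen_light_curve(light_params(46.03, 0.09, 0.8, 2), sigma = 0.5, seed = 1)
gen_light_curve <- function(params, ladder = ppfd_ladder(), sigma = 0,
                            seed = NULL, cultivar = NA_character_,
                            stage = NA_character_, date = NA_character_) {
  params <- as_light_params(params)
  stopifnot(sigma >= 0)
  pn <- nrh_pn(ladder, params)
  if (sigma > 0)
    pn <- pn + with_seed(seed, stats::rnorm(length(ladder), 0, sigma))
  gas_exchange_curve(ladder, pn, kind = "PPFD", cultivar = cultivar,
                     stage = stage, date = date)
}

#' Simulate an A/Ci curve
#'
#' Evaluates [fvcb_pn()] on a CO2 ladder and adds seeded Gaussian noise. The
#' default ladder is the 13-level measurement sequence ([co2_ladder()]); the
#' chamber CO2 setpoints are used directly as Ci (real intercellular CO2 is
#' below ambient, but for synthesis the distinction is irrelevant).
#'
#' @param params An [fvcb_params()] object.
#' @param kinetics A [kinetic_constants()] object.
#' @param ladder Ci levels (umol mol-1), in measurement order.
#' @inheritParams gen_light_curve
#' @return A [gas_exchange_curve()] with Ci driver.
#' @export
gen_aci_curve <- function(params, kinetics = kinetic_constants(),
                          ladder = co2_ladder(), sigma = 0, seed = NULL,
                          cultivar = NA_character_, stage = NA_character_,
                          date = NA_character_) {
  params <- as_fvcb_params(params)
  stopifnot(sigma >= 0)
  pn <- fvcb_pn(ladder, params, kinetics)
  if (sigma > 0)
    pn <- pn + with_seed(seed, stats::rnorm(length(ladder), 0, sigma))
  gas_exchange_curve(ladder, pn, kind = "Ci", cultivar = cultivar,
                     stage = stage, date = date)
}

#' Simulate a closed-chamber CO2 log
#'
#' Generates a 1 Hz headspace CO2 series for one chamber under a cyclic
#' closure schedule. During each closure the mole fraction changes at
#' `d[CO2]/dt = -flux * ground_area / n_air` (the exact inverse of
#' [slope_to_flux()]); during open periods the series sits at `start_co2`
#' (instantaneous re-equilibration with ambient air - the flux estimator
#' never reads open periods, so mixing dynamics are not modelled).
#'
#' @param true_flux Canopy net CO2 uptake (umol m-2 s-1), either a constant
#'   or a function of time (s).
#' @param spec A [chamber_spec()].
#' @param schedule A [closure_schedule()].
#' @param start_co2 Ambient CO2 at closure onset (umol mol-1).
#' @param duration Series length (s); must cover at least one closure.
#' @param sigma Gaussian analyser noise sd (umol mol-1).
#' @param seed Integer seed.
#' @param cycle_start First closure time (s).
#' @param chamber_id Chamber identifier.
#' @return A [chamber_series()].
#' @export
#' @examples
#' s <- gen_chamber_series(30.15, duration = 600)
#' chamber_flux(s)$flux
gen_chamber_series <- function(true_flux, spec = chamber_spec(),
                               schedule = closure_schedule(),
                               start_co2 = 400, duration = 600, sigma = 0,
                               seed = NULL, cycle_start = 0,
                               chamber_id = "1") {
  stopifnot(duration >= schedule$closed_duration, sigma >= 0, start_co2 > 0)
  tt <- seq(0, duration - 1)
  flux_fn <- if (is.function(true_flux)) true_flux
             else function(t) rep(true_flux, length(t))
  n_air <- chamber_air_moles(spec)
  co2 <- rep(start_co2, length(tt))
  starts <- seq(cycle_start, max(tt), by = schedule$period)
  for (s in starts) {
    sel <- which(tt >= s & tt < s + schedule$closed_duration)
    if (!length(sel)) next
    rate <- -flux_fn(tt[sel]) * spec$ground_area / n_air
    # co2 at window start is start_co2; integrate the drawdown at 1 Hz
    co2[sel] <- start_co2 + c(0, cumsum(rate[-length(rate)]))
  }
  if (sigma > 0)
    co2 <- co2 + with_seed(seed, stats::rnorm(length(co2), 0, sigma))
  chamber_series(tt, co2, chamber_id = chamber_id)
}

#' Simulate a grain-filling trajectory
#'
#' Richards growth-curve weights sampled on a regular grid of days after
#' anthesis (default every 5 days), plus seeded Gaussian noise. Superior,
#' middle and inferior grain classes are emulated by calling this with three
#' parameter bundles (inferior grains: larger `b`, delayed onset).
#'
#' @param params A [richards_params()] object.
#' @param interval Sampling interval (days).
#' @param t_max Last sampling day; must be at least `3 * interval`.
#' @param sigma Gaussian noise sd (mg).
#' @param seed Integer seed.
#' @return A data frame with columns `t` (days) and `weight` (mg grain-1).
#' @export
gen_grain_filling <- function(params, interval = 5, t_max = 40, sigma = 0,
                              seed = NULL) {
  params <- as_richards_params(params)
  stopifnot(interval > 0, t_max >= 3 * interval, sigma >= 0)
  tt <- seq(0, t_max, by = interval)
  w <- richards_mass(tt, params)
  if (sigma > 0)
    w <- w + with_seed(seed, stats::rnorm(length(tt), 0, sigma))
  data.frame(t = tt, weight = w)
}

#' Simulate a replicated field-trial trait table
#'
#' Cell mean = base + cultivar effect (test cultivar only; the reference
#' level carries 0) + year effect + interaction, plus replicate-level
#' Gaussian noise; balanced by construction.
#'
#' @param trait Trait name.
#' @param base_mean Grand mean of the reference cultivar in the first year.
#' @param cultivar_effect Additive effect of the test cultivar (same units
#'   as the trait).
#' @param year_effects Named (or unnamed) numeric vector of additive year
#'   effects, one per year; names become the year labels.
#' @param interaction Optional matrix (2 x n_years: rows test/reference
#'   cultivar) of interaction effects; defaults to all zero.
#' @param n_reps Replicates per cell (>= 2).
#' @param sigma Replicate noise sd.
#' @param seed Integer seed.
#' @param cultivars Length-2 character vector: test then reference cultivar.
#' @param unit Unit string.
#' @return A [trait_table()].
#' @export
#' @examples
#' tab <- gen_trial_table("yield", 9.09, 0.73, c(`2013` = 0), n_reps = 3,
#'                        sigma = 0.2, seed = 1)
#' compare_cultivars(tab, "yield", "2013", "YLY1", "LYP9")
gen_trial_table <- function(trait, base_mean, cultivar_effect,
                            year_effects, interaction = NULL, n_reps = 3,
                            sigma = 0, seed = NULL,
                            cultivars = c("YLY1", "LYP9"),
                            unit = NA_character_) {
  stopifnot(n_reps >= 2, sigma >= 0, length(cultivars) == 2)
  ny <- length(year_effects)
  years <- names(year_effects)
  if (is.null(years)) years <- as.character(seq_len(ny))
  if (is.null(interaction)) interaction <- matrix(0, 2, ny)
  stopifnot(nrow(interaction) == 2, ncol(interaction) == ny)

  grid <- expand.grid(rep = seq_len(n_reps), cultivar = cultivars,
                      year = years, stringsAsFactors = FALSE)
  ci <- match(grid$cultivar, cultivars)
  yi <- match(grid$year, years)
  mu <- base_mean + ifelse(ci == 1, cultivar_effect, 0) +
    unname(year_effects)[yi] + interaction[cbind(ci, yi)]
  val <- if (sigma > 0)
    mu + with_seed(seed, stats::rnorm(nrow(grid), 0, sigma)) else mu
  trait_table(grid$cultivar, grid$year, grid$rep, trait, val, unit)
}
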