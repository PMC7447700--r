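#' Non-rectangular hyperbola light response
#'
#' Evaluates leaf net photosynthesis at a given photosynthetic photon flux
#' density (PPFD) under the non-rectangular hyperbola model
#' \deqn{P_n(I) = \frac{\alpha I + P_{nmax} -
#'   \sqrt{(\alpha I + P_{nmax})^2 - 4\theta\alpha I P_{nmax}}}{2\theta} - R_d}
#' taking the minus branch of the quadratic root. At `theta = 0` the analytic
#' rectangular-hyperbola limit
#' \eqn{\alpha I P_{nmax} / (\alpha I + P_{nmax}) - R_d} is used, so no
#' division by zero occurs. A discriminant driven slightly negative by
#' floating-point rounding is clamped to zero with a warning.
#'
#' @param i PPFD (umol photons m-2 s-1); non-negative, vectorized.
#' @param params A [light_params()] object (or coercible list).
#' @return Net photosynthesis (umol CO2 m-2 s-1), same length as `i`.
#' @export
#' @examples
#' p <- light_params(pn_max = 46.03, aqy = 0.09, theta = 0.8, rd = 2)
#' nrh_pn(c(0, 200, 2000), p)
nrh_pn <- function(i, params) {
  params <- as_light_params(params)
  if (!is.numeric(i) || any(!is.finite(i))) stop("'i' must be finite numeric")
  if (any(i < 0)) stop("PPFD 'i' must be non-negative")
  ai <- params$aqy * i
  if (params$theta == 0) {
    # rectangular limit; at i = 0 the ratio is 0/pn_max = 0
    return(ai * params$pn_max / (ai + params$pn_max) - params$rd)
  }
  s <- ai + params$pn_max
  disc <- s^2 - 4 * params$theta * ai * params$pn_max
  if (any(disc < 0)) {
    warning("negative discriminant clamped to zero (floating-point guard)")
    disc <- pmax(disc, 0)
  }
  (s - sqrt(disc)) / (2 * params$theta) - params$rd
}

kprime <- function(kinetics) kinetics$kc * (1 + kinetics$o / kinetics$ko)

#' Rubisco-limited (carboxylation-limited) photosynthesis rate
#'
#' The carboxylation-limited gross rate `Wc`. The default functional form is
#' \eqn{W_c = V_{cmax} C_i / (C_i + K_c (1 + O/K_o))}. With
#' `canonical = TRUE` the textbook FvCB numerator is used instead,
#' \eqn{W_c = V_{cmax} (C_i - \Gamma^*) / (C_i + K_c(1 + O/K_o))}; the
#' default is the simpler form and the switch is opt-in.
#'
#' @param ci Intercellular CO2 concentration (umol mol-1); non-negative,
#'   vectorized.
#' @param params An [fvcb_params()] object.
#' @param kinetics A [kinetic_constants()] object.
#' @param canonical Use the `(Ci - Gamma*)` numerator? Default `FALSE`.
#' @return Rate in umol m-2 s-1.
#' @export
fvcb_wc <- function(ci, params, kinetics = kinetic_constants(),
                    canonical = FALSE) {
  params <- as_fvcb_params(params)
  if (!is.numeric(ci) || any(!is.finite(ci))) stop("'ci' must be finite numeric")
  if (any(ci < 0)) stop("'ci' must be non-negative")
  num <- if (canonical) ci - kinetics$gamma_star else ci
  params$vcmax * num / (ci + kprime(kinetics))
}

#' RuBP-regeneration-limited photosynthesis rate
#'
#' The electron-transport-limited gross rate
#' \eqn{W_j = J_{max} C_i / (4 C_i + 8 \Gamma^*)} (default), or with
#' `canonical = TRUE` \eqn{J_{max}(C_i - \Gamma^*)/(4 C_i + 8 \Gamma^*)}.
#'
#' @inheritParams fvcb_wc
#' @return Rate in umol m-2 s-1.
#' @export
fvcb_wj <- function(ci, params, kinetics = kinetic_constants(),
                    canonical = FALSE) {
  params <- as_fvcb_params(params)
  if (!is.numeric(ci) || any(!is.finite(ci))) stop("'ci' must be finite numeric")
  if (any(ci < 0)) stop("'ci' must be non-negative")
  num <- if (canonical) ci - kinetics$gamma_star else ci
  params$jmax * num / (4 * ci + 8 * kinetics$gamma_star)
}

#' FvCB net photosynthesis
#'
#' Net photosynthesis as the minimum of the Rubisco-limited and
#' RuBP-regeneration-limited rates minus dark respiration,
#' \eqn{P_n = \min(W_c, W_j) - R_d}. Continuous in `ci`, including at the
#' limitation crossover.
#'
#' @inheritParams fvcb_wc
#' @return Net photosynthesis (umol m-2 s-1), same length as `ci`.
#' @export
#' @examples
#' p <- fvcb_params(vcmax = 105.91, jmax = 191.66, rd = 1.5)
#' fvcb_pn(380, p)
fvcb_pn <- function(ci, params, kinetics = kinetic_constants(),
                    canonical = FALSE) {
  params <- as_fvcb_params(params)
  pmin(fvcb_wc(ci, params, kinetics, canonical),
       fvcb_wj(ci, params, kinetics, canonical)) - params$rd
}

#' Limitation crossover Ci
#'
#' Closed-form intercellular CO2 at which the Rubisco-limited and
#' RuBP-regeneration-limited rates are equal:
#' \deqn{C_i^* = \frac{J_{max} K' - 8 \Gamma^* V_{cmax}}{4 V_{cmax} - J_{max}},
#'   \quad K' = K_c (1 + O/K_o).}
#' The `(Ci - Gamma*)` factor of the canonical form cancels in `Wc = Wj`, so
#' the crossover is the same for both functional forms. Returns `NA` when the
#' denominator is non-positive or the root is non-positive (no crossover in
#' the physical domain).
#'
#' @param params An [fvcb_params()] object.
#' @param kinetics A [kinetic_constants()] object.
#' @return The crossover Ci (umol mol-1), or `NA_real_` if none exists.
#' @export
fvcb_crossover_ci <- function(params, kinetics = kinetic_constants()) {
  params <- as_fvcb_params(params)
  den <- 4 * params$vcmax - params$jmax
  if (den <= 0) return(NA_real_)
  ci <- (params$jmax * kprime(kinetics) -
           8 * kinetics$gamma_star * params$vcmax) / den
  if (ci <= 0) NA_real_ else ci
}

#' Richards growth curve: grain weight
#'
#' Grain dry weight at `t` days after anthesis under
#' \eqn{W(t) = A (1 + B e^{-kt})^{-1/N}}; strictly increasing with
#' asymptote `A`. `N = 1` recovers the logistic curve.
#'
#' @param t Days after anthesis; non-negative, vectorized.
#' @param params A [richards_params()] object.
#' @return Grain weight (mg grain-1).
#' @export
richards_mass <- function(t, params) {
  params <- as_richards_params(params)
  if (!is.numeric(t) || any(!is.finite(t))) stop("'t' must be finite numeric")
  if (any(t < 0)) stop("'t' must be non-negative")
  params$a * (1 + params$b * exp(-params$k * t))^(-1 / params$n)
}

#' Richards growth curve: grain filling rate
#'
#' The analytic derivative of [richards_mass()],
#' \eqn{dW/dt = \frac{A k B}{N} e^{-kt} (1 + B e^{-kt})^{-1/N - 1}};
#' non-negative everywhere and unimodal in `t`.
#'
#' @inheritParams richards_mass
#' @return Filling rate (mg grain-1 day-1).
#' @export
richards_rate <- function(t, params) {
  params <- as_richards_params(params)
  if (!is.numeric(t) || any(!is.finite(t))) stop("'t' must be finite numeric")
  if (any(t < 0)) stop("'t' must be non-negative")
  e <- exp(-params$k * t)
  (params$a * params$k * params$b / params$n) * e *
    (1 + params$b * e)^(-1 / params$n - 1)
}
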