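#' Light-response curve parameters
#'
#' Bundle of non-rectangular hyperbola parameters describing the response of
#' leaf net photosynthesis to photosynthetic photon flux density (PPFD).
#'
#' @param pn_max Maximal net photosynthesis at light saturation
#'   (umol CO2 m-2 s-1); must be positive.
#' @param aqy Apparent quantum yield, the initial slope of the light-response
#'   curve (mol CO2 per mol photons); must be positive.
#' @param theta Curve convexity, dimensionless, in `[0, 1]`. `theta = 0` gives
#'   the rectangular hyperbola, `theta = 1` the Blackman limiting response.
#' @param rd Dark (mitochondrial) respiration rate (umol CO2 m-2 s-1);
#'   non-negative.
#' @return An object of class `light_params`.
#' @seealso [nrh_pn()], [fit_light_response()]
#' @export
#' @examples
#' light_params(pn_max = 46.03, aqy = 0.09, theta = 0.8, rd = 2)
light_params <- function(pn_max, aqy, theta = 0.8, rd = 0) {
  stopifnot(is.numeric(pn_max), is.numeric(aqy), is.numeric(theta),
            is.numeric(rd), length(pn_max) == 1L, length(aqy) == 1L,
            length(theta) == 1L, length(rd) == 1L)
  if (pn_max <= 0) stop("'pn_max' must be > 0")
  if (aqy <= 0) stop("'aqy' must be > 0")
  if (theta < 0 || theta > 1) stop("'theta' must lie in [0, 1]")
  if (rd < 0) stop("'rd' must be >= 0")
  structure(list(pn_max = pn_max, aqy = aqy, theta = theta, rd = rd),
            class = "light_params")
}

#' Farquhar-von Caemmerer-Berry (FvCB) model capacities
#'
#' @param vcmax Maximum Rubisco carboxylation rate (umol m-2 s-1).
#' @param jmax Maximum electron transport rate (umol m-2 s-1).
#' @param rd Dark respiration rate (umol m-2 s-1).
#' @return An object of class `fvcb_params`.
#' @seealso [fvcb_pn()], [fit_aci()]
#' @export
#' @examples
#' fvcb_params(vcmax = 105.91, jmax = 191.66, rd = 1.5)
fvcb_params <- function(vcmax, jmax, rd = 0) {
  stopifnot(is.numeric(vcmax), is.numeric(jmax), is.numeric(rd),
            length(vcmax) == 1L, length(jmax) == 1L, length(rd) == 1L)
  if (vcmax <= 0) stop("'vcmax' must be > 0")
  if (jmax <= 0) stop("'jmax' must be > 0")
  if (rd < 0) stop("'rd' must be >= 0")
  structure(list(vcmax = vcmax, jmax = jmax, rd = rd), class = "fvcb_params")
}

#' Rubisco kinetic constants for A/Ci model evaluation
#'
#' The constants that enter the carboxylation- and RuBP-regeneration-limited
#' rates. `kc` and `gamma_star` are CO2 mole fractions (umol mol-1, i.e. ppm at
#' ambient pressure); `ko` and `o` are O2 partial pressures (mbar), so the
#' ratio `o / ko` entering the effective Michaelis constant is dimensionless.
#'
#' @param kc Rubisco Michaelis constant for CO2 (umol mol-1).
#' @param ko Rubisco Michaelis constant for O2 (mbar).
#' @param o Oxygen partial pressure (mbar).
#' @param gamma_star CO2 compensation point in the absence of dark respiration
#'   (umol mol-1).
#' @return An object of class `kinetic_constants`.
#' @export
#' @examples
#' kinetic_constants()          # the default constant set
#' kinetic_constants(kc = 404)$kc
kinetic_constants <- function(kc = 404, ko = 278, o = 210, gamma_star = 45) {
  vals <- c(kc = kc, ko = ko, o = o, gamma_star = gamma_star)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all kinetic constants must be strictly positive and finite")
  structure(as.list(vals), class = "kinetic_constants")
}

#' Richards growth-curve parameters for grain filling
#'
#' Parameterization `W(t) = a * (1 + b * exp(-k * t))^(-1/n)` of grain dry
#' weight against days after anthesis. `n = 1` recovers the logistic curve.
#'
#' @param a Asymptotic final grain weight (mg grain-1).
#' @param b Initial-condition parameter (dimensionless); larger `b` delays
#'   filling onset.
#' @param k Rate constant (day-1).
#' @param n Shape parameter (dimensionless).
#' @return An object of class `richards_params`.
#' @seealso [richards_mass()], [fit_richards()]
#' @export
richards_params <- function(a, b, k, n) {
  vals <- c(a = a, b = b, k = k, n = n)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all Richards parameters must be strictly positive")
  structure(as.list(vals), class = "richards_params")
}

#' @export
print.light_params <- function(x, ...) {
  cat("Light-response parameters (non-rectangular hyperbola):\n")
  cat(sprintf("  Pn_max = %.4g  AQY = %.4g  theta = %.4g  Rd = %.4g\n",
              x$pn_max, x$aqy, x$theta, x$rd))
  invisible(x)
}

#' @export
print.fvcb_params <- function(x, ...) {
  cat("FvCB parameters:\n")
  cat(sprintf("  Vcmax = %.4g  Jmax = %.4g  Rd = %.4g umol m-2 s-1\n",
              x$vcmax, x$jmax, x$rd))
  invisible(x)
}

#' @export
print.kinetic_constants <- function(x, ...) {
  cat(sprintf(
    "Kinetic constants: Kc = %g umol/mol, Ko = %g mbar, O = %g mbar, Gamma* = %g umol/mol\n",
    x$kc, x$ko, x$o, x$gamma_star))
  invisible(x)
}

#' @export
print.richards_params <- function(x, ...) {
  cat(sprintf("Richards parameters: A = %.4g mg, B = %.4g, k = %.4g /day, N = %.4g\n",
              x$a, x$b, x$k, x$n))
  invisible(x)
}

as_light_params <- function(x) {
  if (inherits(x, "light_params")) return(x)
  x <- as.list(x)
  light_params(x$pn_max, x$aqy, x$theta, x$rd)
}

as_fvcb_params <- function(x) {
  if (inherits(x, "fvcb_params")) return(x)
  x <- as.list(x)
  fvcb_params(x$vcmax, x$jmax, x$rd)
}

as_richards_params <- function(x) {
  if (inherits(x, "richards_params")) return(x)
  x <- as.list(x)
  richards_params(x$a, x$b, x$k, x$n)
}
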