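#' Fit a non-rectangular hyperbola light-response curve
#'
#' Estimates `pn_max`, `aqy`, `theta` and `rd` by bounded nonlinear least
#' squares on the [nrh_pn()] model from a measured Pn-vs-PPFD curve. The
#' optimizer is bounded Levenberg-Marquardt restarted from a fixed lattice of
#' starting points over the bound box (3 levels per parameter), so the fit is
#' deterministic: identical input always yields an identical result.
#'
#' Bounds: `pn_max` in (0, 100], `aqy` in (0, 0.15], `theta` in [0, 1],
#' `rd` in [0, 10]. A parameter landing on a bound is reported in the fit
#' flags, not treated as an error. A curve with (numerically) constant Pn is
#' unidentifiable and returns a non-converged result rather than failing.
#'
#' @param curve A [gas_exchange_curve()] with PPFD driver, or a data frame
#'   with columns `ppfd` (or `driver`) and `pn`. At least 5 points required;
#'   a warning is given when the curve does not span both below 100 and above
#'   1000 umol m-2 s-1.
#' @return An object of class `c("light_fit", "photo_fit")` with components
#'   `coefficients`, `se` (Gauss-Newton standard errors), `sse`, `n_obs`,
#'   `converged`, `flags`, `data`, `fitted.values` and `params`
#'   (a [light_params()] bundle). Supports `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `plot` and `simulate`.
#' @seealso [gen_light_curve()] for the matching generator.
#' @export
#' @examples
#' truth <- light_params(pn_max = 46.03, aqy = 0.09, theta = 0.8, rd = 2)
#' fit <- fit_light_response(gen_light_curve(truth))
#' coef(fit)
fit_light_response <- function(curve) {
  curve <- as_gas_exchange_curve(curve, kind = "PPFD")
  if (curve_kind(curve) != "PPFD")
    stop("fit_light_response() needs a PPFD-driven curve")
  if (nrow(curve) < 5) stop("at least 5 points are required for a fit")
  if (!any(curve$driver < 100) || !any(curve$driver > 1000))
    warning("curve does not span PPFD < 100 and > 1000; fit may be poorly constrained")

  lower <- c(pn_max = 1e-6, aqy = 1e-6, theta = 0, rd = 0)
  upper <- c(pn_max = 100, aqy = 0.15, theta = 1, rd = 10)

  flags <- character()
  if (stats::sd(curve$pn) < 1e-12) {
    coefs <- c(pn_max = NA_real_, aqy = NA_real_, theta = NA_real_,
               rd = NA_real_)
    return(new_photo_fit("light_fit", coefs, coefs, NA_real_, nrow(curve),
                         converged = FALSE,
                         flags = "unidentifiable: constant Pn",
                         data = curve, fitted = rep(NA_real_, nrow(curve)),
                         model_label = "non-rectangular hyperbola"))
  }

  resid_fn <- function(par) {
    curve$pn - nrh_eval(curve$driver, par)
  }
  best <- multistart_fit(resid_fn, start_lattice(lower, upper), lower, upper)
  if (!best$converged) flags <- c(flags, "optimizer did not converge")
  flags <- c(flags, bound_flags(best$par, lower, upper))
  se <- gauss_newton_se(resid_fn, best$par, best$sse, nrow(curve))
  fitted <- nrh_eval(curve$driver, best$par)

  new_photo_fit("light_fit", best$par, se, best$sse, nrow(curve),
                converged = best$converged, flags = flags, data = curve,
                fitted = fitted, model_label = "non-rectangular hyperbola",
                extra = list(params = tryCatch(as_light_params(best$par),
                                               error = function(e) NULL)))
}

# raw evaluation without constructor validation (optimizer may probe theta=0
# or other boundary values during the search)
nrh_eval <- function(i, par) {
  ai <- par[["aqy"]] * i
  pm <- par[["pn_max"]]
  th <- par[["theta"]]
  if (th < 1e-12) return(ai * pm / (ai + pm) - par[["rd"]])
  s <- ai + pm
  disc <- pmax(s^2 - 4 * th * ai * pm, 0)
  (s - sqrt(disc)) / (2 * th) - par[["rd"]]
}

#' @export
predict.light_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  i <- if (is.data.frame(newdata)) {
    nm <- tolower(names(newdata))
    newdata[[which(nm %in% c("ppfd", "driver"))[1]]]
  } else as.numeric(newdata)
  nrh_eval(i, object$coefficients)
}
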