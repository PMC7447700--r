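#' Fit an FvCB A/Ci curve
#'
#' Estimates `vcmax` and `jmax` (and optionally `rd`) by bounded nonlinear
#' least squares on the [fvcb_pn()] model from a measured Pn-vs-Ci curve,
#' using the same deterministic multi-start Levenberg-Marquardt protocol as
#' [fit_light_response()]. Each observation is labelled `"Wc"`
#' (Rubisco-limited) or `"Wj"` (RuBP-regeneration-limited) according to which
#' limitation is active at the fitted optimum; when every point falls on one
#' side of the crossover the parameter governing the unvisited limitation is
#' flagged as unidentifiable.
#'
#' @param curve A [gas_exchange_curve()] with Ci driver, or a data frame with
#'   columns `ci` (or `driver`) and `pn`. At least 6 points; a warning is
#'   given unless at least 2 points lie below 300 and 2 above
#'   600 umol mol-1 (both limitation states covered).
#' @param kinetics A [kinetic_constants()] object.
#' @param rd Either the string `"fit"` (default: estimate dark respiration
#'   jointly, bounded to [0, 10]) or a single non-negative number to hold it
#'   fixed at a separately measured value.
#' @param canonical Use the canonical `(Ci - Gamma*)` numerators in the
#'   limited rates? Default `FALSE` (plain-`Ci` numerators).
#' @return An object of class `c("aci_fit", "photo_fit")`; in addition to the
#'   common fit components it carries `limitation` (per-point `"Wc"`/`"Wj"`
#'   labels), `crossover_ci` and `params` (an [fvcb_params()] bundle).
#' @seealso [gen_aci_curve()], [fvcb_crossover_ci()]
#' @export
#' @examples
#' truth <- fvcb_params(vcmax = 105.91, jmax = 191.66, rd = 1.5)
#' fit <- fit_aci(gen_aci_curve(truth), rd = 1.5)
#' coef(fit)
#' table(fit$limitation)
fit_aci <- function(curve, kinetics = kinetic_constants(), rd = "fit",
                    canonical = FALSE) {
  curve <- as_gas_exchange_curve(curve, kind = "Ci")
  if (curve_kind(curve) != "Ci")
    stop("fit_aci() needs a Ci-driven curve")
  if (nrow(curve) < 6) stop("at least 6 points are required for an A/Ci fit")
  if (sum(curve$driver < 300) < 2 || sum(curve$driver > 600) < 2)
    warning("limitation states poorly covered: need >= 2 points below Ci = 300 and >= 2 above 600")

  fit_rd <- identical(rd, "fit")
  if (!fit_rd) {
    stopifnot(is.numeric(rd), length(rd) == 1L, rd >= 0)
    rd_fixed <- rd
  }

  lower <- c(vcmax = 1e-6, jmax = 1e-6)
  upper <- c(vcmax = 500, jmax = 1000)
  if (fit_rd) {
    lower <- c(lower, rd = 0)
    upper <- c(upper, rd = 10)
  }

  eval_pn <- function(ci, par) {
    rd_val <- if (fit_rd) par[["rd"]] else rd_fixed
    wc <- par[["vcmax"]] *
      (if (canonical) ci - kinetics$gamma_star else ci) /
      (ci + kprime(kinetics))
    wj <- par[["jmax"]] *
      (if (canonical) ci - kinetics$gamma_star else ci) /
      (4 * ci + 8 * kinetics$gamma_star)
    pmin(wc, wj) - rd_val
  }
  resid_fn <- function(par) curve$pn - eval_pn(curve$driver, par)

  best <- multistart_fit(resid_fn, start_lattice(lower, upper), lower, upper)
  flags <- if (best$converged) character() else "optimizer did not converge"
  flags <- c(flags, bound_flags(best$par, lower, upper))

  coefs <- best$par
  par_full <- c(vcmax = coefs[["vcmax"]], jmax = coefs[["jmax"]],
                rd = if (fit_rd) coefs[["rd"]] else rd_fixed)
  params <- fvcb_params(par_full[["vcmax"]], par_full[["jmax"]],
                        par_full[["rd"]])

  wc <- fvcb_wc(curve$driver, params, kinetics, canonical)
  wj <- fvcb_wj(curve$driver, params, kinetics, canonical)
  labels <- ifelse(wc <= wj, "Wc", "Wj")
  if (all(labels == "Wc"))
    flags <- c(flags, "jmax unidentifiable: no RuBP-regeneration-limited points")
  if (all(labels == "Wj"))
    flags <- c(flags, "vcmax unidentifiable: no Rubisco-limited points")

  se <- gauss_newton_se(resid_fn, best$par, best$sse, nrow(curve))
  fitted <- eval_pn(curve$driver, best$par)

  new_photo_fit("aci_fit", coefs, se, best$sse, nrow(curve),
                converged = best$converged, flags = flags, data = curve,
                fitted = fitted, model_label = "FvCB A/Ci",
                extra = list(params = params, limitation = labels,
                             crossover_ci = fvcb_crossover_ci(params, kinetics),
                             kinetics = kinetics, canonical = canonical,
                             rd_mode = if (fit_rd) "fit" else "fixed"))
}

#' @export
predict.aci_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  ci <- if (is.data.frame(newdata)) {
    nm <- tolower(names(newdata))
    newdata[[which(nm %in% c("ci", "driver"))[1]]]
  } else as.numeric(newdata)
  fvcb_pn(ci, object$params, object$kinetics, object$canonical)
}
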