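#' Fit a Richards growth curve to a grain-filling trajectory
#'
#' Estimates the four parameters of `W(t) = a (1 + b e^(-k t))^(-1/n)` by
#' bounded nonlinear least squares from a grain dry-weight time series
#' (typically sampled every 5 days after anthesis). The deterministic
#' multi-start protocol of the other fitters is used, with the `b` lattice
#' log-spaced because its bounds span four decades.
#'
#' Bounds: `a` in (0, 2 max(weight)], `b` in (0, 1e4], `k` in (0, 2],
#' `n` in (0, 10].
#'
#' @param t Days after anthesis (or a data frame with columns `t` and
#'   `weight`, in which case `weight` is ignored).
#' @param weight Grain weight (mg grain-1), positive.
#' @return An object of class `c("richards_fit", "photo_fit")` with the usual
#'   fit components plus `params` (a [richards_params()] bundle).
#' @seealso [richards_mass()], [richards_rate()], [gen_grain_filling()]
#' @export
#' @examples
#' truth <- richards_params(a = 27, b = 25, k = 0.25, n = 1.2)
#' traj <- gen_grain_filling(truth, t_max = 40)
#' coef(fit_richards(traj))
fit_richards <- function(t, weight = NULL) {
  if (is.data.frame(t)) {
    nm <- tolower(names(t))
    weight <- t[[which(nm %in% c("weight", "w"))[1]]]
    t <- t[[which(nm %in% c("t", "time", "day", "days"))[1]]]
  }
  stopifnot(is.numeric(t), is.numeric(weight), length(t) == length(weight))
  if (length(t) < 6) stop("at least 6 time points are required")
  if (any(weight <= 0)) stop("weights must be positive")
  if (weight[which.max(t)] < 0.8 * max(weight))
    warning("final point < 80% of maximum weight; asymptote poorly constrained")

  wmax <- max(weight)
  lower <- c(a = 1e-6, b = 1e-6, k = 1e-6, n = 1e-3)
  upper <- c(a = 2 * wmax, b = 1e4, k = 2, n = 10)

  resid_fn <- function(par) {
    weight - par[["a"]] *
      (1 + par[["b"]] * exp(-par[["k"]] * t))^(-1 / par[["n"]])
  }
  starts <- start_lattice(lower, upper, log_scale = "b")
  best <- multistart_fit(resid_fn, starts, lower, upper)

  flags <- if (best$converged) character() else "optimizer did not converge"
  flags <- c(flags, bound_flags(best$par, lower, upper))
  se <- gauss_newton_se(resid_fn, best$par, best$sse, length(t))
  fitted <- weight - resid_fn(best$par)

  new_photo_fit("richards_fit", best$par, se, best$sse, length(t),
                converged = best$converged, flags = flags,
                data = data.frame(t = t, weight = weight), fitted = fitted,
                model_label = "Richards growth curve",
                extra = list(params = tryCatch(as_richards_params(best$par),
                                               error = function(e) NULL)))
}

#' @export
predict.richards_fit <- function(object, newdata = NULL,
                                 type = c("mass", "rate"), ...) {
  type <- match.arg(type)
  tt <- if (is.null(newdata)) object$data$t
        else if (is.data.frame(newdata)) newdata[[1]]
        else as.numeric(newdata)
  if (type == "mass") richards_mass(tt, object$params)
  else richards_rate(tt, object$params)
}
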