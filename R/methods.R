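# Common S3 methods for fitted curve objects ("photo_fit").

#' @export
print.photo_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit, %d observations\n", x$model, x$n_obs))
  if (all(is.na(x$coefficients))) {
    cat("  fit unavailable:", paste(x$flags, collapse = "; "), "\n")
    return(invisible(x))
  }
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("SSE: %.*g   converged: %s\n", digits, x$sse, x$converged))
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.photo_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  structure(list(model = object$model, coefficients = tab, sse = object$sse,
                 n_obs = object$n_obs,
                 sigma = if (object$n_obs > length(object$coefficients))
                   sqrt(object$sse / (object$n_obs - length(object$coefficients)))
                 else NA_real_,
                 converged = object$converged, flags = object$flags,
                 limitation = object$limitation),
            class = "summary.photo_fit")
}

#' @export
print.summary.photo_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit (n = %d)\n\n", x$model, x$n_obs))
  print(round(x$coefficients, digits))
  cat(sprintf("\nResidual SSE: %.*g  (residual sd %.3g)\n", digits, x$sse,
              x$sigma))
  if (!is.null(x$limitation)) {
    cat("Limitation states: ")
    print(table(x$limitation))
  }
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.photo_fit <- function(object, ...) object$coefficients

#' @export
fitted.photo_fit <- function(object, ...) object$fitted.values

#' @export
residuals.photo_fit <- function(object, ...) {
  y <- if ("pn" %in% names(object$data)) object$data$pn else object$data$weight
  y - object$fitted.values
}

#' Diagnostic plot of a fitted response curve
#'
#' Observations with the fitted model curve overlaid on a fine driver grid.
#'
#' @param x A `photo_fit` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.photo_fit <- function(x, ...) {
  drv <- if ("driver" %in% names(x$data)) x$data$driver else x$data$t
  y <- if ("pn" %in% names(x$data)) x$data$pn else x$data$weight
  xlab <- switch(class(x)[1],
                 light_fit = "PPFD (umol m-2 s-1)",
                 aci_fit = "Ci (umol mol-1)",
                 richards_fit = "Days after anthesis", "driver")
  ylab <- if (inherits(x, "richards_fit")) "Grain weight (mg)"
          else "Pn (umol m-2 s-1)"
  graphics::plot(drv, y, xlab = xlab, ylab = ylab,
                 main = paste(x$model, "fit"), ...)
  grid_x <- seq(min(drv), max(drv), length.out = 200)
  graphics::lines(grid_x, predict(x, grid_x))
  invisible(x)
}

#' Simulate new noisy curves from a fitted model
#'
#' Draws `nsim` replicate synthetic curves at the fitted parameters, using
#' the residual standard deviation of the fit as the Gaussian noise level.
#'
#' @param object A fitted `light_fit`, `aci_fit` or `richards_fit`.
#' @param nsim Number of replicate curves.
#' @param seed Integer seed (required for reproducibility).
#' @param ... Unused.
#' @return A list of `nsim` simulated data sets of the same shape as the
#'   training data.
#' @export
simulate.photo_fit <- function(object, nsim = 1, seed = 1, ...) {
  p <- length(object$coefficients)
  sigma <- if (object$n_obs > p) sqrt(object$sse / (object$n_obs - p)) else 0
  drv <- if ("driver" %in% names(object$data)) object$data$driver
         else object$data$t
  mu <- predict(object, drv)
  with_seed(seed, lapply(seq_len(nsim), function(k) {
    out <- object$data
    if ("pn" %in% names(out)) out$pn <- mu + stats::rnorm(length(mu), 0, sigma)
    else out$weight <- mu + stats::rnorm(length(mu), 0, sigma)
    out
  }))
}
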