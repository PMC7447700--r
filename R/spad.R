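#' SPAD-to-chlorophyll linear calibration
#'
#' Fits the ordinary least-squares line mapping nondestructive SPAD meter
#' readings to extracted leaf chlorophyll content (mg g-1 fresh weight).
#' Calibrations are per cultivar: do not pool readings across cultivars
#' unless the lines are known to coincide.
#'
#' @param spad SPAD readings (dimensionless); at least 3, non-constant.
#' @param chlorophyll Chlorophyll content (mg g-1 FW), same length.
#' @param cultivar Optional cultivar label carried in the result.
#' @return An object of class `spad_calibration` with components `intercept`,
#'   `slope`, `r_squared`, `residuals`, `n`, `cultivar` and the underlying
#'   `lm` fit. Use [predict()] to apply it to new readings.
#' @export
#' @examples
#' cal <- fit_spad_calibration(c(20, 30, 40, 50), 0.30 + 0.04 * c(20, 30, 40, 50))
#' predict(cal, 40)   # 1.90 mg g-1 FW
fit_spad_calibration <- function(spad, chlorophyll, cultivar = NA_character_) {
  stopifnot(is.numeric(spad), is.numeric(chlorophyll),
            length(spad) == length(chlorophyll))
  if (length(spad) < 3) stop("at least 3 (SPAD, chlorophyll) pairs required")
  if (stats::sd(spad) == 0) stop("SPAD readings are constant; slope undefined")
  fit <- stats::lm(chlorophyll ~ spad)
  # exact calibration lines trip summary.lm's perfect-fit warning
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 residuals = unname(stats::residuals(fit)),
                 n = length(spad), cultivar = cultivar, lm = fit),
            class = "spad_calibration")
}

#' Apply a SPAD calibration
#'
#' Maps SPAD readings to chlorophyll content through the fitted line;
#' negative predictions (possible at very low readings with a negative
#' intercept) are clamped to zero with a warning.
#'
#' @param object A [fit_spad_calibration()] result.
#' @param newdata SPAD readings, numeric vector.
#' @param ... Unused.
#' @return Chlorophyll content (mg g-1 FW).
#' @export
predict.spad_calibration <- function(object, newdata, ...) {
  out <- object$intercept + object$slope * as.numeric(newdata)
  if (any(out < 0)) {
    warning("negative chlorophyll prediction(s) clamped to 0")
    out <- pmax(out, 0)
  }
  out
}

#' @export
print.spad_calibration <- function(x, digits = 4, ...) {
  cat(sprintf("SPAD calibration%s: chlorophyll = %.*g + %.*g * SPAD  (r2 = %.3f, n = %d)\n",
              if (is.na(x$cultivar)) "" else paste0(" [", x$cultivar, "]"),
              digits, x$intercept, digits, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @export
summary.spad_calibration <- function(object, ...) {
  cat(sprintf("SPAD calibration on %d pairs (r2 = %.4f)\n", object$n,
              object$r_squared))
  cat("Residuals (largest |value| flagged as potential outlier):\n")
  res <- data.frame(index = seq_along(object$residuals),
                    residual = object$residuals)
  res$flag <- ifelse(seq_len(nrow(res)) == which.max(abs(res$residual)),
                     "<- max", "")
  print(res, row.names = FALSE)
  invisible(object)
}
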