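#' PPFD and CO2 measurement ladders
#'
#' The standard measurement sequences for the two response-curve protocols:
#' the 14-level PPFD descent used for light-response curves, and the 13-level
#' CO2 sequence for A/Ci curves (six setpoints descending from 425 to 50 ppm,
#' then seven ascending from 500 to 1800 ppm after re-acclimation at 425).
#'
#' @return Numeric vector of driver setpoints, in measurement order.
#' @export
#' @examples
#' ppfd_ladder()
#' co2_ladder()
ppfd_ladder <- function() {
  c(2000, 1800, 1500, 1200, 1000, 800, 600, 400, 200, 150, 100, 50, 20, 0)
}

#' @rdname ppfd_ladder
#' @export
co2_ladder <- function() {
  c(425, 350, 250, 150, 100, 50, 500, 700, 900, 1100, 1300, 1500, 1800)
}

#' Gas-exchange response curve container
#'
#' An ordered set of (driver, Pn) observations from one response-curve
#' measurement: either net photosynthesis against PPFD (light-response) or
#' against intercellular CO2 (A/Ci). Driver values must be non-negative and
#' unique after rounding to 0.1 (duplicate setpoints indicate a malformed
#' curve).
#'
#' @param driver Driver values: PPFD (umol m-2 s-1) or Ci (umol mol-1).
#' @param pn Net photosynthesis (umol CO2 m-2 s-1).
#' @param kind `"PPFD"` or `"Ci"`.
#' @param cultivar,stage,date Optional metadata strings.
#' @return A data frame of class `gas_exchange_curve` with columns `driver`
#'   and `pn` and attributes `kind`, `cultivar`, `stage`, `date`.
#' @export
#' @examples
#' gas_exchange_curve(ppfd_ladder(), nrh_pn(ppfd_ladder(),
#'   light_params(46, 0.09, 0.8, 2)), kind = "PPFD")
gas_exchange_curve <- function(driver, pn, kind = c("PPFD", "Ci"),
                               cultivar = NA_character_,
                               stage = NA_character_,
                               date = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(driver), is.numeric(pn), length(driver) == length(pn))
  if (any(!is.finite(driver)) || any(!is.finite(pn)))
    stop("driver and pn must be finite")
  if (any(driver < 0)) stop("driver values must be non-negative")
  if (anyDuplicated(round(driver, 1)))
    stop("driver values must be unique after rounding to 0.1")
  structure(data.frame(driver = driver, pn = pn),
            kind = kind, cultivar = cultivar, stage = stage, date = date,
            class = c("gas_exchange_curve", "data.frame"))
}

curve_kind <- function(curve) attr(curve, "kind")

#' @export
print.gas_exchange_curve <- function(x, ...) {
  cat(sprintf("Gas-exchange curve (%s driver), %d points\n",
              curve_kind(x), nrow(x)))
  meta <- c(cultivar = attr(x, "cultivar"), stage = attr(x, "stage"),
            date = attr(x, "date"))
  meta <- meta[!is.na(meta)]
  if (length(meta))
    cat("  ", paste(names(meta), meta, sep = ": ", collapse = ", "), "\n",
        sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

# coerce a plain data.frame (driver/pn or ppfd/pn or ci/pn columns) into a curve
as_gas_exchange_curve <- function(x, kind = NULL) {
  if (inherits(x, "gas_exchange_curve")) return(x)
  stopifnot(is.data.frame(x))
  nm <- tolower(names(x))
  if ("driver" %in% nm) {
    drv <- x[[which(nm == "driver")[1]]]
    if (is.null(kind)) stop("'kind' required when coercing a driver/pn frame")
  } else if ("ppfd" %in% nm) {
    drv <- x[[which(nm == "ppfd")[1]]]; kind <- "PPFD"
  } else if ("ci" %in% nm) {
    drv <- x[[which(nm == "ci")[1]]]; kind <- "Ci"
  } else stop("no driver column found (expected 'driver', 'ppfd' or 'ci')")
  if (!"pn" %in% nm) stop("no 'pn' column found")
  gas_exchange_curve(drv, x[[which(nm == "pn")[1]]], kind = kind)
}
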