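#' Closed-chamber geometry and air state
#'
#' Describes one canopy chamber: a transparent box lowered over a plot whose
#' headspace CO2 is logged while the lid is closed. Defaults match a
#' 1 m x 1 m x 1.5 m chamber over 1 m2 of ground. Temperature and pressure
#' enter the ideal-gas conversion from CO2 mole-fraction drawdown to a molar
#' flux; pressure defaults to standard atmospheric when not logged.
#'
#' @param length,width,height Chamber dimensions (m).
#' @param ground_area Ground area covered (m2).
#' @param air_temperature Air temperature (K); must lie in (250, 330).
#' @param pressure Air pressure (Pa); must lie in (8e4, 1.1e5).
#' @return An object of class `chamber_spec`.
#' @export
#' @examples
#' chamber_spec()
chamber_spec <- function(length = 1, width = 1, height = 1.5,
                         ground_area = 1, air_temperature = 303.15,
                         pressure = 101325) {
  vol <- length * width * height
  if (!is.finite(vol) || vol <= 0) stop("chamber volume must be positive")
  if (ground_area <= 0) stop("'ground_area' must be positive")
  if (air_temperature <= 250 || air_temperature >= 330)
    stop("'air_temperature' must lie in (250, 330) K")
  if (pressure <= 8e4 || pressure >= 1.1e5)
    stop("'pressure' must lie in (8e4, 1.1e5) Pa")
  structure(list(length = length, width = width, height = height,
                 volume = vol, ground_area = ground_area,
                 air_temperature = air_temperature, pressure = pressure),
            class = "chamber_spec")
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf("Chamber %gx%gx%g m (V = %g m3) over %g m2; T = %g K, P = %g Pa\n",
              x$length, x$width, x$height, x$volume, x$ground_area,
              x$air_temperature, x$pressure))
  invisible(x)
}

#' Chamber closure schedule
#'
#' The cyclic measurement schedule of a multi-chamber system: each chamber
#' closes for `closed_duration` seconds (the measurement), then stays open
#' while the controller cycles through the other chambers.
#'
#' @param closed_duration Closure length (s).
#' @param open_duration Open period between closures of one chamber (s).
#' @param n_chambers Number of chambers sharing the controller.
#' @return An object of class `closure_schedule`.
#' @export
closure_schedule <- function(closed_duration = 45, open_duration = 495,
                             n_chambers = 10) {
  if (closed_duration <= 0) stop("'closed_duration' must be positive")
  if (open_duration < 0) stop("'open_duration' must be non-negative")
  if (n_chambers < 1) stop("'n_chambers' must be >= 1")
  structure(list(closed_duration = closed_duration,
                 open_duration = open_duration, n_chambers = n_chambers,
                 period = closed_duration + open_duration),
            class = "closure_schedule")
}

#' Per-second chamber CO2 log
#'
#' @param time_s Timestamps (s), strictly increasing at 1 Hz.
#' @param co2 CO2 mole fraction (umol mol-1), positive.
#' @param chamber_id Chamber identifier.
#' @param ppfd Optional PPFD log (umol m-2 s-1), same length.
#' @return A data frame of class `chamber_series`.
#' @export
chamber_series <- function(time_s, co2, chamber_id = "1", ppfd = NULL) {
  stopifnot(is.numeric(time_s), is.numeric(co2),
            length(time_s) == length(co2))
  if (any(diff(time_s) <= 0)) stop("timestamps must be strictly increasing")
  if (length(time_s) > 1 && any(abs(diff(time_s) - 1) > 1e-9))
    warning("non-1 Hz sampling gaps present")
  if (any(co2 <= 0)) stop("CO2 values must be positive")
  df <- data.frame(time_s = time_s, co2 = co2)
  if (!is.null(ppfd)) {
    stopifnot(length(ppfd) == length(time_s))
    df$ppfd <- ppfd
  }
  structure(df, chamber_id = as.character(chamber_id),
            class = c("chamber_series", "data.frame"))
}

#' Segment a chamber log into closure windows
#'
#' Enumerates the closure windows `[cycle_start + k * period,
#' cycle_start + k * period + closed_duration)` for integer `k >= 0` that lie
#' entirely within the logged time span. A closure whose 45 s are fully
#' logged counts even if the following open period is truncated; a partially
#' logged closure is dropped.
#'
#' @param series A [chamber_series()].
#' @param schedule A [closure_schedule()].
#' @param cycle_start Time of this chamber's first closure (s); per-chamber
#'   phase offsets in a multi-chamber system are expressed through this.
#' @return A data frame with columns `start` and `end` (end exclusive), one
#'   row per complete closure; zero rows (with a warning) when the series is
#'   too short.
#' @export
#' @examples
#' s <- gen_chamber_series(30, duration = 1800)
#' segment_closures(s)
segment_closures <- function(series, schedule = closure_schedule(),
                             cycle_start = 0) {
  t0 <- min(series$time_s)
  t1 <- max(series$time_s)
  starts <- seq(cycle_start, t1, by = schedule$period)
  starts <- starts[starts >= t0 & (starts + schedule$closed_duration - 1) <= t1]
  if (!length(starts)) {
    warning("series shorter than one complete closure; no windows")
    return(data.frame(start = numeric(), end = numeric()))
  }
  data.frame(start = starts, end = starts + schedule$closed_duration)
}

#' OLS drawdown slope within one closure window
#'
#' Linear regression of CO2 mole fraction on time over
#' `[start + trim_head, end)`. The first `trim_head` seconds are discarded by
#' default: immediately after lid closure the headspace is not yet well
#' mixed, a standard closed-chamber precaution (set `trim_head = 0` to keep
#' everything).
#'
#' @param series A [chamber_series()].
#' @param window One row of [segment_closures()] output (or a list with
#'   `start` and `end`).
#' @param trim_head Seconds discarded at the start of the window.
#' @return A list with `slope` (umol mol-1 s-1), `slope_se`, `r_squared` and
#'   `n`. `r_squared` is `NA` for a constant-CO2 (degenerate) window.
#' @export
estimate_slope <- function(series, window, trim_head = 5) {
  sel <- series$time_s >= window$start + trim_head &
    series$time_s < window$end
  tt <- series$time_s[sel]
  y <- series$co2[sel]
  if (length(tt) < 10)
    stop("fewer than 10 samples in the trimmed window")
  if (stats::sd(y) == 0)
    return(list(slope = 0, slope_se = 0, r_squared = NA_real_,
                n = length(tt)))
  fit <- stats::lm(y ~ tt)
  # noise-free windows trip summary.lm's "essentially perfect fit" warning
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       slope_se = sm$coefficients[2, 2],
       r_squared = sm$r.squared, n = length(tt))
}

# moles of air in the chamber headspace by the ideal gas law
chamber_air_moles <- function(spec) {
  spec$pressure * spec$volume / (8.314 * spec$air_temperature)
}

#' Convert a drawdown slope to a canopy flux
#'
#' The CO2 mole-fraction slope during closure is converted to a molar flux
#' per unit ground area with the ideal gas law:
#' `flux = -slope * n_air / ground_area`, `n_air = P V / (R T)`. A slope in
#' umol mol-1 s-1 yields a flux in umol CO2 m-2 s-1 directly. The sign
#' convention is positive for net uptake: CO2 falling while the canopy is
#' enclosed means daytime net photosynthesis.
#'
#' @param slope Drawdown slope (umol mol-1 s-1).
#' @param spec A [chamber_spec()].
#' @return Canopy net CO2 uptake (umol m-2 ground s-1).
#' @export
#' @examples
#' slope_to_flux(-0.5, chamber_spec())   # about +30.15
slope_to_flux <- function(slope, spec = chamber_spec()) {
  -slope * chamber_air_moles(spec) / spec$ground_area
}

#' Per-closure canopy flux estimates from a chamber log
#'
#' Runs the full chain [segment_closures()] -> [estimate_slope()] ->
#' [slope_to_flux()] on one chamber's log, one flux estimate per complete
#' closure. `slope_se` and `r_squared` are carried through so poor closures
#' (leaks, disturbance) can be filtered downstream.
#'
#' @inheritParams segment_closures
#' @inheritParams estimate_slope
#' @param spec A [chamber_spec()].
#' @return A data frame of class `flux_estimates`, one row per closure, with
#'   columns `chamber_id`, `t_start`, `t_end`, `slope`, `slope_se`,
#'   `r_squared`, `flux` and `mean_ppfd` (`NA` when the log has no PPFD).
#' @export
#' @examples
#' s <- gen_chamber_series(15, duration = 1800)
#' chamber_flux(s)
chamber_flux <- function(series, spec = chamber_spec(),
                         schedule = closure_schedule(), cycle_start = 0,
                         trim_head = 5) {
  win <- segment_closures(series, schedule, cycle_start)
  empty <- data.frame(chamber_id = character(), t_start = numeric(),
                      t_end = numeric(), slope = numeric(),
                      slope_se = numeric(), r_squared = numeric(),
                      flux = numeric(), mean_ppfd = numeric())
  if (!nrow(win))
    return(structure(empty, class = c("flux_estimates", "data.frame")))
  rows <- lapply(seq_len(nrow(win)), function(i) {
    est <- estimate_slope(series, win[i, ], trim_head)
    sel <- series$time_s >= win$start[i] & series$time_s < win$end[i]
    data.frame(chamber_id = attr(series, "chamber_id") %||% "1",
               t_start = win$start[i], t_end = win$end[i],
               slope = est$slope, slope_se = est$slope_se,
               r_squared = est$r_squared,
               flux = slope_to_flux(est$slope, spec),
               mean_ppfd = if ("ppfd" %in% names(series))
                 mean(series$ppfd[sel]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("flux_estimates", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bin flux estimates by PPFD
#'
#' Groups per-closure flux estimates into PPFD bins and reports per-bin mean
#' and standard deviation, the canopy light-response summary.
#'
#' @param estimates A [chamber_flux()] result (or any data frame with `flux`
#'   and `mean_ppfd` columns); rows without PPFD are dropped.
#' @param breaks Bin breaks passed to [cut()], or a single bin width
#'   (umol m-2 s-1).
#' @return A data frame with columns `ppfd_bin`, `ppfd_mid`, `n`,
#'   `mean_flux`, `sd_flux` (`NA` for single-member bins).
#' @export
flux_light_curve <- function(estimates, breaks = 200) {
  est <- estimates[!is.na(estimates$mean_ppfd), , drop = FALSE]
  if (!nrow(est)) stop("no PPFD data available for binning")
  if (length(breaks) == 1) {
    top <- max(est$mean_ppfd)
    breaks <- seq(0, top + breaks, by = breaks)
  }
  bin <- cut(est$mean_ppfd, breaks, include.lowest = TRUE, right = FALSE)
  agg <- lapply(split(est$flux, bin, drop = TRUE), function(v) {
    c(n = length(v), mean_flux = mean(v),
      sd_flux = if (length(v) > 1) stats::sd(v) else NA_real_)
  })
  keep <- names(agg)
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  names(mids) <- levels(bin)
  out <- data.frame(ppfd_bin = keep, ppfd_mid = unname(mids[keep]),
                    do.call(rbind, agg), row.names = NULL)
  out
}
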