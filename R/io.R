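# CSV readers/writers for the pipeline's file schemas, JSON fit reports and
# run configuration. All files are plain UTF-8, comma-separated, '.' decimal,
# header required; both LF and CRLF line endings are accepted (read.csv
# handles either).

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
}

numeric_column <- function(df, col, path) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
  if (length(bad))
    stop("file '", path, "', column '", col, "': non-numeric value at line ",
         bad[1] + 1L)  # +1 for the header line
  v
}

#' Read a gas-exchange curve from CSV
#'
#' Schema: columns `driver_kind` (all `PPFD` or all `Ci`), `driver`, `pn`,
#' and optional `cultivar`, `stage`, `date`. Row order is preserved.
#'
#' @param path CSV path.
#' @return A [gas_exchange_curve()].
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  check_columns(df, c("driver_kind", "driver", "pn"), path)
  kinds <- unique(df$driver_kind)
  if (length(kinds) != 1)
    stop("file '", path, "': mixed driver_kind values (",
         paste(kinds, collapse = ", "), "); one curve per file")
  meta <- function(col) if (col %in% names(df)) df[[col]][1] else NA_character_
  gas_exchange_curve(numeric_column(df, "driver", path),
                     numeric_column(df, "pn", path),
                     kind = kinds,
                     cultivar = meta("cultivar"), stage = meta("stage"),
                     date = meta("date"))
}

#' Write a gas-exchange curve to CSV
#'
#' Inverse of [read_curve_csv()]; write-then-read is the identity.
#'
#' @param curve A [gas_exchange_curve()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  df <- data.frame(driver_kind = curve_kind(curve), driver = curve$driver,
                   pn = curve$pn, cultivar = attr(curve, "cultivar"),
                   stage = attr(curve, "stage"), date = attr(curve, "date"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read chamber CO2 logs from CSV
#'
#' Schema: columns `time_s`, `chamber_id`, `co2_ppm` and optional `ppfd`.
#' Rows are split by chamber id; within each chamber time must be strictly
#' increasing (an error otherwise) and non-1 Hz gaps are flagged with a
#' warning.
#'
#' @param path CSV path.
#' @return A named list of [chamber_series()], one per chamber id.
#' @export
read_chamber_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  check_columns(df, c("time_s", "chamber_id", "co2_ppm"), path)
  df$time_s <- numeric_column(df, "time_s", path)
  df$co2_ppm <- numeric_column(df, "co2_ppm", path)
  if ("ppfd" %in% names(df)) df$ppfd <- numeric_column(df, "ppfd", path)
  out <- lapply(split(df, df$chamber_id), function(d) {
    if (any(diff(d$time_s) <= 0))
      stop("file '", path, "': time going backwards for chamber ",
           d$chamber_id[1])
    chamber_series(d$time_s, d$co2_ppm, chamber_id = d$chamber_id[1],
                   ppfd = if ("ppfd" %in% names(d)) d$ppfd)
  })
  out[order(names(out))]
}

#' Write chamber series to CSV
#'
#' @param series A [chamber_series()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_chamber_csv <- function(series, path) {
  if (inherits(series, "chamber_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    d <- data.frame(time_s = s$time_s,
                    chamber_id = attr(s, "chamber_id"), co2_ppm = s$co2)
    if ("ppfd" %in% names(s)) d$ppfd <- s$ppfd
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read or write a trait table CSV
#'
#' Schema: columns `cultivar`, `year`, `replicate`, `trait`, `value`,
#' optional `unit`.
#'
#' @param path CSV path.
#' @return [read_trait_csv()]: a [trait_table()].
#' @export
read_trait_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  check_columns(df, c("cultivar", "year", "replicate", "trait", "value"), path)
  trait_table(df$cultivar, df$year, df$replicate, df$trait,
              numeric_column(df, "value", path),
              if ("unit" %in% names(df)) df$unit else NA_character_)
}

#' @rdname read_trait_csv
#' @param table A [trait_table()].
#' @export
write_trait_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Serialize a fit as a JSON report
#'
#' Writes coefficients, standard errors, SSE, convergence state, flags and
#' (for A/Ci fits) limitation labels, under a `schema_version` field.
#'
#' @param fit A `photo_fit` or `spad_calibration` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  rep <- if (inherits(fit, "spad_calibration")) {
    list(schema_version = 1L, model = "SPAD calibration",
         params = list(intercept = fit$intercept, slope = fit$slope),
         r_squared = fit$r_squared, n_obs = fit$n)
  } else {
    list(schema_version = 1L, model = fit$model,
         params = as.list(fit$coefficients), se = as.list(fit$se),
         sse = fit$sse, n_obs = fit$n_obs, converged = fit$converged,
         flags = fit$flags,
         limitation_labels = fit$limitation)
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Flat key-value configuration with documented defaults; unknown keys are
#' rejected. `pipeline_config()` builds one in code, `read_config()` loads
#' one from a JSON object or `key=value` lines.
#'
#' @param ... Overrides of the defaults: `kc`, `ko`, `o`, `gamma_star`
#'   (kinetic constants), `trim_head` (s), `closed_duration` (s),
#'   `open_duration` (s), `n_chambers`, `air_temperature` (K),
#'   `pressure` (Pa), `alpha`, `seed`.
#' @return A named list of class `pipeline_config`.
#' @export
#' @examples
#' pipeline_config(trim_head = 0)$trim_head
pipeline_config <- function(...) {
  defaults <- list(kc = 404, ko = 278, o = 210, gamma_star = 45,
                   trim_head = 5, closed_duration = 45, open_duration = 495,
                   n_chambers = 10, air_temperature = 303.15,
                   pressure = 101325, alpha = 0.05, seed = 1L)
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all config entries must be named")
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  structure(utils::modifyList(defaults, over), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a JSON file (object of scalars) or a text file of
#'   `key=value` lines (`#` comments allowed).
#' @export
read_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  first <- trimws(paste(txt, collapse = ""))
  vals <- if (startsWith(first, "{")) {
    jsonlite::fromJSON(paste(txt, collapse = "\n"), simplifyVector = TRUE)
  } else {
    lines <- trimws(txt)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    bad <- lengths(kv) != 2
    if (any(bad)) stop("malformed config line: ", lines[bad][1])
    vals <- lapply(kv, function(p) {
      v <- trimws(p[2])
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    })
    names(vals) <- trimws(vapply(kv, `[`, "", 1))
    vals
  }
  do.call(pipeline_config, as.list(vals))
}
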