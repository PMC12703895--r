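# Delimited-text I/O with schema validation. All files are plain CSV with
# ISO-8601 dates; readers validate headers and reject duplicate keys.

series_schema <- c("date", "location_id", "deaths", "deaths_cvd",
                   "deaths_resp", "deaths_other", "deaths_male",
                   "deaths_female", "deaths_0_64", "deaths_65p",
                   "tmax", "tmin", "tmean", "rh", "pm25", "o3")

write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

check_schema <- function(d, required, path) {
  missing <- setdiff(required, names(d))
  extra <- setdiff(names(d), required)
  if (length(missing)) {
    stop("schema mismatch in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "),
         if (length(extra)) paste0("; extra column(s) ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  invisible(d)
}

#' Read a daily per-location series file
#'
#' Validates the canonical header (`date, location_id, deaths, ...`,
#' see [write_daily_series()]), parses ISO-8601 dates, and rejects
#' duplicated (location, date) rows.
#'
#' @param path CSV path.
#' @return data.frame with a `Date` column `date`.
#' @export
read_daily_series <- function(path) {
  d <- read_table(path)
  check_schema(d, series_schema, path)
  d$date <- as.Date(d$date)
  if (anyNA(d$date)) stop("unparseable dates in ", path, call. = FALSE)
  dup <- duplicated(d[c("location_id", "date")])
  if (any(dup)) {
    stop("duplicated (location, date) rows in ", path, ": ",
         paste(format(utils::head(d$date[dup], 5)), collapse = ", "),
         call. = FALSE)
  }
  d[order(d$location_id, d$date), , drop = FALSE]
}

#' Write a daily per-location series file
#'
#' @param series data.frame with the canonical series columns.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_daily_series <- function(series, path) {
  check_schema(series, series_schema, path)
  write_table(series[series_schema], path)
}

#' Read the per-city annual population table
#'
#' Columns: `city_id, year, pop_total, pop_0_64, pop_65p, gdp_level`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_population_table <- function(path) {
  d <- read_table(path)
  check_schema(d, c("city_id", "year", "pop_total", "pop_0_64", "pop_65p",
                    "gdp_level"), path)
  if (anyDuplicated(d[c("city_id", "year")])) {
    stop("duplicated (city, year) rows in ", path, call. = FALSE)
  }
  d
}

#' Read the annual mortality-rate table
#'
#' Columns: `city_id, year, group, daily_rate`, optionally
#' `daily_rate_se`; when the SE column is absent a relative SE
#' (`rel_se`, default 5%) is applied and noted with a message.
#'
#' @param path CSV path.
#' @param rel_se relative standard error applied when the file carries
#'   none.
#' @return data.frame including `daily_rate_se`.
#' @export
read_rate_table <- function(path, rel_se = 0.05) {
  d <- read_table(path)
  req <- c("city_id", "year", "group", "daily_rate")
  missing <- setdiff(req, names(d))
  if (length(missing)) {
    stop("schema mismatch in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(d$daily_rate_se)) {
    message(sprintf(
      "rates file has no `daily_rate_se`; applying relative SE %.0f%%",
      100 * rel_se))
    d$daily_rate_se <- rel_se * d$daily_rate
  }
  if (anyDuplicated(d[c("city_id", "year", "group")])) {
    stop("duplicated (city, year, group) rows in ", path, call. = FALSE)
  }
  d
}

#' Write detected heatwave events
#'
#' Columns: `location_id, start, end, duration, mean_metric,
#' excess_degree_days`.
#'
#' @param events `"hw_events"` data.frame.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_events <- function(events, path) {
  write_table(as.data.frame(events), path)
}

#' Read detected heatwave events
#' @param path CSV path.
#' @return `"hw_events"` data.frame.
#' @export
read_events <- function(path) {
  d <- read_table(path)
  check_schema(d, c("location_id", "start", "end", "duration",
                    "mean_metric", "excess_degree_days"), path)
  d$start <- as.Date(d$start)
  d$end <- as.Date(d$end)
  class(d) <- c("hw_events", "data.frame")
  d
}

#' Write location fits
#'
#' Columns: `location_id, beta_cum, se, dispersion, qaic, n_days`.
#'
#' @param fits list of `"location_fit"` objects (NULLs dropped).
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_fits <- function(fits, path) {
  fits <- Filter(Negate(is.null), fits)
  d <- do.call(rbind, lapply(fits, function(f) {
    data.frame(location_id = f$location_id, beta_cum = f$beta_cum,
               se = f$se, dispersion = f$dispersion, qaic = f$qaic,
               n_days = f$n_days, stringsAsFactors = FALSE)
  }))
  write_table(d, path)
}

#' Read location fits
#' @param path CSV path.
#' @return data.frame with `var_beta_cum` reconstructed from `se`.
#' @export
read_fits <- function(path) {
  d <- read_table(path)
  check_schema(d, c("location_id", "beta_cum", "se", "dispersion", "qaic",
                    "n_days"), path)
  d$var_beta_cum <- d$se^2
  d
}
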