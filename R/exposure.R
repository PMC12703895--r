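#' Heatwave definition
#'
#' A heatwave definition is a rule of the form "at least `min_duration`
#' consecutive days on which `metric` exceeds the `percentile`-th percentile
#' of its reference distribution". The reference distribution is restricted
#' to `reference_period` (calendar years) and, when
#' `threshold_season = "warm"`, to warm-season months, since an all-year
#' percentile would be dominated by winter values.
#'
#' @param metric which daily metric the rule applies to: `"tmax"`, `"tmin"`,
#'   or `"heat_index"` (apparent temperature from mean temperature and
#'   relative humidity, see [heat_index()]).
#' @param percentile percentile of the reference distribution, strictly
#'   between 0 and 100. Default 92.5.
#' @param min_duration minimum run length in days (>= 1). Default 2.
#' @param reference_period integer vector of calendar years defining the
#'   reference distribution, or `NULL` to use all years present.
#' @param reference_season months (1-12) whose days form the reference
#'   distribution and within which runs are sought. Default May-September.
#' @param threshold_season `"warm"` (default) restricts the percentile
#'   computation to `reference_season` days; `"all"` uses every calendar day
#'   of the reference period.
#' @return An object of class `"hw_definition"`.
#' @export
heatwave_definition <- function(metric = c("tmax", "tmin", "heat_index"),
                                percentile = 92.5,
                                min_duration = 2L,
                                reference_period = NULL,
                                reference_season = 5:9,
                                threshold_season = c("warm", "all")) {
  metric <- match.arg(metric)
  threshold_season <- match.arg(threshold_season)
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile >= 100) {
    stop("`percentile` must be a single number strictly between 0 and 100",
         call. = FALSE)
  }
  if (!is.numeric(min_duration) || length(min_duration) != 1L ||
      min_duration < 1 || min_duration != round(min_duration)) {
    stop("`min_duration` must be a whole number >= 1", call. = FALSE)
  }
  if (!all(reference_season %in% 1:12)) {
    stop("`reference_season` must be months in 1..12", call. = FALSE)
  }
  structure(
    list(metric = metric, percentile = percentile,
         min_duration = as.integer(min_duration),
         reference_period = reference_period,
         reference_season = as.integer(reference_season),
         threshold_season = threshold_season),
    class = "hw_definition"
  )
}

#' @export
print.hw_definition <- function(x, ...) {
  cat(sprintf(
    "Heatwave definition: %s > %gth percentile for >= %d consecutive days\n",
    x$metric, x$percentile, x$min_duration))
  invisible(x)
}

#' Percentile threshold for a heatwave definition
#'
#' Computes the temperature threshold as the `percentile`-th percentile of
#' the daily metric over the definition's reference period and season,
#' using linear interpolation between closest order statistics (the
#' convention interpolating at position `(n - 1) * p / 100` of the sorted
#' values; `stats::quantile()` type 7).
#'
#' @param dates `Date` vector.
#' @param values daily metric values aligned with `dates`.
#' @param definition an [heatwave_definition()].
#' @return The threshold, a single number (same unit as `values`).
#'   Missing values are excluded with a message stating how many.
#' @export
compute_threshold <- function(dates, values, definition = heatwave_definition()) {
  stopifnot(inherits(definition, "hw_definition"))
  dates <- as.Date(dates)
  if (length(dates) != length(values)) {
    stop("`dates` and `values` must have equal length", call. = FALSE)
  }
  keep <- rep(TRUE, length(dates))
  if (!is.null(definition$reference_period)) {
    keep <- keep & (date_year(dates) %in% definition$reference_period)
  }
  if (identical(definition$threshold_season, "warm")) {
    keep <- keep & (date_month(dates) %in% definition$reference_season)
  }
  v <- values[keep]
  n_na <- sum(is.na(v))
  if (n_na > 0L) {
    message(sprintf("compute_threshold: excluding %d missing days", n_na))
    v <- v[!is.na(v)]
  }
  if (length(v) == 0L) {
    stop("no data in the reference period/season for threshold computation",
         call. = FALSE)
  }
  unname(stats::quantile(v, probs = definition$percentile / 100, type = 7))
}

#' Detect heatwave events
#'
#' Finds maximal runs of consecutive warm-season days on which the metric
#' strictly exceeds the threshold, and keeps runs of length at least
#' `min_duration`. Runs never bridge a gap in the date sequence, so a run
#' cannot span the end of one warm season and the start of the next.
#'
#' @param dates `Date` vector, strictly increasing.
#' @param values daily metric values aligned with `dates`.
#' @param threshold exceedance threshold (same unit as `values`).
#' @param min_duration minimum run length in days.
#' @param season_months months defining the analysed season; days outside
#'   them are removed before run-finding. `NULL` keeps all days.
#' @param location_id identifier copied into the output.
#' @return A data.frame of class `"hw_events"` with columns `location_id`,
#'   `start`, `end`, `duration`, `mean_metric`, `excess_degree_days`
#'   (the summed exceedance over the run, in degree-days).
#' @export
detect_heatwaves <- function(dates, values, threshold,
                             min_duration = 2L, season_months = 5:9,
                             location_id = NA_character_) {
  dates <- as.Date(dates)
  if (length(dates) != length(values)) {
    stop("`dates` and `values` must have equal length", call. = FALSE)
  }
  if (is.unsorted(dates, strictly = TRUE)) {
    stop("`dates` must be strictly increasing", call. = FALSE)
  }
  if (!is.null(season_months)) {
    keep <- date_month(dates) %in% season_months
    dates <- dates[keep]
    values <- values[keep]
  }
  empty <- data.frame(
    location_id = character(), start = as.Date(character()),
    end = as.Date(character()), duration = integer(),
    mean_metric = numeric(), excess_degree_days = numeric(),
    stringsAsFactors = FALSE)
  class(empty) <- c("hw_events", "data.frame")
  if (length(dates) == 0L) return(empty)

  # contiguous blocks: a new block starts whenever dates are not consecutive
  block <- cumsum(c(1L, as.integer(diff(dates) != 1L)))
  exceed <- !is.na(values) & values > threshold

  out <- vector("list", 0L)
  for (b in unique(block)) {
    sel <- block == b
    e <- exceed[sel]
    if (!any(e)) next
    r <- rle(e)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= min_duration)
    for (i in ok) {
      idx <- which(sel)[starts[i]:ends[i]]
      out[[length(out) + 1L]] <- data.frame(
        location_id = location_id,
        start = dates[idx[1L]],
        end = dates[idx[length(idx)]],
        duration = length(idx),
        mean_metric = mean(values[idx]),
        excess_degree_days = sum(values[idx] - threshold),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("hw_events", "data.frame")
  res
}

#' Daily heatwave-day indicator
#'
#' Expands a set of detected events into a 0/1 series over a date index:
#' 1 exactly on days inside an event. Events must be disjoint.
#'
#' @param events an `"hw_events"` data.frame from [detect_heatwaves()].
#' @param dates `Date` index over which the indicator is evaluated.
#' @return Integer 0/1 vector aligned with `dates`; its sum equals the sum
#'   of event durations that fall inside `dates`.
#' @export
heatwave_day_indicator <- function(events, dates) {
  dates <- as.Date(dates)
  ind <- integer(length(dates))
  if (is.null(events) || nrow(events) == 0L) return(ind)
  ev <- events[order(events$start), , drop = FALSE]
  if (nrow(ev) > 1L && any(ev$start[-1L] <= ev$end[-nrow(ev)])) {
    stop("overlapping heatwave events", call. = FALSE)
  }
  for (i in seq_len(nrow(ev))) {
    ind[dates >= ev$start[i] & dates <= ev$end[i]] <- 1L
  }
  ind
}

#' Cumulative excessive degree-days (CEDD)
#'
#' CEDD summarises frequency and intensity of heatwaves in one number: the
#' sum, over all heatwave days, of the exceedance of the metric above the
#' threshold (degree-days). Here it is the sum of the per-event
#' `excess_degree_days` of the supplied events.
#'
#' @param events an `"hw_events"` data.frame (typically one location-year).
#' @return Nonnegative number of degree-days; 0 for no events.
#' @export
compute_cedd <- function(events) {
  if (is.null(events) || nrow(events) == 0L) return(0)
  sum(events$excess_degree_days)
}

#' Person-days of heatwave exposure
#'
#' The product of the number of heatwave days and the exposed population;
#' a combined duration-by-population exposure measure.
#'
#' @param n_heatwave_days number of heatwave days (nonnegative).
#' @param population exposed population count (nonnegative).
#' @return `n_heatwave_days * population`, exactly. Vectorised.
#' @export
compute_person_days <- function(n_heatwave_days, population) {
  if (any(n_heatwave_days < 0, na.rm = TRUE) || any(population < 0, na.rm = TRUE)) {
    stop("`n_heatwave_days` and `population` must be nonnegative", call. = FALSE)
  }
  n_heatwave_days * population
}

celsius_to_fahrenheit <- function(x) x * 9 / 5 + 32
fahrenheit_to_celsius <- function(x) (x - 32) * 5 / 9

#' Heat index (apparent temperature)
#'
#' Apparent temperature from daily mean temperature and relative humidity,
#' via the US National Weather Service Rothfusz regression with its
#' standard low- and high-humidity adjustments; below the regression's
#' activation range (simple estimate under 80 degF) the NWS simple formula
#' is used. Conversion degC <-> degF is internal.
#'
#' @param tmean daily mean temperature, degC.
#' @param rh relative humidity, percent, in \[0, 100\].
#' @return Heat index in degC. Vectorised.
#' @export
heat_index <- function(tmean, rh) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) {
    stop("`rh` must be within [0, 100]", call. = FALSE)
  }
  t_f <- celsius_to_fahrenheit(tmean)
  hi <- 0.5 * (t_f + 61 + (t_f - 68) * 1.2 + rh * 0.094)
  hot <- !is.na(hi) & hi >= 80
  if (any(hot)) {
    tf <- t_f[hot]; r <- rh[hot]
    reg <- -42.379 + 2.04901523 * tf + 10.14333127 * r -
      0.22475541 * tf * r - 0.00683783 * tf^2 - 0.05481717 * r^2 +
      0.00122874 * tf^2 * r + 0.00085282 * tf * r^2 -
      0.00000199 * tf^2 * r^2
    lowrh <- r < 13 & tf >= 80 & tf <= 112
    reg[lowrh] <- reg[lowrh] - ((13 - r[lowrh]) / 4) *
      sqrt((17 - abs(tf[lowrh] - 95)) / 17)
    highrh <- r > 85 & tf >= 80 & tf <= 87
    reg[highrh] <- reg[highrh] + ((r[highrh] - 85) / 10) *
      ((87 - tf[highrh]) / 5)
    hi[hot] <- reg
  }
  fahrenheit_to_celsius(hi)
}

#' Annual exposure summary
#'
#' Summarises detected events per calendar year: number of events, heatwave
#' days, CEDD, and (when a population table is supplied) person-days of
#' exposure per population group.
#'
#' @param events an `"hw_events"` data.frame for one location.
#' @param years integer vector of years to summarise (years with no events
#'   get zero rows).
#' @param population optional data.frame with column `year` and one column
#'   per population group (e.g. `pop_total`, `pop_0_64`, `pop_65p`); adds a
#'   `person_days_<group>` column per group.
#' @return data.frame with one row per year.
#' @export
exposure_summary <- function(events, years, population = NULL) {
  years <- sort(unique(as.integer(years)))
  ev_year <- if (nrow(events)) date_year(events$start) else integer()
  out <- data.frame(year = years)
  out$n_events <- vapply(years, function(y) sum(ev_year == y), integer(1))
  out$n_heatwave_days <- vapply(
    years, function(y) sum(events$duration[ev_year == y]), numeric(1))
  out$cedd <- vapply(
    years, function(y) sum(events$excess_degree_days[ev_year == y]), numeric(1))
  if (!is.null(population)) {
    missing_years <- setdiff(years, population$year)
    if (length(missing_years)) {
      stop("population table missing years: ",
           paste(missing_years, collapse = ", "), call. = FALSE)
    }
    groups <- setdiff(names(population), c("year", "city_id", "gdp_level"))
    m <- match(out$year, population$year)
    for (g in groups) {
      out[[paste0("person_days_", sub("^pop_", "", g))]] <-
        compute_person_days(out$n_heatwave_days, population[[g]][m])
    }
  }
  out
}

#' Compare a target year against a baseline-period mean
#'
#' Computes `target - mean(baseline)` and a two-sided one-sample t-test of
#' the baseline annual values against the target value. This is the
#' year-vs-baseline contrast used for exposure indicators (CEDD,
#' person-days): the difference is exact; the test treats the baseline
#' years as the sample and the target-year value as the hypothesised mean.
#'
#' @param baseline_values annual values for the baseline years (>= 2 for
#'   the test).
#' @param target_value the target-year value.
#' @return list with `difference`, `baseline_mean`, `target`, `p_value`.
#' @export
compare_exposure <- function(baseline_values, target_value) {
  if (length(baseline_values) < 2L) {
    stop("need >= 2 baseline years for the comparison test", call. = FALSE)
  }
  bm <- mean(baseline_values)
  p <- if (stats::var(baseline_values) == 0) {
    if (bm == target_value) 1 else 0
  } else {
    stats::t.test(baseline_values, mu = target_value)$p.value
  }
  list(difference = target_value - bm, baseline_mean = bm,
       target = target_value, p_value = p)
}

# small date helpers (POSIXlt fields; much faster than format() on long vectors)
date_year <- function(d) as.POSIXlt(d)$year + 1900L
date_month <- function(d) as.POSIXlt(d)$mon + 1L
date_yday <- function(d) as.POSIXlt(d)$yday + 1L
date_wday <- function(d) {
  w <- as.POSIXlt(d)$wday  # 0 = Sunday
  ifelse(w == 0L, 7L, w)   # 1 = Monday .. 7 = Sunday
}
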