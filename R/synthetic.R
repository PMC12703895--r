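#' Simulation configuration
#'
#' Parameters of the synthetic multi-location study: a sinusoidal annual
#' temperature cycle with AR(1) noise (so that runs of hot days arise
#' naturally), overdispersed daily death counts with annual-sinusoid
#' seasonality and day-of-week structure, and a multiplicative heatwave
#' effect on the log scale distributed over lags 0..3 by `lag_weights`
#' (which sum to 1, so the cumulative log relative risk injected equals
#' `beta` exactly). Between-location heterogeneity of the true effect is
#' Normal with standard deviation `beta_tau`.
#'
#' @param n_locations number of locations.
#' @param years inclusive vector of calendar years.
#' @param warm_season_months analysis season months. Default May-September.
#' @param temp_mean_annual annual mean of daily maximum temperature, degC.
#' @param temp_seasonal_amplitude amplitude of the annual cycle, degC.
#' @param temp_ar1_rho lag-1 autocorrelation of the noise, in \[0, 1).
#' @param temp_noise_sd marginal standard deviation of the AR(1) noise, degC.
#' @param baseline_daily_deaths expected deaths per day at seasonal average.
#' @param overdispersion variance/mean ratio of daily counts (>= 1; 1 is
#'   pure Poisson, above 1 uses a gamma-Poisson mixture).
#' @param mort_seasonal_amplitude log-scale amplitude of the annual
#'   mortality sinusoid (winter peak). Default 0.1.
#' @param beta_mean pooled true cumulative log relative risk.
#' @param beta_tau between-location SD of the true log relative risk.
#' @param lag_weights 4 nonnegative weights summing to 1 distributing the
#'   effect over lags 0-3.
#' @param dow_effects 7 multiplicative day-of-week factors
#'   (Monday..Sunday).
#' @param hw_percentile,hw_min_duration heatwave definition used to inject
#'   the effect (and to be recovered downstream).
#' @param seed integer seed; all outputs are deterministic given the seed.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_locations = 20L,
                       years = 2008:2017,
                       warm_season_months = 5:9,
                       temp_mean_annual = 16,
                       temp_seasonal_amplitude = 12,
                       temp_ar1_rho = 0.7,
                       temp_noise_sd = 3,
                       baseline_daily_deaths = 8,
                       overdispersion = 1.3,
                       mort_seasonal_amplitude = 0.1,
                       beta_mean = log(1.0841),
                       beta_tau = 0.03,
                       lag_weights = c(0.4, 0.3, 0.2, 0.1),
                       dow_effects = c(1.02, 0.99, 0.98, 0.99, 1.00, 1.00, 1.02),
                       hw_percentile = 92.5,
                       hw_min_duration = 2L,
                       seed = 1L) {
  fail <- function(field, msg) {
    stop("invalid `", field, "`: ", msg, call. = FALSE)
  }
  if (n_locations < 1) fail("n_locations", "must be >= 1")
  if (length(years) < 1) fail("years", "must be nonempty")
  if (!all(warm_season_months %in% 1:12)) fail("warm_season_months", "months in 1..12")
  if (temp_ar1_rho < 0 || temp_ar1_rho >= 1) fail("temp_ar1_rho", "must be in [0, 1)")
  if (temp_noise_sd < 0) fail("temp_noise_sd", "must be >= 0")
  if (baseline_daily_deaths <= 0) fail("baseline_daily_deaths", "must be > 0")
  if (overdispersion < 1) fail("overdispersion", "must be >= 1")
  if (beta_tau < 0) fail("beta_tau", "must be >= 0")
  if (any(lag_weights < 0)) fail("lag_weights", "must be nonnegative")
  if (abs(sum(lag_weights) - 1) > 1e-12) fail("lag_weights", "must sum to 1 (within 1e-12)")
  if (length(dow_effects) != 7 || any(dow_effects <= 0)) {
    fail("dow_effects", "must be 7 positive factors")
  }
  if (hw_percentile <= 0 || hw_percentile >= 100) fail("hw_percentile", "in (0, 100)")
  if (hw_min_duration < 1) fail("hw_min_duration", "must be >= 1")
  structure(as.list(environment())[setdiff(names(formals()), "")],
            class = "sim_config")
}

# deterministic per-location stream seed, kept below 2^31
location_seed <- function(config, location_id, stream = 0L) {
  (as.integer(config$seed) %% 100000L) * 10007L +
    as.integer(location_id) * 131L + as.integer(stream)
}

#' Generate one location's daily maximum temperature series
#'
#' Sinusoidal annual cycle (peak in mid-July) plus a location-specific
#' level offset and stationary AR(1) noise with marginal SD
#' `temp_noise_sd`. Covers every calendar day of the configured years, so
#' warm-season subsetting and threshold conventions are exercised
#' downstream. Deterministic given `(seed, location_id)`.
#'
#' @param config a [sim_config()].
#' @param location_id integer location index (1-based).
#' @return data.frame with columns `date`, `tmax`.
#' @export
generate_temperature <- function(config, location_id = 1L) {
  stopifnot(inherits(config, "sim_config"))
  dates <- seq(as.Date(sprintf("%d-01-01", min(config$years))),
               as.Date(sprintf("%d-12-31", max(config$years))), by = "day")
  set.seed(location_seed(config, location_id, 0L))
  offset <- stats::rnorm(1, 0, 1)
  doy <- date_yday(dates)
  seasonal <- config$temp_seasonal_amplitude *
    cos(2 * pi * (doy - 196) / 365.25)
  n <- length(dates)
  rho <- config$temp_ar1_rho
  sd_marg <- config$temp_noise_sd
  if (sd_marg > 0) {
    innov <- stats::rnorm(n, 0, sd_marg * sqrt(1 - rho^2))
    innov[1L] <- stats::rnorm(1, 0, sd_marg)
    noise <- as.numeric(stats::filter(innov, rho, method = "recursive"))
  } else {
    noise <- numeric(n)
    offset <- 0  # noise-free degenerate case: constant = configured mean
  }
  data.frame(date = dates,
             tmax = config$temp_mean_annual + offset + seasonal + noise)
}

#' Generate daily death counts with an injected heatwave effect
#'
#' Counts follow a gamma-Poisson (negative binomial) mixture whose
#' variance/mean ratio equals the configured overdispersion on every day;
#' at overdispersion 1 the counts are pure Poisson. The log mean is
#' `log(baseline) + seasonal + log(dow factor) +
#' beta * sum_l w_l HW(t - l)`, so the cumulative log relative risk of a
#' sustained heatwave equals `beta` exactly.
#'
#' @param config a [sim_config()].
#' @param dates `Date` vector (contiguous days).
#' @param hw_indicator 0/1 heatwave-day series aligned with `dates`.
#' @param beta true cumulative log relative risk for this location.
#' @param seed optional seed set before drawing (`NULL` uses the current
#'   RNG state).
#' @return Integer vector of daily deaths aligned with `dates`.
#' @export
generate_mortality <- function(config, dates, hw_indicator, beta,
                               seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(hw_indicator) != length(dates)) {
    stop("`hw_indicator` must align with `dates`", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  mu <- mortality_mean(config, dates, hw_indicator, beta)
  n <- length(mu)
  phi <- config$overdispersion
  if (phi > 1) {
    k <- mu / (phi - 1)
    mix <- stats::rgamma(n, shape = k, rate = k)
    stats::rpois(n, mu * mix)
  } else {
    stats::rpois(n, mu)
  }
}

# closed-form daily intensity of the mortality generator
mortality_mean <- function(config, dates, hw_indicator, beta) {
  dates <- as.Date(dates)
  doy <- date_yday(dates)
  seasonal <- config$mort_seasonal_amplitude *
    cos(2 * pi * (doy - 15) / 365.25)
  dow <- log(config$dow_effects[date_wday(dates)])
  w <- config$lag_weights
  n <- length(dates)
  lagged <- numeric(n)
  x <- as.numeric(hw_indicator)
  for (l in seq_along(w) - 1L) {
    if (l < n) {
      lagged[(l + 1):n] <- lagged[(l + 1):n] + w[l + 1L] * x[1:(n - l)]
    }
  }
  exp(log(config$baseline_daily_deaths) + seasonal + dow + beta * lagged)
}

#' Generate a complete synthetic study
#'
#' For each location: a full-years temperature series; the warm-season
#' percentile threshold under the configured heatwave definition;
#' detected heatwaves and the injected heatwave-day indicator; death
#' counts (total and by cause/sex/age subgroup) with that location's true
#' effect `beta_c ~ Normal(beta_mean, beta_tau^2)`; covariates (tmin,
#' tmean, relative humidity, PM2.5, O3); plus per-city annual population
#' and mortality-rate tables (with rate standard errors) and a truth
#' table. Because the injected indicator is computed with the same
#' definition used downstream, recomputing it from the written
#' temperature series reproduces it exactly.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, writes one
#'   `series_<id>.csv` per location plus `population.csv`, `rates.csv`,
#'   and `truth.csv`, and records the paths in the result.
#' @return Object of class `"sim_study"`: list with `series` (named list
#'   of per-location data.frames), `population`, `rates`, `truth`,
#'   `indicators` (injected 0/1 series over the full date index),
#'   `config`, and `files` (when written).
#' @export
generate_study <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_locations
  set.seed(as.integer(config$seed))
  beta_true <- stats::rnorm(n, config$beta_mean, config$beta_tau)
  pop_base <- round(exp(stats::rnorm(n, log(1e6), 0.4)))
  gdp_level <- sample(c("low", "medium", "high"), n, replace = TRUE)
  rate_base <- stats::rlnorm(n, log(2e-5), 0.15)  # ~7.3 per 1000 per year

  def <- heatwave_definition(percentile = config$hw_percentile,
                             min_duration = config$hw_min_duration,
                             reference_period = config$years,
                             reference_season = config$warm_season_months)
  ids <- sprintf("loc%03d", seq_len(n))
  series <- vector("list", n)
  names(series) <- ids
  indicators <- vector("list", n)
  names(indicators) <- ids
  thresholds <- numeric(n)

  for (i in seq_len(n)) {
    tmp <- generate_temperature(config, i)
    thr <- compute_threshold(tmp$date, tmp$tmax, def)
    ev <- detect_heatwaves(tmp$date, tmp$tmax, thr, def$min_duration,
                           config$warm_season_months, location_id = ids[i])
    ind <- heatwave_day_indicator(ev, tmp$date)
    deaths <- generate_mortality(config, tmp$date, ind, beta_true[i],
                                 seed = location_seed(config, i, 1L))
    set.seed(location_seed(config, i, 2L))
    nd <- length(deaths)
    cvd <- stats::rbinom(nd, deaths, 0.38)
    resp <- stats::rbinom(nd, deaths - cvd, 0.24)
    male <- stats::rbinom(nd, deaths, 0.52)
    a65 <- stats::rbinom(nd, deaths, 0.70)
    rh <- pmin(100, pmax(15, stats::rnorm(nd, 70, 10)))
    pm25 <- stats::rlnorm(nd, log(35), 0.4)
    o3 <- pmax(1, stats::rnorm(nd, 80, 20))
    tmin <- tmp$tmax - 8 + stats::rnorm(nd, 0, 1)
    series[[i]] <- data.frame(
      date = tmp$date, location_id = ids[i], deaths = deaths,
      deaths_cvd = cvd, deaths_resp = resp, deaths_other = deaths - cvd - resp,
      deaths_male = male, deaths_female = deaths - male,
      deaths_0_64 = deaths - a65, deaths_65p = a65,
      tmax = tmp$tmax, tmin = tmin, tmean = (tmp$tmax + tmin) / 2,
      rh = rh, pm25 = pm25, o3 = o3, stringsAsFactors = FALSE)
    indicators[[i]] <- ind
    thresholds[i] <- thr
  }

  years <- config$years
  population <- do.call(rbind, lapply(seq_len(n), function(i) {
    growth <- (1.01)^(seq_along(years) - 1L)
    pt <- round(pop_base[i] * growth)
    p65 <- round(pt * 0.13)
    data.frame(city_id = ids[i], year = years, pop_total = pt,
               pop_0_64 = pt - p65, pop_65p = p65,
               gdp_level = gdp_level[i], stringsAsFactors = FALSE)
  }))
  rates <- do.call(rbind, lapply(seq_len(n), function(i) {
    r_tot <- rate_base[i]
    grp <- c("total", "0_64", "65p")
    r <- c(r_tot, r_tot * 0.30 / 0.87, r_tot * 0.70 / 0.13)
    do.call(rbind, lapply(years, function(y) {
      data.frame(city_id = ids[i], year = y, group = grp, daily_rate = r,
                 daily_rate_se = 0.05 * r, stringsAsFactors = FALSE)
    }))
  }))
  truth <- data.frame(location_id = ids, beta_true = beta_true,
                      threshold = thresholds, stringsAsFactors = FALSE)

  study <- structure(list(series = series, population = population,
                          rates = rates, truth = truth,
                          indicators = indicators, config = config),
                     class = "sim_study")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character()
    for (i in seq_len(n)) {
      f <- file.path(dir, sprintf("series_%s.csv", ids[i]))
      write_table(series[[i]], f)
      files <- c(files, f)
    }
    write_table(population, file.path(dir, "population.csv"))
    write_table(rates, file.path(dir, "rates.csv"))
    write_table(truth, file.path(dir, "truth.csv"))
    study$files <- c(files, file.path(dir, c("population.csv", "rates.csv",
                                             "truth.csv")))
  }
  study
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: %d locations x %d years (seed %d); true pooled beta %.4f (tau %.3f)\n",
    x$config$n_locations, length(x$config$years), x$config$seed,
    x$config$beta_mean, x$config$beta_tau))
  invisible(x)
}
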