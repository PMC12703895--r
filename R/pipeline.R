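#' Pipeline configuration
#'
#' Builds (and validates) the single nested configuration that drives
#' [run_pipeline()]. Accepts a YAML file path or a named list; unsupplied
#' entries fall back to defaults. Sensitivity analyses (alternative lag
#' lengths, time-spline df, pollutant sets, definitions) are configuration
#' changes, not code changes.
#'
#' Structure (defaults in parentheses):
#' * `series`: character vector of daily-series CSV paths, or `NULL` when
#'   `simulate` is given.
#' * `population`, `rates`: table paths (required unless simulating).
#' * `simulate`: optional list of [sim_config()] arguments; when present
#'   the study is generated into `out_dir/sim/` and used as input.
#' * `definition`: list(`metric` ("tmax"), `percentile` (92.5),
#'   `min_duration` (2), `threshold_season` ("warm")).
#' * `model`: list(`max_lag` (3), `n_internal_knots` (2),
#'   `time_df_per_year` (4), `rh_df` (3), `pollutants` (pm25, o3)).
#' * `season_months` (5:9); `strata`: optional named mapping
#'   location -> group.
#' * `burden`: list(`target_year`, `baseline_years`, `draws` (1000),
#'   `seed` (1), `rate_group` ("total"), `pop_column` ("pop_total")).
#' * `out_dir`: output directory (required).
#'
#' @param config YAML path or named list.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    definition = list(metric = "tmax", percentile = 92.5, min_duration = 2,
                      threshold_season = "warm"),
    model = list(max_lag = 3, n_internal_knots = 2, time_df_per_year = 4,
                 rh_df = 3, pollutants = c("pm25", "o3")),
    season_months = 5:9,
    burden = list(draws = 1000, seed = 1, rate_group = "total",
                  pop_column = "pop_total",
                  target_year = NULL, baseline_years = NULL),
    strata = NULL, simulate = NULL, series = NULL,
    population = NULL, rates = NULL, out_dir = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]]) && is.list(config[[nm]])) {
      for (k in names(defaults[[nm]])) {
        if (is.null(config[[nm]][[k]])) config[[nm]][[k]] <- defaults[[nm]][[k]]
      }
    }
  }
  if (is.null(config$out_dir)) stop("config requires `out_dir`", call. = FALSE)
  if (is.null(config$simulate)) {
    for (f in c(config$series, config$population, config$rates)) {
      if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
    }
    if (is.null(config$series)) stop("config requires `series` paths", call. = FALSE)
  }
  structure(config, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Sequences the stages end to end: (optionally) simulate, detect
#' heatwaves per location, fit the location-level distributed-lag
#' quasi-Poisson models, pool cumulative effects by random-effects
#' meta-analysis (overall and by stratum), and estimate the attributable
#' burden with Monte-Carlo confidence intervals. All intermediate tables
#' are written to `out_dir` (`events.csv`, `fits.csv`, `pooled.csv`,
#' `burden_by_year.csv`, `burden_by_city.csv`, `comparison.csv`) together
#' with a provenance file (`provenance.yaml`: config hash, seed, package
#' and R versions). A failure in any stage aborts with the stage name and
#' the offending entity.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @return Invisibly, a list with `events`, `fits`, `pooled`, `burden`,
#'   and `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- inputs -----------------------------------------------------------
  if (!is.null(config$simulate)) {
    study <- stage("simulate", {
      sc <- do.call(sim_config, config$simulate)
      generate_study(sc, dir = file.path(out_dir, "sim"))
    })
    series_list <- study$series
    population <- study$population
    rates <- study$rates
  } else {
    series_list <- stage("read_series", {
      sl <- lapply(config$series, read_daily_series)
      all <- do.call(rbind, sl)
      split(all, all$location_id)
    })
    population <- stage("read_population",
                        read_population_table(config$population))
    rates <- stage("read_rates", read_rate_table(config$rates))
  }

  defn <- config$definition
  season <- config$season_months
  def <- heatwave_definition(metric = defn$metric,
                             percentile = defn$percentile,
                             min_duration = defn$min_duration,
                             reference_season = season,
                             threshold_season = defn$threshold_season)
  mod <- model_spec(
    lag_basis = lag_basis_spec(config$model$max_lag,
                               config$model$n_internal_knots),
    time_df_per_year = config$model$time_df_per_year,
    rh_df = config$model$rh_df,
    pollutants = config$model$pollutants)

  # -- detect + fit per location ---------------------------------------
  events_all <- list()
  fits <- list()
  hw_days <- list()
  for (id in names(series_list)) {
    s <- series_list[[id]]
    vals <- if (def$metric == "heat_index") {
      heat_index(s$tmean, s$rh)
    } else s[[def$metric]]
    ev <- stage(paste0("detect:", id), {
      thr <- compute_threshold(s$date, vals, def)
      detect_heatwaves(s$date, vals, thr, def$min_duration, season,
                       location_id = id)
    })
    events_all[[id]] <- ev
    in_season <- date_month(as.Date(s$date)) %in% season
    ss <- s[in_season, , drop = FALSE]
    ind <- heatwave_day_indicator(ev, as.Date(ss$date))
    fits[[id]] <- stage(paste0("fit:", id),
                        fit_location(ss, ind, mod, location_id = id))
    yrs <- date_year(as.Date(ss$date))
    es <- exposure_summary(ev, yrs)
    es$city_id <- id
    es$season_days <- as.vector(table(factor(yrs, levels = es$year)))
    hw_days[[id]] <- es
  }
  events <- do.call(rbind, events_all)
  rownames(events) <- NULL

  # -- pool -------------------------------------------------------------
  pooled <- stage("pool", {
    if (is.null(config$strata)) {
      pooled_row(pool_fits(fits, "national"))
    } else {
      pool_stratified(fits, config$strata)
    }
  })

  # -- burden -----------------------------------------------------------
  bcfg <- config$burden
  burden <- stage("burden", {
    exp_tab <- do.call(rbind, hw_days)
    nat <- pooled[pooled$group == "national", , drop = FALSE]
    r <- rates[rates$group == bcfg$rate_group, , drop = FALSE]
    inp <- merge(exp_tab[c("city_id", "year", "n_heatwave_days",
                           "season_days")],
                 population[c("city_id", "year", bcfg$pop_column)],
                 by = c("city_id", "year"))
    inp <- merge(inp, r[c("city_id", "year", "daily_rate", "daily_rate_se")],
                 by = c("city_id", "year"))
    names(inp)[names(inp) == "n_heatwave_days"] <- "hw_days"
    names(inp)[names(inp) == bcfg$pop_column] <- "pop"
    names(inp)[names(inp) == "daily_rate_se"] <- "rate_se"
    inp$beta <- nat$beta
    inp$beta_se <- nat$se
    monte_carlo_burden(inp, n_draws = bcfg$draws, seed = bcfg$seed,
                       target_year = bcfg$target_year,
                       baseline_years = bcfg$baseline_years)
  })

  # -- write ------------------------------------------------------------
  paths <- c(events = file.path(out_dir, "events.csv"),
             fits = file.path(out_dir, "fits.csv"),
             pooled = file.path(out_dir, "pooled.csv"),
             by_year = file.path(out_dir, "burden_by_year.csv"),
             by_city = file.path(out_dir, "burden_by_city.csv"))
  write_events(events, paths[["events"]])
  write_fits(fits, paths[["fits"]])
  write_table(pooled, paths[["pooled"]])
  write_table(burden$by_year, paths[["by_year"]])
  write_table(burden$by_city, paths[["by_city"]])
  if (!is.null(burden$comparison)) {
    paths[["comparison"]] <- file.path(out_dir, "comparison.csv")
    write_table(burden$comparison, paths[["comparison"]])
  }
  prov <- list(
    config_hash = unname(tools::md5sum(
      write_yaml_file(unclass(config), file.path(out_dir, "config_used.yaml")))),
    seed = bcfg$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("heatburden")))
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))

  invisible(list(events = events, fits = fits, pooled = pooled,
                 burden = burden, paths = paths))
}

write_yaml_file <- function(x, path) {
  yaml::write_yaml(x, path)
  path
}
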