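#' Attributable number of deaths
#'
#' Deaths attributable to heatwave exposure over a set of days:
#' `AN = sum_i pop * rate_i * HW_i * (1 - exp(-beta))`, where `rate_i` is
#' the daily mortality rate (deaths/person/day), `HW_i` the 0/1
#' heatwave-day indicator, and `beta` the cumulative log relative risk.
#' AN is linear in `pop` and in the rates.
#'
#' @param pop exposed population (persons, > 0).
#' @param daily_rate daily mortality rate; either one number (constant
#'   over days) or a vector aligned with `hw_indicator`.
#' @param hw_indicator 0/1 heatwave-day series.
#' @param beta cumulative log relative risk.
#' @return Attributable deaths (one number).
#' @export
attributable_number <- function(pop, daily_rate, hw_indicator, beta) {
  n <- length(hw_indicator)
  if (length(daily_rate) == 1L) daily_rate <- rep(daily_rate, n)
  if (length(daily_rate) != n) {
    stop("`daily_rate` must be scalar or aligned with `hw_indicator`",
         call. = FALSE)
  }
  sum(pop * daily_rate * hw_indicator) * (1 - exp(-beta))
}

#' Attributable fraction (per mille)
#'
#' `AF = AN / (pop * mort_s)`, expressed in deaths per 1000 warm-season
#' deaths, where `mort_s` is the cumulative warm-season mortality rate per
#' person (daily rate times the number of warm-season days), so that
#' `pop * mort_s` is the expected total number of warm-season deaths.
#'
#' @param an attributable number of deaths.
#' @param pop population (persons).
#' @param mort_s warm-season cumulative mortality rate (deaths/person per
#'   warm season).
#' @return AF in per mille. Vectorised.
#' @export
attributable_fraction <- function(an, pop, mort_s) {
  denom <- pop * mort_s
  if (any(denom <= 0)) {
    stop("`pop * mort_s` must be > 0", call. = FALSE)
  }
  an / denom * 1000
}

#' Percentage change of a target value against a baseline mean
#'
#' `(value - baseline_mean) / baseline_mean * 100`.
#'
#' @param value the target-period value.
#' @param baseline_mean the baseline-period mean (nonzero).
#' @return Percentage change. Vectorised.
#' @export
percentage_change <- function(value, baseline_mean) {
  if (any(baseline_mean == 0)) {
    stop("`baseline_mean` must be nonzero", call. = FALSE)
  }
  (value - baseline_mean) / baseline_mean * 100
}

#' Monte-Carlo burden estimation with confidence intervals
#'
#' Point estimates and Monte-Carlo 95% intervals for attributable numbers
#' (AN), attributable fractions (AF, per mille), and the percentage change
#' of a target year against a baseline-period mean. Per draw, the log
#' relative risk is sampled as `Normal(beta, beta_se^2)` (one draw per
#' distinct `beta_id`, shared by every row carrying it) and each row's
#' daily rate as `Normal(rate, rate_se^2)` truncated at zero; AN/AF and
#' the comparison are recomputed and the interval is the empirical
#' 2.5th-97.5th percentile range. Within a draw the same sampled values
#' drive the target year and the baseline years, so comparison intervals
#' reflect correlated numerator and denominator. The two-sided P-value of
#' a comparison is `2 * min(share of draws <= 0, share >= 0)` of the
#' target-minus-baseline difference.
#'
#' @param input data.frame with one row per (city, year) and columns
#'   `city_id`, `year`, `pop`, `daily_rate`, `rate_se`, `hw_days`,
#'   `season_days`, `beta`, `beta_se`, and optionally `beta_id` (defaults
#'   to one shared beta for all rows).
#' @param n_draws number of Monte-Carlo samples. Default 1000.
#' @param seed integer seed for reproducibility.
#' @param target_year,baseline_years define the comparison; `NULL` skips it.
#' @return Object of class `"burden_result"`: list with
#'   `by_year` (national AN/AF per year with CIs),
#'   `by_city` (per city-year AN with CIs),
#'   `comparison` (target vs baseline AN and AF percentage change, CIs,
#'   P-values), `n_draws`, and `seed`.
#' @export
monte_carlo_burden <- function(input, n_draws = 1000L, seed = 1L,
                               target_year = NULL, baseline_years = NULL) {
  req <- c("city_id", "year", "pop", "daily_rate", "rate_se", "hw_days",
           "season_days", "beta", "beta_se")
  miss <- setdiff(req, names(input))
  if (length(miss)) {
    stop("`input` lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(input[req])) stop("`input` contains missing values", call. = FALSE)
  if (anyDuplicated(input[c("city_id", "year")])) {
    stop("duplicate (city_id, year) rows in `input`", call. = FALSE)
  }
  if (is.null(input$beta_id)) input$beta_id <- "pooled"
  n <- nrow(input)
  set.seed(as.integer(seed))

  bid <- factor(input$beta_id)
  beta_map <- tapply(seq_len(n), bid, function(i) i[1L])
  beta_pt <- input$beta[unlist(beta_map)]
  beta_se_pt <- input$beta_se[unlist(beta_map)]
  # draws: rows = draws, cols = distinct betas
  z_beta <- matrix(stats::rnorm(n_draws * nlevels(bid)), n_draws)
  beta_draw <- sweep(sweep(z_beta, 2, beta_se_pt, "*"), 2, beta_pt, "+")
  rate_draw <- matrix(stats::rnorm(n_draws * n), n_draws) *
    rep(input$rate_se, each = n_draws) + rep(input$daily_rate, each = n_draws)
  rate_draw[rate_draw < 0] <- 0

  risk_pt <- 1 - exp(-input$beta)
  an_pt <- input$pop * input$daily_rate * input$hw_days * risk_pt
  deaths_pt <- input$pop * input$daily_rate * input$season_days

  risk_draw <- 1 - exp(-beta_draw[, as.integer(bid), drop = FALSE])
  scale_row <- rep(input$pop * input$hw_days, each = n_draws)
  an_draw <- matrix(scale_row, n_draws) * rate_draw * risk_draw
  deaths_draw <- matrix(rep(input$pop * input$season_days, each = n_draws),
                        n_draws) * rate_draw

  ci <- function(m) apply(m, 2, stats::quantile, probs = c(0.025, 0.975),
                          names = FALSE)

  # per city-year
  city_ci <- apply(an_draw, 2, stats::quantile, probs = c(0.025, 0.975),
                   names = FALSE)
  by_city <- data.frame(city_id = input$city_id, year = input$year,
                        an = an_pt, an_lo = city_ci[1L, ],
                        an_hi = city_ci[2L, ], stringsAsFactors = FALSE)

  # national by year (sum ANs per draw; AF from summed AN over summed deaths)
  yr <- factor(input$year)
  an_year_pt <- as.vector(tapply(an_pt, yr, sum))
  deaths_year_pt <- as.vector(tapply(deaths_pt, yr, sum))
  an_year_draw <- t(rowsum(t(an_draw), yr))
  deaths_year_draw <- t(rowsum(t(deaths_draw), yr))
  af_year_pt <- an_year_pt / deaths_year_pt * 1000
  af_year_draw <- an_year_draw / deaths_year_draw * 1000
  an_ci <- ci(an_year_draw)
  af_ci <- ci(af_year_draw)
  by_year <- data.frame(
    year = as.integer(levels(yr)),
    an = an_year_pt, an_lo = an_ci[1L, ], an_hi = an_ci[2L, ],
    af_permille = af_year_pt, af_lo = af_ci[1L, ], af_hi = af_ci[2L, ],
    stringsAsFactors = FALSE)

  comparison <- NULL
  if (!is.null(target_year) && !is.null(baseline_years)) {
    missing_years <- setdiff(c(target_year, baseline_years), by_year$year)
    if (length(missing_years)) {
      stop("comparison years absent from input: ",
           paste(missing_years, collapse = ", "), call. = FALSE)
    }
    ti <- match(target_year, by_year$year)
    bi <- match(baseline_years, by_year$year)
    comp_one <- function(pt, draws, label) {
      base_pt <- mean(pt[bi])
      base_draw <- rowMeans(draws[, bi, drop = FALSE])
      pc_pt <- percentage_change(pt[ti], base_pt)
      pc_draw <- (draws[, ti] - base_draw) / base_draw * 100
      diff_draw <- draws[, ti] - base_draw
      p <- 2 * min(mean(diff_draw <= 0), mean(diff_draw >= 0))
      q <- stats::quantile(pc_draw, c(0.025, 0.975), names = FALSE)
      data.frame(measure = label, target = pt[ti], baseline_mean = base_pt,
                 pct_change = pc_pt, pc_lo = q[1L], pc_hi = q[2L],
                 p = min(1, p), stringsAsFactors = FALSE)
    }
    comparison <- rbind(
      comp_one(an_year_pt, an_year_draw, "an"),
      comp_one(af_year_pt, af_year_draw, "af_permille"))
  }

  structure(list(by_year = by_year, by_city = by_city,
                 comparison = comparison, n_draws = n_draws, seed = seed),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("Burden over %d year(s), %d city-years, %d Monte-Carlo draws\n",
              nrow(x$by_year), nrow(x$by_city), x$n_draws))
  print(utils::head(x$by_year, 5))
  if (!is.null(x$comparison)) {
    cat("Comparison (target vs baseline mean):\n")
    print(x$comparison)
  }
  invisible(x)
}

#' Aggregate city-level point burdens
#'
#' Sums attributable numbers over cities within grouping keys and
#' recomputes AF from the summed AN over the summed expected warm-season
#' deaths (never by averaging per-city AFs).
#'
#' @param input as in [monte_carlo_burden()]; `by` names grouping columns
#'   (e.g. `"year"`, or `c("province", "year")`).
#' @param by character vector of grouping column names present in `input`.
#' @return data.frame with the grouping keys, `an`, `deaths`,
#'   `af_permille`.
#' @export
aggregate_burden <- function(input, by = "year") {
  if (anyDuplicated(input[c("city_id", "year")])) {
    stop("duplicate (city_id, year) rows in `input`", call. = FALSE)
  }
  an <- input$pop * input$daily_rate * input$hw_days * (1 - exp(-input$beta))
  deaths <- input$pop * input$daily_rate * input$season_days
  key <- interaction(input[by], drop = TRUE, sep = "\r")
  out <- unique(input[by])
  out <- out[match(levels(key), do.call(paste, c(out, sep = "\r"))), ,
             drop = FALSE]
  out$an <- as.vector(tapply(an, key, sum))
  out$deaths <- as.vector(tapply(deaths, key, sum))
  out$af_permille <- out$an / out$deaths * 1000
  rownames(out) <- NULL
  out
}

#' Annual linear trend
#'
#' Ordinary least-squares slope of an annual series on calendar year, with
#' the two-sided t-test of the slope.
#'
#' @param years calendar years (>= 3).
#' @param values annual values aligned with `years`.
#' @return list with `slope` (per year), `se`, `p_value`, `intercept`.
#' @export
annual_trend <- function(years, values) {
  if (length(years) < 3L) stop("need >= 3 years for a trend", call. = FALSE)
  fit <- stats::lm(values ~ years)
  # suppress the "essentially perfect fit" note for degenerate exact lines
  s <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(s["years", "Estimate"]),
       se = unname(s["years", "Std. Error"]),
       p_value = unname(s["years", "Pr(>|t|)"]),
       intercept = unname(s["(Intercept)", "Estimate"]))
}
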