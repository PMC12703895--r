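#' Lag-basis specification
#'
#' Describes the spline basis spanning the lag-response curve of a binary
#' heatwave exposure over lags `0..max_lag`: a natural cubic spline with
#' `n_internal_knots` internal knots placed at exponentials of equally
#' spaced points between `log(1)` and `log(max_lag)` (the usual log-knot
#' convention for distributed-lag bases; boundary knots at 0 and
#' `max_lag`), optionally preceded by a constant (intercept) column.
#' `n_internal_knots = NULL` drops the spline part entirely and keeps only
#' the constant column, which constrains the lag distribution to be
#' uniform: the cross-basis then reduces to a moving sum of the exposure.
#'
#' @param max_lag maximum lag in days (>= 1). Default 3.
#' @param n_internal_knots number of internal knots (default 2), or `NULL`
#'   for the constant-only basis.
#' @param include_intercept prepend an all-ones column. Default `TRUE`.
#' @return Object of class `"lag_basis_spec"`.
#' @export
lag_basis_spec <- function(max_lag = 3L, n_internal_knots = 2L,
                           include_intercept = TRUE) {
  if (!is.numeric(max_lag) || max_lag < 1 || max_lag != round(max_lag)) {
    stop("`max_lag` must be a whole number >= 1", call. = FALSE)
  }
  if (is.null(n_internal_knots)) {
    if (!include_intercept) {
      stop("constant-only basis (`n_internal_knots = NULL`) requires an intercept",
           call. = FALSE)
    }
  } else {
    if (n_internal_knots < 0 || n_internal_knots != round(n_internal_knots)) {
      stop("`n_internal_knots` must be a whole number >= 0", call. = FALSE)
    }
    df <- n_internal_knots + 1L + as.integer(include_intercept)
    if (df > max_lag + 1L) {
      stop("lag basis has more columns (", df, ") than lags (", max_lag + 1L,
           "); reduce `n_internal_knots`", call. = FALSE)
    }
  }
  structure(list(max_lag = as.integer(max_lag),
                 n_internal_knots = if (is.null(n_internal_knots)) NULL
                                    else as.integer(n_internal_knots),
                 include_intercept = isTRUE(include_intercept)),
            class = "lag_basis_spec")
}

#' Lag basis matrix
#'
#' Evaluates the lag basis at integer lags `0..max_lag`. Rows index lags,
#' columns index basis functions; the first column is all ones when the
#' spec includes an intercept.
#'
#' @param spec a [lag_basis_spec()].
#' @return Numeric matrix with `max_lag + 1` rows.
#' @export
lag_basis <- function(spec = lag_basis_spec()) {
  stopifnot(inherits(spec, "lag_basis_spec"))
  lags <- 0:spec$max_lag
  cols <- list()
  if (spec$include_intercept) cols$int <- rep(1, length(lags))
  if (!is.null(spec$n_internal_knots)) {
    k <- spec$n_internal_knots
    knots <- if (k > 0) {
      exp(log(spec$max_lag) * seq_len(k) / (k + 1))
    } else NULL
    sp <- splines::ns(lags, knots = knots,
                      Boundary.knots = c(0, spec$max_lag))
    colnames(sp) <- paste0("s", seq_len(ncol(sp)))
    cols$sp <- sp
  }
  B <- do.call(cbind, cols)
  colnames(B) <- c(if (spec$include_intercept) "int",
                   if (!is.null(spec$n_internal_knots))
                     paste0("s", seq_len(ncol(B) - spec$include_intercept)))
  rownames(B) <- paste0("lag", lags)
  B
}

#' Cross-basis of a binary exposure with the lag basis
#'
#' Column `j` of the cross-basis at day `t` is
#' `sum_l B[l, j] * HW(t - l)`: the exposure history convolved with the
#' `j`-th lag-basis function. Lags never reach across the start of a
#' season block — days before the block contribute zero (zero-padding), so
#' the design stays balanced at the first days of each warm season.
#'
#' @param indicator 0/1 exposure series.
#' @param spec a [lag_basis_spec()].
#' @param blocks optional vector (same length) labelling contiguous season
#'   blocks; `NULL` treats the whole series as one block.
#' @return Matrix `length(indicator) x df` with attributes `lag_basis`
#'   (the matrix B) and `spec`.
#' @export
cross_basis <- function(indicator, spec = lag_basis_spec(), blocks = NULL) {
  stopifnot(inherits(spec, "lag_basis_spec"))
  x <- as.numeric(indicator)
  if (anyNA(x)) stop("`indicator` must not contain NA", call. = FALSE)
  n <- length(x)
  if (is.null(blocks)) blocks <- rep(1L, n)
  if (length(blocks) != n) {
    stop("`blocks` must align with `indicator`", call. = FALSE)
  }
  B <- lag_basis(spec)
  L <- spec$max_lag
  # lagged copies of x, zero-padded at each block start
  lagmat <- matrix(0, n, L + 1L)
  for (b in unique(blocks)) {
    sel <- which(blocks == b)
    xb <- x[sel]
    nb <- length(xb)
    for (l in 0:L) {
      if (l < nb) {
        lagmat[sel[(l + 1):nb], l + 1L] <-
          lagmat[sel[(l + 1):nb], l + 1L] + xb[1:(nb - l)]
      }
    }
  }
  Q <- lagmat %*% B
  colnames(Q) <- paste0("b", seq_len(ncol(Q)))
  attr(Q, "lag_basis") <- B
  attr(Q, "spec") <- spec
  Q
}

#' Model specification for location-level regressions
#'
#' Covariate structure of the quasi-Poisson model: the heatwave
#' cross-basis, a natural cubic spline of calendar time with
#' `time_df_per_year` df per year (df rounded to the nearest integer over
#' the observed span) absorbing seasonality and long-term trends, a
#' natural cubic spline of relative humidity with `rh_df` df, linear terms
#' for the selected pollutants, and a day-of-week factor.
#'
#' @param lag_basis a [lag_basis_spec()].
#' @param time_df_per_year df per year for the time spline (>= 1). Default 4.
#' @param rh_df df for the humidity spline (>= 1; 0 omits it). Default 3.
#' @param pollutants subset of `c("pm25", "o3")` entered linearly.
#' @param dow include the day-of-week factor. Default `TRUE`.
#' @return Object of class `"hw_model_spec"`.
#' @export
model_spec <- function(lag_basis = lag_basis_spec(), time_df_per_year = 4,
                       rh_df = 3, pollutants = c("pm25", "o3"), dow = TRUE) {
  stopifnot(inherits(lag_basis, "lag_basis_spec"))
  if (time_df_per_year < 1) stop("`time_df_per_year` must be >= 1", call. = FALSE)
  if (rh_df < 0) stop("`rh_df` must be >= 0", call. = FALSE)
  if (length(pollutants) && !all(pollutants %in% c("pm25", "o3"))) {
    stop("`pollutants` must be a subset of c('pm25', 'o3')", call. = FALSE)
  }
  structure(list(lag_basis = lag_basis, time_df_per_year = time_df_per_year,
                 rh_df = rh_df, pollutants = pollutants, dow = isTRUE(dow)),
            class = "hw_model_spec")
}

#' Fit the location-level distributed-lag model
#'
#' Quasi-Poisson (log link, variance proportional to the mean) regression
#' of daily deaths on the heatwave cross-basis plus the covariates of the
#' [model_spec()]. The cumulative log relative risk over lags
#' `0..max_lag` is the reduction `beta_cum = u' eta` with
#' `u_j = sum_l B[l, j]`, where `eta` are the cross-basis coefficients;
#' its variance is `u' V u` with `V` the dispersion-scaled covariance
#' block. Dispersion is the Pearson chi-square / residual df estimator.
#'
#' @param series data.frame with columns `date`, the outcome column, and
#'   any covariates the spec needs (`rh`, `pm25`, `o3`). Rows should be the
#'   warm-season days; season blocks are inferred from gaps in `date`.
#' @param indicator 0/1 heatwave-day series aligned with `series$date`.
#' @param model a [model_spec()].
#' @param outcome name of the death-count column. Default `"deaths"`.
#' @param location_id identifier carried into the result.
#' @return Object of class `"location_fit"`: list with `location_id`,
#'   `beta_cum`, `var_beta_cum`, `se`, `dispersion`, `qaic`, `n_days`,
#'   `n_hw_days`, `beta_by_lag` (lag-specific log-RRs, summing to
#'   `beta_cum`), and `n_coef`. Returns `NULL` with a warning when the
#'   exposure is degenerate (no heatwave days).
#' @export
fit_location <- function(series, indicator, model = model_spec(),
                         outcome = "deaths", location_id = NA_character_) {
  stopifnot(inherits(model, "hw_model_spec"))
  if (!outcome %in% names(series)) {
    stop("outcome column `", outcome, "` not found", call. = FALSE)
  }
  if (length(indicator) != nrow(series)) {
    stop("`indicator` must align with `series` rows", call. = FALSE)
  }
  y <- series[[outcome]]
  if (any(y < 0, na.rm = TRUE)) stop("deaths must be nonnegative", call. = FALSE)
  if (sum(indicator) == 0) {
    warning("no heatwave days for location ", location_id, "; fit skipped",
            call. = FALSE)
    return(NULL)
  }
  dates <- as.Date(series$date)
  blocks <- cumsum(c(1L, as.integer(diff(dates) != 1L)))
  cb <- cross_basis(indicator, model$lag_basis, blocks = blocks)
  B <- attr(cb, "lag_basis")

  n_years <- length(unique(date_year(dates)))
  time_df <- max(1L, round(model$time_df_per_year * n_years))
  tnum <- as.numeric(dates)

  dat <- data.frame(.y = y)
  terms <- "cb"
  env <- environment()
  if (model$rh_df > 0) {
    if (!"rh" %in% names(series)) stop("series lacks `rh`", call. = FALSE)
    dat$rh <- series$rh
    terms <- c(terms, sprintf("splines::ns(rh, df = %d)", model$rh_df))
  }
  dat$.t <- tnum
  terms <- c(terms, sprintf("splines::ns(.t, df = %d)", time_df))
  if (model$dow) {
    dat$.dow <- factor(date_wday(dates), levels = 1:7)
    terms <- c(terms, ".dow")
  }
  for (p in model$pollutants) {
    if (!p %in% names(series)) stop("series lacks `", p, "`", call. = FALSE)
    dat[[p]] <- series[[p]]
    terms <- c(terms, p)
  }
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")),
                           env = env)
  fit <- stats::glm(fml, family = stats::quasipoisson(), data = dat,
                    na.action = stats::na.exclude)
  if (!fit$converged) {
    stop("quasi-Poisson fit failed to converge for location ", location_id,
         call. = FALSE)
  }
  cf <- stats::coef(fit)
  cb_idx <- grep("^cb", names(cf))
  if (anyNA(cf[cb_idx])) {
    stop("aliased cross-basis coefficients for location ", location_id,
         call. = FALSE)
  }
  eta <- cf[cb_idx]
  dispersion <- sum(stats::residuals(fit, type = "pearson")^2, na.rm = TRUE) /
    fit$df.residual
  V_all <- summary(fit)$cov.scaled
  V <- V_all[cb_idx, cb_idx, drop = FALSE]
  u <- colSums(B)
  beta_cum <- drop(u %*% eta)
  var_beta_cum <- drop(u %*% V %*% u)
  beta_by_lag <- drop(B %*% eta)

  mu <- stats::fitted(fit)
  ll <- sum(stats::dpois(y[!is.na(y)], mu[!is.na(y)], log = TRUE))
  k <- sum(!is.na(cf))
  qaic_val <- -2 * ll / dispersion + 2 * k

  structure(list(
    location_id = location_id,
    beta_cum = beta_cum, var_beta_cum = var_beta_cum,
    se = sqrt(var_beta_cum),
    beta_by_lag = beta_by_lag,
    dispersion = dispersion, qaic = qaic_val,
    n_days = sum(!is.na(y)), n_hw_days = sum(indicator),
    n_coef = k, loglik_poisson = ll
  ), class = "location_fit")
}

#' @export
print.location_fit <- function(x, ...) {
  cat(sprintf(
    "location %s: beta_cum = %.4f (se %.4f), dispersion %.2f, qAIC %.1f, %d days (%d heatwave)\n",
    x$location_id, x$beta_cum, x$se, x$dispersion, x$qaic, x$n_days, x$n_hw_days))
  invisible(x)
}

#' Excess risk from a log relative risk
#'
#' `ER = (exp(beta) - 1) * 100` percent, with the 95% Wald interval
#' `(exp(beta +- 1.96 sqrt(var)) - 1) * 100`.
#'
#' @param beta cumulative log relative risk.
#' @param var its variance (>= 0). Default 0 gives a degenerate interval.
#' @return data.frame with `er`, `er_lo`, `er_hi` (percent). Vectorised.
#' @export
excess_risk <- function(beta, var = 0) {
  if (any(var < 0)) stop("`var` must be >= 0", call. = FALSE)
  se <- sqrt(var)
  data.frame(er = (exp(beta) - 1) * 100,
             er_lo = (exp(beta - 1.96 * se) - 1) * 100,
             er_hi = (exp(beta + 1.96 * se) - 1) * 100)
}

#' Quasi-AIC
#'
#' `qAIC = -2 * loglik / dispersion + 2 * k`, the quasi-likelihood
#' analogue of AIC for quasi-Poisson fits: the Poisson log-likelihood at
#' the fitted means, penalised by the dispersion. At dispersion 1 this is
#' the ordinary AIC. `k` counts estimated (non-aliased) coefficients, so a
#' rank-deficient duplicate column does not change the score; this
#' rank-deficiency convention is deliberate and documented here.
#'
#' @param loglik Poisson log-likelihood at the fitted means.
#' @param k number of estimated coefficients.
#' @param dispersion quasi-Poisson dispersion estimate (> 0).
#' @return The qAIC score (lower is better).
#' @export
qaic <- function(loglik, k, dispersion = 1) {
  if (dispersion <= 0) stop("`dispersion` must be > 0", call. = FALSE)
  -2 * loglik / dispersion + 2 * k
}

#' Compare candidate heatwave definitions by qAIC
#'
#' Fits the location-level model under each candidate definition (each a
#' percentile / minimum-duration pair, optionally with its own metric) and
#' ranks definitions by qAIC, ties broken by lower percentile then shorter
#' duration. Candidates producing no heatwave days get `NA` and rank last.
#'
#' @param series daily series for one location (see [fit_location()]),
#'   including the metric column(s) the candidates refer to.
#' @param candidates data.frame with columns `percentile`, `min_duration`,
#'   and optionally `metric` (default `"tmax"`).
#' @param model a [model_spec()].
#' @param season_months analysis season. Default May-September.
#' @param outcome death-count column name.
#' @return data.frame of candidates with `threshold`, `n_hw_days`, `qaic`,
#'   and `rank`; attribute `best` holds the top row.
#' @export
select_definition <- function(series, candidates, model = model_spec(),
                              season_months = 5:9, outcome = "deaths") {
  if (nrow(candidates) < 1L) stop("need >= 1 candidate", call. = FALSE)
  if (is.null(candidates$metric)) candidates$metric <- "tmax"
  dates <- as.Date(series$date)
  res <- candidates
  res$threshold <- NA_real_
  res$n_hw_days <- NA_real_
  res$qaic <- NA_real_
  season <- series[date_month(dates) %in% season_months, , drop = FALSE]
  sdates <- as.Date(season$date)
  for (i in seq_len(nrow(candidates))) {
    def <- heatwave_definition(metric = candidates$metric[i],
                               percentile = candidates$percentile[i],
                               min_duration = candidates$min_duration[i],
                               reference_season = season_months)
    vals <- series[[def$metric]]
    thr <- compute_threshold(dates, vals, def)
    ev <- detect_heatwaves(dates, vals, thr, def$min_duration, season_months)
    ind <- heatwave_day_indicator(ev, sdates)
    res$threshold[i] <- thr
    res$n_hw_days[i] <- sum(ind)
    if (sum(ind) == 0) next
    f <- suppressWarnings(
      fit_location(season, ind, model, outcome = outcome))
    if (!is.null(f)) res$qaic[i] <- f$qaic
  }
  if (all(is.na(res$qaic))) {
    stop("all candidate definitions are degenerate (no heatwave days)",
         call. = FALSE)
  }
  ord <- order(res$qaic, res$percentile, res$min_duration, na.last = TRUE)
  res$rank <- match(seq_len(nrow(res)), ord)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res$rank <- seq_len(nrow(res))
  attr(res, "best") <- res[1L, , drop = FALSE]
  res
}
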