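#' Random-effects pooling of location-level effects
#'
#' DerSimonian-Laird (method-of-moments) random-effects meta-analysis of
#' the cumulative log relative risks. With inverse-variance weights
#' `w_i = 1/v_i`, the fixed-effect mean is `bFE = sum(w b) / sum(w)`,
#' Cochran's `Q = sum(w (b - bFE)^2)`, the between-location variance is
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))`, and the
#' pooled estimate uses random-effects weights `1 / (v_i + tau2)`.
#' Heterogeneity is summarised by `I2 = max(0, (Q - df)/Q) * 100`.
#' When `Q <= k - 1`, `tau2 = 0` and the pooled estimate equals the
#' fixed-effect one exactly.
#'
#' @param fits either a list of `"location_fit"` objects or a data.frame
#'   with columns `beta_cum` and `var_beta_cum` (or `se`), plus optionally
#'   `location_id`.
#' @param group_label label carried into the result. Default `"overall"`.
#' @return Object of class `"pooled_effect"`: list with `group_label`,
#'   `beta`, `se`, `tau2`, `Q`, `df`, `I2`, `k`, and the excess-risk
#'   summary `er`, `er_lo`, `er_hi` (percent).
#' @export
pool_fits <- function(fits, group_label = "overall") {
  d <- as_fit_frame(fits)
  k <- nrow(d)
  if (k < 2L) stop("pooling requires k >= 2 locations", call. = FALSE)
  if (any(d$var_beta_cum <= 0)) {
    bad <- d$location_id[d$var_beta_cum <= 0]
    stop("nonpositive variance for location(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  b <- d$beta_cum
  v <- d$var_beta_cum
  w <- 1 / v
  b_fe <- sum(w * b) / sum(w)
  Q <- sum(w * (b - b_fe)^2)
  df <- k - 1L
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  w_re <- 1 / (v + tau2)
  beta <- sum(w_re * b) / sum(w_re)
  se <- sqrt(1 / sum(w_re))
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  er <- excess_risk(beta, se^2)
  structure(list(group_label = group_label, beta = beta, se = se,
                 tau2 = tau2, Q = Q, df = df, I2 = I2, k = k,
                 er = er$er, er_lo = er$er_lo, er_hi = er$er_hi),
            class = "pooled_effect")
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf(
    "%s (k = %d): beta = %.4f (se %.4f); ER %.2f%% (%.2f to %.2f)\n  Q = %.2f on %d df, I2 = %.1f%%, tau2 = %.5f\n",
    x$group_label, x$k, x$beta, x$se, x$er, x$er_lo, x$er_hi,
    x$Q, x$df, x$I2, x$tau2))
  invisible(x)
}

#' Stratified pooling with an excess-risk table
#'
#' Pools location fits within each stratum (and overall as `"national"`),
#' returning one row per stratum with the pooled effect, heterogeneity
#' statistics, and excess risk. Strata with a single location are reported
#' unpooled with a warning (their `tau2`, `Q`, `I2` are `NA`).
#'
#' @param fits as in [pool_fits()].
#' @param strata vector mapping each fit to a stratum label (recycled
#'   against the fits by position), or a named vector/list keyed by
#'   `location_id`.
#' @param include_overall add a `"national"` row pooling everything.
#' @return data.frame with columns `group`, `k`, `beta`, `se`, `tau2`,
#'   `Q`, `I2`, `er`, `er_lo`, `er_hi`.
#' @export
pool_stratified <- function(fits, strata, include_overall = TRUE) {
  d <- as_fit_frame(fits)
  if (!is.null(names(strata)) && !is.null(d$location_id)) {
    strata <- unlist(strata)[as.character(d$location_id)]
  }
  if (length(strata) != nrow(d)) {
    stop("`strata` must map every fit to a stratum", call. = FALSE)
  }
  groups <- unique(as.character(strata))
  rows <- list()
  if (include_overall) {
    p <- pool_fits(d, "national")
    rows[["national"]] <- pooled_row(p)
  }
  for (g in sort(groups)) {
    dg <- d[strata == g, , drop = FALSE]
    if (nrow(dg) < 2L) {
      warning("stratum '", g, "' has a single location; reported unpooled",
              call. = FALSE)
      er <- excess_risk(dg$beta_cum, dg$var_beta_cum)
      rows[[g]] <- data.frame(
        group = g, k = 1L, beta = dg$beta_cum,
        se = sqrt(dg$var_beta_cum), tau2 = NA_real_, Q = NA_real_,
        I2 = NA_real_, er = er$er, er_lo = er$er_lo, er_hi = er$er_hi,
        stringsAsFactors = FALSE)
    } else {
      rows[[g]] <- pooled_row(pool_fits(dg, g))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pooled_row <- function(p) {
  data.frame(group = p$group_label, k = p$k, beta = p$beta, se = p$se,
             tau2 = p$tau2, Q = p$Q, I2 = p$I2,
             er = p$er, er_lo = p$er_lo, er_hi = p$er_hi,
             stringsAsFactors = FALSE)
}

as_fit_frame <- function(fits) {
  if (is.data.frame(fits)) {
    d <- fits
    if (is.null(d$var_beta_cum)) {
      if (is.null(d$se)) stop("need `var_beta_cum` or `se`", call. = FALSE)
      d$var_beta_cum <- d$se^2
    }
  } else {
    fits <- Filter(Negate(is.null), fits)
    d <- data.frame(
      location_id = vapply(fits, function(f) as.character(f$location_id),
                           character(1)),
      beta_cum = vapply(fits, function(f) f$beta_cum, numeric(1)),
      var_beta_cum = vapply(fits, function(f) f$var_beta_cum, numeric(1)),
      stringsAsFactors = FALSE)
  }
  if (is.null(d$location_id)) d$location_id <- seq_len(nrow(d))
  d
}
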