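test_that("lag basis has the documented shape and an all-ones intercept column", {
  B <- lag_basis(lag_basis_spec())
  expect_equal(dim(B), c(4L, 4L))
  expect_true(all(B[, 1] == 1))
  # spline columns evaluated at integer lags 0..3 with log-placed knots
  expect_equal(qr(B)$rank, 4L)
  expect_error(lag_basis_spec(max_lag = 3, n_internal_knots = 4), "columns")
})

test_that("zero-knot basis without intercept is linear in the lag up to affine scale", {
  B <- lag_basis(lag_basis_spec(n_internal_knots = 0, include_intercept = FALSE))
  expect_equal(ncol(B), 1L)
  fit <- stats::lm(B[, 1] ~ c(0:3))
  expect_equal(unname(stats::fitted(fit)), unname(B[, 1]), tolerance = 1e-10)
})

test_that("natural spline columns are linear beyond the boundary knots", {
  # evaluate the same log-knot basis on a fine grid extending past both
  # boundaries; second differences must vanish outside [0, max_lag]
  knots <- exp(log(3) * (1:2) / 3)
  x <- seq(-2, 5, by = 0.05)
  S <- splines::ns(x, knots = knots, Boundary.knots = c(0, 3))
  n <- length(x)
  # second difference at i spans x[i..i+2]; test triplets fully outside
  fully_out <- x[3:n] < 0 | x[1:(n - 2)] > 3
  for (j in seq_len(ncol(S))) {
    d2 <- diff(S[, j], differences = 2)
    expect_lt(max(abs(d2[fully_out])), 1e-8)
  }
})

test_that("constant-only lag basis makes the cross-basis a moving sum", {
  spec <- lag_basis_spec(n_internal_knots = NULL)
  ind <- c(0, 0, 1, 1, 0, 0, 0, 1, 0, 0)
  cb <- cross_basis(ind, spec)
  ms <- vapply(seq_along(ind),
               function(t) sum(ind[max(1, t - 3):t]), numeric(1))
  expect_equal(unname(cb[, 1]), ms)
})

test_that("cross-basis is zero for a zero indicator and convolves one HW day correctly", {
  spec <- lag_basis_spec()
  expect_true(all(cross_basis(integer(30), spec) == 0))
  ind <- integer(30); ind[10] <- 1L
  cb <- cross_basis(ind, spec)
  B <- attr(cb, "lag_basis")
  expect_equal(unname(cb[10:13, 1]), rep(1, 4))  # intercept column
  expect_true(all(cb[-(10:13), 1] == 0))
  for (j in 1:4) expect_equal(unname(cb[10:13, j]), unname(B[, j]))
})

test_that("lags do not leak across season-block starts", {
  ind <- c(0, 0, 0, 1, 1, 0, 0, 0, 0, 0)
  blocks <- rep(1:2, each = 5)
  cb <- cross_basis(ind, lag_basis_spec(), blocks = blocks)
  expect_true(all(cb[6:10, ] == 0))  # block 2 unaffected by block-1 exposure
  cb1 <- cross_basis(ind[1:5], lag_basis_spec())
  expect_equal(unname(cb[1:5, ]), unname(cb1[, ]))
})

test_that("fit reduction identity holds and matches the moving-sum GLM oracle", {
  cfg <- sim_config(n_locations = 1, years = 2010:2014, seed = 77)
  st <- generate_study(cfg)
  sl <- season_slice(st, 1)
  skip_if(sum(sl$indicator) == 0)

  # reduction identity: cumulative = sum of lag-specific log-RRs
  f <- fit_location(sl$series, sl$indicator, model_spec(), location_id = "x")
  expect_equal(sum(f$beta_by_lag), f$beta_cum, tolerance = 1e-12)

  # with a constant-only lag basis the model is a GLM on the 4-day moving
  # sum of the indicator (zero-padded at season starts): independent oracle
  mod <- model_spec(lag_basis = lag_basis_spec(n_internal_knots = NULL))
  f0 <- fit_location(sl$series, sl$indicator, mod, location_id = "x")
  s <- sl$series
  dates <- as.Date(s$date)
  blocks <- cumsum(c(1L, as.integer(diff(dates) != 1L)))
  ms <- numeric(nrow(s))
  for (b in unique(blocks)) {
    i <- which(blocks == b)
    for (l in 0:3) {
      if (l < length(i)) {
        ms[i[(l + 1):length(i)]] <- ms[i[(l + 1):length(i)]] +
          sl$indicator[i[1:(length(i) - l)]]
      }
    }
  }
  n_years <- length(unique(as.integer(format(dates, "%Y"))))
  dow <- factor(heatburden:::date_wday(dates), levels = 1:7)
  tnum <- as.numeric(dates)
  oracle <- stats::glm(
    s$deaths ~ ms + splines::ns(s$rh, df = 3) +
      splines::ns(tnum, df = round(4 * n_years)) + dow + s$pm25 + s$o3,
    family = stats::quasipoisson())
  expect_equal(f0$beta_cum, 4 * unname(stats::coef(oracle)["ms"]),
               tolerance = 1e-6)
})

test_that("dispersion estimate is near 1 for Poisson-generated data", {
  cfg <- sim_config(n_locations = 10, years = 2010:2014, overdispersion = 1,
                    seed = 55)
  st <- generate_study(cfg)
  disp <- c()
  for (i in 1:10) {
    sl <- season_slice(st, i)
    if (sum(sl$indicator) == 0) next
    f <- fit_location(sl$series, sl$indicator, model_spec(), location_id = i)
    disp <- c(disp, f$dispersion)
  }
  expect_equal(mean(disp), 1, tolerance = 0.05)
})

test_that("degenerate exposure is skipped with a warning", {
  cfg <- sim_config(n_locations = 1, years = 2010:2012, seed = 5)
  st <- generate_study(cfg)
  sl <- season_slice(st, 1)
  expect_warning(out <- fit_location(sl$series, integer(nrow(sl$series)),
                                     model_spec(), location_id = "z"),
                 "no heatwave days")
  expect_null(out)
})

test_that("excess risk transforms the log relative risk as (exp(beta)-1)x100", {
  expect_equal(excess_risk(0)$er, 0)
  er <- excess_risk(log(1.0841), 0)
  expect_equal(er$er, 8.41, tolerance = 1e-10)
  b <- seq(-0.2, 0.3, by = 0.01)
  expect_true(all(diff(excess_risk(b)$er) > 0))
  er2 <- excess_risk(0.1, 0.04)
  expect_equal(er2$er_lo, (exp(0.1 - 1.96 * 0.2) - 1) * 100)
  expect_equal(er2$er_hi, (exp(0.1 + 1.96 * 0.2) - 1) * 100)
})

test_that("qAIC reduces to AIC at dispersion 1", {
  set.seed(8)
  y <- stats::rpois(200, 5)
  x <- stats::rnorm(200)
  fit <- stats::glm(y ~ x, family = stats::poisson())
  expect_equal(qaic(as.numeric(stats::logLik(fit)), 2, 1), stats::AIC(fit))
  expect_error(qaic(-100, 2, 0), "dispersion")
})

test_that("definition selection ranks by qAIC with documented tie-breaking", {
  cfg <- sim_config(n_locations = 1, years = 2010:2015, seed = 21)
  st <- generate_study(cfg)
  s <- st$series[[1]]
  cands <- data.frame(percentile = c(92.5, 92.5, 95),
                      min_duration = c(2, 2, 2))
  sel <- select_definition(s, cands, model_spec())
  expect_equal(nrow(sel), 3L)
  expect_equal(sel$rank, 1:3)
  # duplicate candidates have identical qaic; the lower row index wins by
  # (percentile, duration) tie-break, so the two 92.5s rank adjacently
  dup <- sel[sel$percentile == 92.5, ]
  expect_equal(dup$qaic[1], dup$qaic[2], tolerance = 1e-10)
  single <- select_definition(s, cands[3, , drop = FALSE], model_spec())
  expect_equal(attr(single, "best")$percentile, 95)
  # all-degenerate grid errors
  cold <- data.frame(percentile = 99.9, min_duration = 14)
  expect_error(
    suppressWarnings(select_definition(s, cold, model_spec())),
    "degenerate")
})
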