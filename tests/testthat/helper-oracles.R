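# Independent brute-force oracles used across tests. These deliberately
# re-derive results by the most literal route possible (day-by-day loops,
# textbook formulas) so they stay independent of the package internals.

# enumerate maximal exceedance runs by walking the series day by day
brute_force_runs <- function(dates, values, threshold, min_duration,
                             season_months = 5:9) {
  keep <- as.integer(format(dates, "%m")) %in% season_months
  dates <- dates[keep]; values <- values[keep]
  runs <- list()
  cur <- c()
  for (i in seq_along(dates)) {
    new_block <- i > 1 && as.integer(dates[i] - dates[i - 1]) != 1L
    if (new_block && length(cur)) {
      runs[[length(runs) + 1]] <- cur; cur <- c()
    }
    if (!is.na(values[i]) && values[i] > threshold) {
      cur <- c(cur, i)
    } else if (length(cur)) {
      runs[[length(runs) + 1]] <- cur; cur <- c()
    }
  }
  if (length(cur)) runs[[length(runs) + 1]] <- cur
  runs <- Filter(function(r) length(r) >= min_duration, runs)
  if (!length(runs)) {
    return(data.frame(start = as.Date(character()), end = as.Date(character()),
                      duration = integer(), excess = numeric()))
  }
  do.call(rbind, lapply(runs, function(r) {
    data.frame(start = dates[r[1]], end = dates[r[length(r)]],
               duration = length(r), excess = sum(values[r] - threshold))
  }))
}

# textbook DerSimonian-Laird, written independently of the package
brute_force_dl <- function(b, v) {
  w <- 1 / v
  bfe <- sum(w * b) / sum(w)
  Q <- sum(w * (b - bfe)^2)
  k <- length(b)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (v + tau2)
  list(beta = sum(wr * b) / sum(wr), se = sqrt(1 / sum(wr)), tau2 = tau2,
       Q = Q, I2 = if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0)
}

# day-by-day attributable-number loop
brute_force_an <- function(pop, rates, hw, beta) {
  total <- 0
  for (i in seq_along(hw)) {
    if (hw[i] == 1) total <- total + pop * rates[i] * (1 - 1 / exp(beta))
  }
  total
}

# random daily series over two warm seasons for detection property tests
random_series <- function(n_years = 2, start_year = 2010) {
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1)),
               by = "day")
  list(dates = dates, values = round(stats::rnorm(length(dates), 28, 4), 1))
}

# warm-season subset of a simulated location, with its injected indicator
season_slice <- function(study, i, months = 5:9) {
  s <- study$series[[i]]
  m <- as.integer(format(s$date, "%m")) %in% months
  list(series = s[m, , drop = FALSE], indicator = study$indicators[[i]][m])
}
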