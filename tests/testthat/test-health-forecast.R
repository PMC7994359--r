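# weekly count series builder: one value per day from `from`, length n
day_series <- function(from, n, counts) {
  data.frame(date = as.Date(from) + seq_len(n) - 1, count = rep_len(counts, n))
}

test_that("trailing same-weekday mean skips holidays and extends the lookback", {
  # Mondays 2018: Jul 2, 9, 16, 23, 30, Aug 6 ...
  s <- data.frame(date = as.Date("2018-07-02") + 7 * (0:4),
                  count = c(50, 40, 30, 20, 10))
  target <- as.Date("2018-08-06")  # the following Monday
  expect_equal(trailing_dow_mean(s, target, 4), mean(c(40, 30, 20, 10)))
  # most recent Monday is a holiday: skip it and reach one week further back
  hol <- as.Date("2018-07-30")
  expect_equal(trailing_dow_mean(s, target, 4, hol), mean(c(50, 40, 30, 20)))
  # constant series stays constant for any k
  cs <- day_series("2018-01-01", 200, 7)
  expect_equal(trailing_dow_mean(cs, as.Date("2018-07-18"), 12), 7)
  # fewer qualifying dates than k: mean of those available, flagged
  expect_warning(v <- trailing_dow_mean(s, target, 12), "qualifying")
  expect_equal(v, mean(s$count))
  expect_error(trailing_dow_mean(s, as.Date("2018-07-02"), 4), "qualifying")
})

test_that("week_of_year follows the ISO-8601 calendar", {
  expect_equal(week_of_year(as.Date("2018-01-01")), 1L)
  expect_equal(week_of_year(as.Date("2018-12-31")), 1L)  # week 1 of 2019
  # mid-year: 7 days apart differ by exactly one week
  d <- as.Date("2018-05-03") + 7 * (0:10)
  expect_equal(diff(week_of_year(d)), rep(1L, 10))
  # agreement with the C library's %V formatting on random dates
  set.seed(41)
  rd <- as.Date("2015-01-01") + sample.int(2500, 200)
  expect_equal(week_of_year(rd), as.integer(format(rd, "%V")))
})

test_that("build_health_table applies the 15 ug/m3 rule and seeded low-exposure sampling", {
  n <- 200
  ind <- cbind(hsda_id = 1, day_series("2018-01-01", n, c(30, 32, 31, 29, 33, 9, 6)))
  pm <- rep(3, n); pm[(n - 4):n] <- c(5, 10, 16, 20, 3)
  expo <- data.frame(hsda_id = 1, date = ind$date, pm25 = pm)
  t0 <- build_health_table(ind, expo, low_sample_frac = 0, seed = 1)
  expect_equal(t0$date, ind$date[(n - 4):n][c(3, 4)])   # only the 16 and 20 days
  expect_equal(t0$pm_day0, c(16, 20))
  expect_equal(t0$pm_lag1, c(10, 16))
  t1 <- build_health_table(ind, expo, low_sample_frac = 1, seed = 1)
  # all dates with computable features are retained (the first week has
  # no same-weekday predecessor; its first day also lacks the lag)
  expect_equal(nrow(t1), n - 7)
  expect_true(all(t1$week == week_of_year(t1$date)))
  ta <- build_health_table(ind, expo, low_sample_frac = 0.3, seed = 9)
  tb <- build_health_table(ind, expo, low_sample_frac = 0.3, seed = 9)
  expect_identical(ta, tb)
  # features are trailing means of the weekly pattern
  i <- nrow(t1)
  expect_equal(t1$dow4[i], mean(ind$count[ind$date %in% (t1$date[i] - 7 * (1:4))]))
})

health_rows <- function(n, seed) {
  set.seed(seed)
  data.frame(pm_day0 = stats::runif(n, 0, 80), pm_lag1 = stats::runif(n, 0, 80),
             dow12 = stats::runif(n, 5, 60), dow4 = stats::runif(n, 5, 60),
             week = sample(1:53, n, replace = TRUE))
}

test_that("the health forest recovers a pure trailing-mean signal and none from permuted targets", {
  rows <- health_rows(2000, seed = 42)
  rows$target <- rows$dow4
  m <- fit_health_model(rows, seed = 3)
  expect_gte(m$oob_pseudo_r2, 0.95)
  perm <- rows
  set.seed(43); perm$target <- sample(perm$target)
  mp <- fit_health_model(perm, seed = 3)
  expect_lte(mp$oob_pseudo_r2, 0.1)
  expect_identical(fit_health_model(rows, seed = 3)$oob_rmse, m$oob_rmse)
})

test_that("forecast substitution uses day-of-week structure and keeps horizons consistent", {
  # world with a pure weekly signal, flat exposure
  n <- 400
  wk <- c(30, 32, 31, 29, 33, 9, 6)  # Mon..Sun pattern starting 2018-01-01 (a Monday)
  ind <- cbind(hsda_id = 1, day_series("2018-01-01", n, wk))
  expo <- data.frame(hsda_id = 1, date = ind$date, pm25 = 3)
  rows <- build_health_table(ind, expo, low_sample_frac = 1, seed = 2)
  m <- fit_health_model(rows, seed = 4)
  issue <- ind$date[n] + 1  # next unseen day
  hist <- ind[c("date", "count")]
  fc <- forecast_indicator(m, hist, list(day0 = 3, day1 = 3), 3, issue)
  expect_s3_class(fc, "forecast_pair")
  expect_gte(fc$day0, 0); expect_gte(fc$day1, 0)
  # within 10% of that weekday's trailing mean
  tm <- trailing_dow_mean(hist, issue, 4)
  expect_lt(abs(fc$day0 - tm) / tm, 0.1)
  # near-constant count world with equal PM forecasts: day0 and day1
  # nearly equal (an exactly constant target is rejected as degenerate)
  ind2 <- cbind(hsda_id = 1, day_series("2018-01-01", n, c(20, 21)))
  rows2 <- build_health_table(ind2, expo, low_sample_frac = 1, seed = 2)
  m2 <- suppressWarnings(fit_health_model(rows2, seed = 4))
  expect_error(fit_health_model(transform(rows2, target = 5), seed = 1),
               "constant")
  fc2 <- forecast_indicator(m2, ind2[c("date", "count")],
                            list(day0 = 3, day1 = 3), 3, issue)
  expect_lt(abs(fc2$day0 - fc2$day1) / fc2$day0, 0.05)
  # history reaching into the issue date is leakage and rejected
  expect_error(forecast_indicator(m, hist, list(day0 = 3, day1 = 3), 3,
                                  ind$date[n]), "history")
  expect_error(forecast_indicator(m, hist, list(day0 = NA, day1 = 3), 3, issue),
               "PM2.5 forecast")
})
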