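# deterministic synthetic training rows: target driven by the forecast
# covariate
make_rows <- function(n, seed, target = NULL) {
  set.seed(seed)
  rows <- data.frame(pm25_lag1 = stats::runif(n, 0, 60),
                     aod = stats::runif(n, 0, 2),
                     frp = stats::runif(n, 0, 500),
                     hms = stats::rbinom(n, 1, 0.3),
                     vi = round(stats::runif(n, 1, 100)),
                     firework = stats::runif(n, 0, 120))
  rows$target <- if (is.null(target)) rows$firework else target
  rows
}

test_that("firework_daily splits 48 hourly values into the two daily means", {
  expect_equal(firework_daily(rep(10, 48)), c(day0 = 10, day1 = 10))
  expect_equal(firework_daily(c(rep(0, 24), rep(24, 24))), c(day0 = 0, day1 = 24))
  expect_equal(firework_daily(c(1:24, rep(0, 24))), c(day0 = 12.5, day1 = 0))
  expect_error(firework_daily(rep(1, 47)), "48")
  expect_error(firework_daily(c(rep(1, 47), -1)), "non-negative")
})

test_that("hourly expansion of the simulated forecast preserves daily means exactly", {
  fw <- data.frame(cell_id = "c1", issue_date = as.Date("2018-08-01"),
                   day0 = 13.7, day1 = 42.1)
  h <- firework_hourly(fw, "c1", "2018-08-01")
  expect_length(h, 48)
  expect_equal(unname(firework_daily(h)), c(13.7, 42.1), tolerance = 1e-12)
  tbl <- firework_daily_table(data.frame(cell_id = "c1",
                                         issue_date = as.Date("2018-08-01"),
                                         hour = 1:48, pm25 = h))
  expect_equal(tbl$day0, 13.7, tolerance = 1e-12)
  expect_equal(tbl$day1, 42.1, tolerance = 1e-12)
})

# minimal hand-built world for the training-table assembly: two
# stations, three dates, one grid cell
blend_world <- function(obs_values) {
  dates <- as.Date("2018-08-01") + 0:2
  all_d <- seq(min(dates) - 1, max(dates), by = "day")
  stations <- data.frame(station_id = c("s1", "s2"), x_km = c(10, 30), y_km = 10)
  cells <- data.frame(cell_id = "c1", x_km = 20, y_km = 10)
  observations <- expand.grid(station_id = stations$station_id, date = all_d,
                              stringsAsFactors = FALSE)
  observations$pm25 <- obs_values[seq_len(nrow(observations))]
  predictors <- list(
    aod = data.frame(date = rep(all_d, each = 1), id = "a1", x = 10, y = 10,
                     value = 0.5),
    frp = data.frame(date = all_d, id = "f1", x = 15, y = 10, value = 200),
    hms = data.frame(date = all_d, cell_id = "c1", flag = 1L),
    vi = data.frame(date = all_d, id = "v1", x = 0, y = 0, value = 55))
  firework <- data.frame(cell_id = "c1", issue_date = rep(dates, each = 1),
                         day0 = c(5, 6, 7), day1 = c(8, 9, 10))
  list(stations = stations, cells = cells, observations = observations,
       predictors = predictors, firework = firework, dates = dates)
}

test_that("build_blend_table assembles one complete row per station-date with capping and imputation", {
  w <- blend_world(rep(20, 8))
  tbl <- build_blend_table(w$stations, w$observations, w$predictors,
                           w$firework, w$cells, w$dates)
  expect_equal(nrow(tbl), 6)  # 2 stations x 3 dates
  expect_true(all(tbl$target == 20))
  expect_true(all(tbl$vi == 55) && all(tbl$hms == 1) && all(tbl$frp == 200))
  expect_equal(tbl$firework, rep(c(5, 6, 7), each = 2))

  # an observed 400 is truncated to the 150 cap
  ov <- rep(20, 8); ov[3] <- 400  # s1 on the first target date
  tbl2 <- build_blend_table(w$stations, w$observations |>
                              transform(pm25 = ov), w$predictors,
                            w$firework, w$cells, w$dates)
  expect_equal(max(tbl2$target), 150)

  # AOD beyond 50 km everywhere -> imputed with the training median (of
  # nothing missing here the median equals the value itself); push one
  # station out of range instead
  w3 <- w; w3$predictors$aod$x <- 45   # 35 km from s1, 15 km from s2
  w3$stations$x_km <- c(-40, 30)       # s1 now 85 km from retrievals
  tbl3 <- build_blend_table(w3$stations, w3$observations, w3$predictors,
                            w3$firework, w3$cells, w3$dates)
  med <- stats::median(rep(0.5, 3))    # independent recomputation
  expect_equal(attr(tbl3, "imputation")[["aod"]], med)
  expect_true(all(tbl3$aod == med))
})

test_that("the blend forest recovers a perfect forecast signal and none from permuted targets", {
  rows <- make_rows(2000, seed = 31)
  m <- fit_blend_model(rows, seed = 99)
  expect_gte(m$oob_pseudo_r2, 0.95)
  perm <- rows
  set.seed(32); perm$target <- sample(perm$target)
  mp <- fit_blend_model(perm, seed = 99)
  expect_lte(mp$oob_pseudo_r2, 0.1)
  # determinism: same rows and seed give identical OOB RMSE
  m2 <- fit_blend_model(rows, seed = 99)
  expect_identical(m$oob_rmse, m2$oob_rmse)
  expect_error(fit_blend_model(transform(rows, target = 1), seed = 1), "constant")
})

test_that("out-of-bag metrics match an independent recomputation from stored predictions", {
  rows <- make_rows(400, seed = 33)
  m <- fit_blend_model(rows, n_trees = 300, seed = 5)
  met <- oob_metrics(m)
  p <- m$oob$oob_pred; o <- m$oob$target
  expect_equal(met[["rmse"]], sqrt(sum((p - o)^2) / length(o)), tolerance = 1e-12)
  expect_equal(met[["pseudo_r2"]],
               1 - mean((p - o)^2) / mean((o - mean(o))^2), tolerance = 1e-12)
  expect_equal(met[["rmse"]], m$oob_rmse)
  # rmse^2 * n equals the brute-force sum of squared errors
  expect_equal(met[["rmse"]]^2 * length(o), sum((p - o)^2), tolerance = 1e-9)
})

test_that("day0 predictions track the signal, respect the cap and floor, and are deterministic", {
  rows <- make_rows(2000, seed = 34)
  m <- fit_blend_model(rows, seed = 7)
  pv <- data.frame(pm25_lag1 = 20, aod = 1, frp = 100, hms = 0, vi = 50,
                   firework = 30)
  p <- predict_day0(m, pv)
  expect_gte(p, 20); expect_lte(p, 40)
  expect_identical(predict_day0(m, pv), p)
  expect_true(all(predict_day0(m, make_rows(50, seed = 35)) <= 150))
  expect_error(predict_day0(m, transform(pv, firework = NA)), "forecast")
  # missing AOD is imputed from the recorded median, not rejected
  expect_no_error(predict_day0(m, transform(pv, aod = NA)))
})

test_that("blend_day1 averages before capping", {
  expect_equal(blend_day1(50, 100), 75)
  expect_equal(blend_day1(150, 150), 150)
  expect_equal(blend_day1(150, 300), 150)  # mean 225, then capped
  expect_error(blend_day1(-1, 10), "non-negative")
  set.seed(36)
  a <- stats::runif(100, 0, 150); b <- stats::runif(100, 0, 150)
  d1 <- blend_day1(a, b)
  expect_true(all(d1 >= pmin(a, b) & d1 <= pmax(a, b)))
  expect_true(all(d1 >= 0 & d1 <= 150))
})
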