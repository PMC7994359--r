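test_that("simulate_geography produces the configured cardinalities, populations and determinism", {
  cfg <- tiny_cfg(n_hsdas = 4, das_per_hsda = 50)
  g <- simulate_geography(cfg)
  expect_equal(nrow(g$das), 200)
  expect_true(all(g$das$population >= 400 & g$das$population <= 700))
  expect_equal(nrow(g$stations), 4 * cfg$n_stations_per_hsda)
  expect_true(all(table(g$stations$hsda_id) >= 1))
  # health-area population is exactly the sum of member DA populations
  sums <- tapply(g$das$population, g$das$hsda_id, sum)
  expect_equal(as.vector(sums[as.character(g$hsdas$hsda_id)]), g$hsdas$population)
  g2 <- simulate_geography(cfg)
  expect_identical(g, g2)
  expect_error(scenario_config(extent_km = 103, cell_km = 5), "multiple")
})

test_that("a fixed geography seed pins the map while the master seed re-draws the noise", {
  b1 <- make_scenario(tiny_cfg(seed = 1, geo_seed = 99))
  b2 <- make_scenario(tiny_cfg(seed = 2, geo_seed = 99))
  expect_identical(b1$geography, b2$geography)
  expect_false(identical(b1$observations$pm25, b2$observations$pm25))
  b3 <- make_scenario(tiny_cfg(seed = 1, geo_seed = 99))
  expect_identical(b1$observations, b3$observations)
})

test_that("smoke fields reduce to background without episodes and follow the plume closed form", {
  g0 <- simulate_geography(cfg0 <- tiny_cfg(episodes_per_year = 0))
  f0 <- simulate_smoke_fields(cfg0, g0)
  expect_true(all(f0$cell_pm == cfg0$background_pm))

  cfg1 <- tiny_cfg(episodes_per_year = 1, start_date = "2018-04-01",
                   predictor_start = "2018-06-01")
  g1 <- simulate_geography(cfg1)
  f1 <- simulate_smoke_fields(cfg1, g1)
  ep <- f1$episodes
  expect_equal(nrow(ep), 1)
  peak_day <- ep$start + (ep$duration - 1) %/% 2
  d2 <- (g1$cells$x_km - ep$x_km)^2 + (g1$cells$y_km - ep$y_km)^2
  ci <- which.min(d2)
  expected <- cfg1$background_pm +
    ep$peak * exp(-d2[ci] / (2 * cfg1$decay_length_km^2))
  expect_equal(f1$cell_pm[ci, format(peak_day)], expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  # plume flags equal a brute-force recount of cells above threshold
  pdates <- seq(cfg1$predictor_start, cfg1$eval_end + 1, by = "day")
  expect_equal(nrow(f1$predictors$hms),
               sum(f1$cell_pm[, format(pdates)] > cfg1$hms_threshold))
})

test_that("monitor noise is recoverable from observation-truth residuals", {
  cfg <- tiny_cfg(seed = 5, background_pm = 30)  # high floor: no zero-truncation
  g <- simulate_geography(cfg); f <- simulate_smoke_fields(cfg, g)
  obs <- simulate_observations(cfg, g, f)
  st_cell <- assign_nearest(g$stations, g$cells)
  truth <- f$cell_pm[st_cell, format(sort(unique(obs$date)))]
  res <- obs$pm25 - as.numeric(truth[cbind(match(obs$station_id, g$stations$station_id),
                                           match(obs$date, sort(unique(obs$date))))])
  expect_lt(abs(stats::sd(res) / cfg$monitor_noise_sd - 1), 0.1)
})

test_that("the numerical forecast applies near-fire bias on top of the truth", {
  cfg <- tiny_cfg(seed = 3, forecast_bias = 1, forecast_noise_sd = 0)
  g <- simulate_geography(cfg); f <- simulate_smoke_fields(cfg, g)
  fw <- simulate_firework(cfg, g, f)
  i <- sample(nrow(fw), 200)
  t0 <- f$cell_pm[cbind(match(fw$cell_id[i], g$cells$cell_id),
                        match(fw$issue_date[i], f$dates))]
  t1 <- f$cell_pm[cbind(match(fw$cell_id[i], g$cells$cell_id),
                        match(fw$issue_date[i] + 1, f$dates))]
  expect_equal(fw$day0[i], unname(t0), tolerance = 1e-12)
  expect_equal(fw$day1[i], unname(t1), tolerance = 1e-12)
  # and the hourly expansion reproduces those daily means
  h <- firework_hourly(fw, fw$cell_id[i[1]], fw$issue_date[i[1]])
  expect_equal(unname(firework_daily(h)), c(fw$day0[i[1]], fw$day1[i[1]]),
               tolerance = 1e-12)

  cfgb <- tiny_cfg(seed = 3, forecast_bias = 3, forecast_noise_sd = 0)
  fwb <- simulate_firework(cfgb, g, f)
  ep <- f$episodes
  # pick a cell-date within one decay length of an active episode centre
  d <- ep$start[1] + (ep$duration[1] - 1) %/% 2  # the episode's peak day
  near <- which((g$cells$x_km - ep$x_km[1])^2 + (g$cells$y_km - ep$y_km[1])^2 <=
                  cfgb$decay_length_km^2)
  row <- fwb[fwb$cell_id == g$cells$cell_id[near[1]] & fwb$issue_date == d, ]
  if (nrow(row) == 1) {
    truth_here <- f$cell_pm[near[1], format(d)]
    expect_equal(row$day0, unname(3 * truth_here), tolerance = 1e-12)
  }
  expect_identical(simulate_firework(cfgb, g, f), fwb)
})

test_that("dispensation counts follow the configured Poisson moments", {
  flat <- function(seed) tiny_cfg(seed = seed, beta_pm = 0,
                                  dow_multipliers = rep(1, 7),
                                  holidays = as.Date(character()))
  cfg <- flat(8)
  dates <- seq(as.Date("2018-01-01"), as.Date("2018-12-31"), by = "day")
  expo <- data.frame(hsda_id = 1, date = dates, pm25 = 4.2)
  pops <- c("1" = 8e4)
  counts <- simulate_dispensations(cfg, expo, pops)
  lam <- cfg$base_rate * 8e4 / 1e4     # 19.2/day
  se <- sqrt(lam / nrow(counts))
  expect_lt(abs(mean(counts$count) - lam), 3 * se)

  # weekend multiplier 0.2 scales weekend means accordingly
  cfgw <- tiny_cfg(seed = 9, beta_pm = 0,
                   dow_multipliers = c(1, 1, 1, 1, 1, 0.2, 0.2),
                   holidays = as.Date(character()))
  cw <- simulate_dispensations(cfgw, expo, pops)
  wd <- as.POSIXlt(cw$date)$wday
  ratio <- mean(cw$count[wd %in% c(0, 6)]) / mean(cw$count[!wd %in% c(0, 6)])
  expect_lt(abs(ratio - 0.2), 0.05)

  # the log-linear response: +22 ug/m3 over clean scales the season total
  # by exp(beta * 22) = 1.3 (constant exposure, so the factor is exact in
  # expectation; averaged over 10 seeds)
  ratios <- vapply(1:10, function(s) {
    cfa <- flat(100 + s); cfa$beta_pm <- log(1.3) / 22
    cfb <- cfa; cfb$seed <- cfa$seed + 50L
    clean <- simulate_dispensations(cfa, expo, pops)
    smoky <- simulate_dispensations(cfb, transform(expo, pm25 = pm25 + 22), pops)
    sum(smoky$count) / sum(clean$count)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1.3), 0.05 * 1.3)
})

test_that("a scenario bundle round-trips through its delimited-text files", {
  cfg <- tiny_cfg(seed = 11, predictor_start = "2018-07-01",
                  eval_start = "2018-07-15", eval_end = "2018-07-24")
  b <- make_scenario(cfg)
  dir <- tempfile("scenario")
  write_scenario(b, dir)
  expect_true(all(file.exists(file.path(dir, c("stations.csv", "firework.csv",
                                               "scenario.yaml", "indicators.csv")))))
  # output files are self-describing
  head1 <- readLines(file.path(dir, "observations.csv"), n = 3)
  expect_match(head1[1], "^# smokecast ")
  expect_match(head1[2], "^# config_hash ")
  b2 <- read_scenario(dir)
  expect_equal(b2$observations$pm25, b$observations$pm25, tolerance = 1e-8)
  expect_identical(b2$indicators$count, b$indicators$count)
  expect_equal(b2$firework$day0, b$firework$day0, tolerance = 1e-8)
  expect_equal(as.numeric(b2$fields$cell_pm), as.numeric(b$fields$cell_pm),
               tolerance = 1e-8)
  expect_equal(b2$exposure$pm25, b$exposure$pm25, tolerance = 1e-8)
  expect_identical(b2$cfg$seed, b$cfg$seed)
  expect_identical(b2$holidays, b$holidays)
  # and the read-back bundle drives the pipeline end-to-end
  run <- suppressWarnings(run_season(b2))
  expect_s3_class(run, "season_run")
  expect_equal(nrow(run$indicator_forecasts), 10 * cfg$n_hsdas)
  unlink(dir, recursive = TRUE)
})
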