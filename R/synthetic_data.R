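# Seeded synthetic smoke seasons: planar geography, episodic gridded
# PM2.5 truth, noisy monitors, satellite-style predictor points, a
# biased 48-h numerical forecast, and Poisson dispensation counts.
# Every generator is a pure function of (config, seed), so the whole
# pipeline is testable end-to-end with no external data.

#' Scenario configuration for a synthetic smoke season
#'
#' Defines the study conditions of a synthetic world: a planar province
#' split into health areas, dissemination-area centroids with census
#' populations, regulatory monitors, a 5-km grid, episodic smoke
#' seasons, a near-fire-biased numerical forecast, and a Poisson count
#' process for reliever-inhaler dispensations with strong day-of-week
#' and holiday structure and a log-linear PM2.5 response.
#'
#' Defaults describe a desk-scale province: 4 health areas x 50
#' dissemination areas of 400-700 residents, 4 monitors per area, a
#' 20 x 20 grid of 5-km cells, two history years plus one evaluation
#' season, three smoke episodes per summer peaking at 60-140 ug/m3 over
#' a 4.2 ug/m3 background, a numerical forecast that overestimates
#' 3-fold near active fires, weekend dispensation rates about a third
#' of weekday rates, and a PM2.5 response of log(1.3)/22 per ug/m3 (a
#' 22 ug/m3 season-mean exposure raises dispensations about 30 percent).
#'
#' @param seed master integer seed; the sub-generators draw from fixed
#'   offsets of it so streams are independent but reproducible.
#' @param geo_seed optional separate seed for the geography, so smoke
#'   and noise can be re-drawn on a fixed map; defaults to `seed`.
#' @param n_hsdas,das_per_hsda,da_population_range,n_stations_per_hsda,n_vi_stations
#'   geography sizes.
#' @param extent_km,cell_km square domain size and grid cell size (km).
#' @param start_date first date of the indicator/exposure record.
#' @param predictor_start first date with monitor, satellite and
#'   numerical-forecast records (the evaluation year's season).
#' @param eval_start,eval_end the evaluation window (inclusive).
#' @param episodes_per_year,fire_window_start,fire_window_end,episode_duration_range,episode_peak_range,decay_length_km
#'   smoke episode model: count per calendar year, seasonal window
#'   (month-day strings), duration in days, peak amplitude in ug/m3,
#'   and Gaussian spatial decay length in km.
#' @param background_pm baseline PM2.5 (ug/m3).
#' @param monitor_noise_sd additive monitor noise sd (ug/m3; draws are
#'   floored at 0).
#' @param aod_per_pm,aod_noise_sd,aod_missing_prob,n_aod_points
#'   AOD retrievals: proportionality to truth PM, log-normal noise sd,
#'   daily missingness, and retrievals per day.
#' @param frp_per_peak fire radiative power (MW) per ug/m3 of episode
#'   peak.
#' @param hms_threshold plume-flag threshold on truth PM (ug/m3).
#' @param vi_clean,vi_smoke venting index ranges (1-100) on ventilated
#'   vs stagnant (episode-active) days.
#' @param forecast_bias,forecast_noise_sd multiplicative forecast bias
#'   within one decay length of an active episode centre, and log-scale
#'   forecast noise sd.
#' @param dow_multipliers 7 positive multipliers, Monday..Sunday.
#' @param holiday_multiplier multiplier on statutory holidays (most
#'   pharmacies closed).
#' @param holidays `Date` vector; default the built-in statutory
#'   calendar over the covered years.
#' @param base_rate weekday dispensations per 10,000 residents per day
#'   at zero smoke.
#' @param beta_pm log count increase per ug/m3 of PM2.5.
#' @param overdispersion 0 for Poisson counts (default); a positive
#'   value is the negative-binomial size parameter.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            geo_seed = NULL,
                            n_hsdas = 4L,
                            das_per_hsda = 150L,
                            da_population_range = c(400L, 700L),
                            n_stations_per_hsda = 4L,
                            n_vi_stations = 8L,
                            extent_km = 100,
                            cell_km = 5,
                            start_date = "2016-01-01",
                            predictor_start = "2018-04-01",
                            eval_start = "2018-07-15",
                            eval_end = "2018-09-15",
                            episodes_per_year = 3L,
                            fire_window_start = "06-20",
                            fire_window_end = "09-05",
                            episode_duration_range = c(7L, 15L),
                            episode_peak_range = c(60, 140),
                            decay_length_km = 30,
                            background_pm = 4.2,
                            monitor_noise_sd = 2,
                            aod_per_pm = 0.04,
                            aod_noise_sd = 0.2,
                            aod_missing_prob = 0.3,
                            n_aod_points = 80L,
                            frp_per_peak = 5,
                            hms_threshold = 20,
                            vi_clean = c(40, 95),
                            vi_smoke = c(1, 40),
                            forecast_bias = 3,
                            forecast_noise_sd = 0.2,
                            dow_multipliers = c(1, 1, 1, 1, 1.05, 0.35, 0.25),
                            holiday_multiplier = 0.3,
                            holidays = NULL,
                            base_rate = 2.4,
                            beta_pm = log(1.3) / 22,
                            overdispersion = 0) {
  cfg <- list(seed = as.integer(seed), geo_seed = geo_seed,
              n_hsdas = as.integer(n_hsdas),
              das_per_hsda = as.integer(das_per_hsda),
              da_population_range = da_population_range,
              n_stations_per_hsda = as.integer(n_stations_per_hsda),
              n_vi_stations = as.integer(n_vi_stations),
              extent_km = extent_km, cell_km = cell_km,
              start_date = as.Date(start_date),
              predictor_start = as.Date(predictor_start),
              eval_start = as.Date(eval_start), eval_end = as.Date(eval_end),
              episodes_per_year = as.integer(episodes_per_year),
              fire_window_start = fire_window_start,
              fire_window_end = fire_window_end,
              episode_duration_range = as.integer(episode_duration_range),
              episode_peak_range = episode_peak_range,
              decay_length_km = decay_length_km,
              background_pm = background_pm,
              monitor_noise_sd = monitor_noise_sd,
              aod_per_pm = aod_per_pm, aod_noise_sd = aod_noise_sd,
              aod_missing_prob = aod_missing_prob,
              n_aod_points = as.integer(n_aod_points),
              frp_per_peak = frp_per_peak, hms_threshold = hms_threshold,
              vi_clean = vi_clean, vi_smoke = vi_smoke,
              forecast_bias = forecast_bias,
              forecast_noise_sd = forecast_noise_sd,
              dow_multipliers = dow_multipliers,
              holiday_multiplier = holiday_multiplier,
              holidays = holidays,
              base_rate = base_rate, beta_pm = beta_pm,
              overdispersion = overdispersion)
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  with(cfg, {
    if (extent_km <= 0 || cell_km <= 0 || extent_km %% cell_km != 0)
      stop("grid extent must be a positive multiple of the cell size",
           call. = FALSE)
    if (n_hsdas < 1 || das_per_hsda < 1 || n_stations_per_hsda < 1)
      stop("geography sizes must be >= 1", call. = FALSE)
    if (diff(da_population_range) < 0 || da_population_range[1] <= 0)
      stop("invalid da_population_range", call. = FALSE)
    if (!(start_date <= predictor_start && predictor_start <= eval_start &&
          eval_start <= eval_end))
      stop("dates must satisfy start <= predictor_start <= eval_start <= eval_end",
           call. = FALSE)
    if (any(dow_multipliers <= 0) || length(dow_multipliers) != 7L)
      stop("dow_multipliers must be 7 positive values (Monday..Sunday)",
           call. = FALSE)
    if (base_rate < 0 || holiday_multiplier < 0 || background_pm < 0 ||
        monitor_noise_sd < 0 || forecast_bias <= 0)
      stop("rates, noise and bias parameters must be non-negative", call. = FALSE)
  })
  invisible(cfg)
}

scenario_years <- function(cfg) {
  seq(as.integer(format(cfg$start_date, "%Y")),
      as.integer(format(cfg$eval_end, "%Y")))
}

scenario_holidays <- function(cfg) {
  cfg$holidays %||% stat_holidays(scenario_years(cfg))
}

truth_dates <- function(cfg) seq(cfg$start_date, cfg$eval_end + 1L, by = "day")
predictor_dates <- function(cfg) seq(cfg$predictor_start, cfg$eval_end + 1L, by = "day")
eval_dates <- function(cfg) seq(cfg$eval_start, cfg$eval_end, by = "day")

#' Simulate the scenario geography
#'
#' Health areas are laid out as rectangular blocks tiling the square
#' domain; dissemination-area centroids cluster around a few town
#' centres inside each block, with populations drawn uniformly from the
#' configured range. Each health area receives its monitors at a random
#' subset of its town clusters (guaranteeing at least one station per
#' area); venting-index stations scatter over the whole domain.
#'
#' @param cfg a [scenario_config()].
#' @return list with `cells` (cell_id, x_km, y_km, populated), `das`,
#'   `hsdas`, `stations`, `vi_stations`, and `cell_hsda` (majority-
#'   population health area of each populated cell).
#' @export
simulate_geography <- function(cfg) {
  set.seed(cfg$geo_seed %||% cfg$seed)
  n_side <- cfg$extent_km / cfg$cell_km
  centro <- cfg$cell_km * (seq_len(n_side) - 0.5)
  cells <- data.frame(cell_id = sprintf("c%03d", seq_len(n_side^2)),
                      x_km = rep(centro, times = n_side),
                      y_km = rep(centro, each = n_side))
  # health-area blocks: near-square tiling
  nbx <- ceiling(sqrt(cfg$n_hsdas)); nby <- ceiling(cfg$n_hsdas / nbx)
  bw <- cfg$extent_km / nbx; bh <- cfg$extent_km / nby
  das <- list(); stations <- list()
  for (h in seq_len(cfg$n_hsdas)) {
    bx <- (h - 1) %% nbx; by <- (h - 1) %/% nbx
    n_towns <- sample(2:3, 1)
    towns <- cbind(x = stats::runif(n_towns, bx * bw + 0.1 * bw, (bx + 1) * bw - 0.1 * bw),
                   y = stats::runif(n_towns, by * bh + 0.1 * bh, (by + 1) * bh - 0.1 * bh))
    ti <- sample(n_towns, cfg$das_per_hsda, replace = TRUE)
    x <- pmin(pmax(stats::rnorm(cfg$das_per_hsda, towns[ti, "x"], 6), bx * bw + 0.5),
              (bx + 1) * bw - 0.5)
    y <- pmin(pmax(stats::rnorm(cfg$das_per_hsda, towns[ti, "y"], 6), by * bh + 0.5),
              (by + 1) * bh - 0.5)
    das[[h]] <- data.frame(
      da_id = sprintf("da%d_%03d", h, seq_len(cfg$das_per_hsda)),
      x_km = x, y_km = y,
      population = sample(cfg$da_population_range[1]:cfg$da_population_range[2],
                          cfg$das_per_hsda, replace = TRUE),
      hsda_id = h)
    sti <- sample(seq_len(n_towns), min(cfg$n_stations_per_hsda, n_towns))
    sti <- rep_len(sti, cfg$n_stations_per_hsda)
    stations[[h]] <- data.frame(
      station_id = sprintf("st%d_%02d", h, seq_len(cfg$n_stations_per_hsda)),
      x_km = towns[sti, "x"] + stats::rnorm(cfg$n_stations_per_hsda, 0, 2),
      y_km = towns[sti, "y"] + stats::rnorm(cfg$n_stations_per_hsda, 0, 2),
      hsda_id = h)
  }
  das <- do.call(rbind, das)
  stations <- do.call(rbind, stations)
  hsdas <- stats::aggregate(population ~ hsda_id, data = das, FUN = sum)
  hsdas$name <- sprintf("Area %d", hsdas$hsda_id)
  vi_stations <- data.frame(vi_id = sprintf("vi%02d", seq_len(cfg$n_vi_stations)),
                            x_km = stats::runif(cfg$n_vi_stations, 0, cfg$extent_km),
                            y_km = stats::runif(cfg$n_vi_stations, 0, cfg$extent_km))
  da_cell <- assign_nearest(das, cells)
  cells$populated <- seq_len(nrow(cells)) %in% da_cell
  # majority-population health area of each populated cell
  cell_hsda <- rep(NA_integer_, nrow(cells))
  for (ci in unique(da_cell)) {
    sel <- da_cell == ci
    tab <- tapply(das$population[sel], das$hsda_id[sel], sum)
    cell_hsda[ci] <- as.integer(names(tab)[which.max(tab)])
  }
  list(cells = cells, das = das,
       hsdas = hsdas[c("hsda_id", "name", "population")],
       stations = stations, vi_stations = vi_stations,
       da_cell = da_cell, cell_hsda = cell_hsda)
}

episode_profile <- function(duration) {
  mid <- (duration - 1) %/% 2
  pmax(0, 1 - abs(seq_len(duration) - 1 - mid) / (mid + 1))
}

draw_episodes <- function(cfg) {
  years <- scenario_years(cfg)
  eps <- list()
  for (y in years) {
    w0 <- as.Date(sprintf("%d-%s", y, cfg$fire_window_start))
    w1 <- as.Date(sprintf("%d-%s", y, cfg$fire_window_end))
    if (w1 < cfg$start_date || w0 > cfg$eval_end + 1L) next
    for (k in seq_len(cfg$episodes_per_year)) {
      dur <- sample(cfg$episode_duration_range[1]:cfg$episode_duration_range[2], 1)
      eps[[length(eps) + 1L]] <- data.frame(
        episode_id = sprintf("ep%d_%d", y, k),
        x_km = stats::runif(1, 0, cfg$extent_km),
        y_km = stats::runif(1, 0, cfg$extent_km),
        start = w0 + sample.int(as.integer(w1 - w0) + 1L, 1) - 1L,
        duration = dur,
        peak = stats::runif(1, cfg$episode_peak_range[1], cfg$episode_peak_range[2]))
    }
  }
  do.call(rbind, eps)
}

#' Simulate the gridded truth and the predictor point data
#'
#' Daily truth PM2.5 on the grid is the background plus, for each smoke
#' episode, a plume that is Gaussian in space (decay length
#' `decay_length_km`) and triangular in time (rising to the episode peak
#' at mid-duration). Satellite-style predictors are derived from the
#' truth for the predictor period: AOD retrievals proportional to truth
#' PM with log-normal noise and random missingness; FRP points at
#' active episode centres with power proportional to the episode's
#' current amplitude; binary plume flags where truth PM exceeds the
#' plume threshold; and a venting index that is low on stagnant
#' (episode-active) days.
#'
#' @param cfg a [scenario_config()].
#' @param geo output of [simulate_geography()].
#' @return list with `dates`, `cell_pm` (cells x dates matrix),
#'   `episodes`, and `predictors` (long tables `aod`, `frp`, `hms`,
#'   `vi`).
#' @export
simulate_smoke_fields <- function(cfg, geo) {
  set.seed(cfg$seed + 1L)
  dates <- truth_dates(cfg)
  nd <- length(dates); nc <- nrow(geo$cells)
  episodes <- draw_episodes(cfg)
  cell_pm <- matrix(cfg$background_pm, nrow = nc, ncol = nd,
                    dimnames = list(geo$cells$cell_id, format(dates)))
  if (!is.null(episodes)) for (e in seq_len(nrow(episodes))) {
    ep <- episodes[e, ]
    d2 <- (geo$cells$x_km - ep$x_km)^2 + (geo$cells$y_km - ep$y_km)^2
    sw <- exp(-d2 / (2 * cfg$decay_length_km^2))
    prof <- episode_profile(ep$duration)
    di <- match(ep$start + seq_along(prof) - 1L, dates)
    ok <- !is.na(di)
    if (any(ok))
      cell_pm[, di[ok]] <- cell_pm[, di[ok]] + ep$peak * outer(sw, prof[ok])
  }
  pdates <- predictor_dates(cfg)
  # episode activity per predictor date (for VI stagnation and FRP)
  active_amp <- function(d) {
    if (is.null(episodes)) return(numeric(0))
    off <- as.integer(d - episodes$start) + 1L
    amp <- numeric(nrow(episodes))
    live <- off >= 1L & off <= episodes$duration
    amp[live] <- vapply(which(live), function(i)
      episode_profile(episodes$duration[i])[off[i]], numeric(1))
    amp
  }
  aod <- list(); frp <- list(); hms <- list(); vi <- list()
  for (j in seq_along(pdates)) {
    d <- pdates[j]
    di <- match(d, dates)
    # AOD retrievals at random locations, with missingness
    keep <- stats::runif(cfg$n_aod_points) > cfg$aod_missing_prob
    if (any(keep)) {
      px <- stats::runif(cfg$n_aod_points, 0, cfg$extent_km)[keep]
      py <- stats::runif(cfg$n_aod_points, 0, cfg$extent_km)[keep]
      pcell <- assign_nearest(data.frame(x_km = px, y_km = py), geo$cells)
      aod[[j]] <- data.frame(date = d, id = sprintf("a%04d", which(keep)),
                             x = px, y = py,
                             value = cfg$aod_per_pm * cell_pm[pcell, di] *
                               exp(stats::rnorm(sum(keep), 0, cfg$aod_noise_sd)))
    }
    amp <- active_amp(d)
    live <- which(amp > 0)
    if (length(live))
      frp[[j]] <- data.frame(date = d, id = episodes$episode_id[live],
                             x = episodes$x_km[live], y = episodes$y_km[live],
                             value = cfg$frp_per_peak * episodes$peak[live] * amp[live])
    flagged <- which(cell_pm[, di] > cfg$hms_threshold)
    if (length(flagged))
      hms[[j]] <- data.frame(date = d, cell_id = geo$cells$cell_id[flagged],
                             flag = 1L)
    stagnant <- length(live) > 0L
    rng <- if (stagnant) cfg$vi_smoke else cfg$vi_clean
    vi[[j]] <- data.frame(date = d, id = geo$vi_stations$vi_id,
                          x = geo$vi_stations$x_km, y = geo$vi_stations$y_km,
                          value = round(stats::runif(nrow(geo$vi_stations),
                                                     rng[1], rng[2])))
  }
  bind <- function(l, empty) if (length(l)) do.call(rbind, l) else empty
  list(dates = dates, cell_pm = cell_pm, episodes = episodes,
       predictors = list(
         aod = bind(aod, data.frame(date = as.Date(character()), id = character(),
                                    x = numeric(), y = numeric(), value = numeric())),
         frp = bind(frp, data.frame(date = as.Date(character()), id = character(),
                                    x = numeric(), y = numeric(), value = numeric())),
         hms = bind(hms, data.frame(date = as.Date(character()),
                                    cell_id = character(), flag = integer())),
         vi = bind(vi, data.frame(date = as.Date(character()), id = character(),
                                  x = numeric(), y = numeric(), value = numeric()))))
}

#' Simulate monitor observations
#'
#' Each station observes the truth PM2.5 of its nearest grid cell plus
#' additive Gaussian noise, floored at zero, for the predictor period
#' (starting one day early so lag-1 values exist on the first predictor
#' date).
#'
#' @param cfg a [scenario_config()].
#' @param geo geography; `fields` output of [simulate_smoke_fields()].
#' @param fields truth fields.
#' @return data frame `station_id`, `date`, `pm25`.
#' @export
simulate_observations <- function(cfg, geo, fields) {
  set.seed(cfg$seed + 2L)
  odates <- seq(cfg$predictor_start - 1L, cfg$eval_end + 1L, by = "day")
  st_cell <- assign_nearest(geo$stations, geo$cells)
  di <- match(odates, fields$dates)
  truth <- fields$cell_pm[st_cell, di, drop = FALSE]
  obs <- pmax(truth + stats::rnorm(length(truth), 0, cfg$monitor_noise_sd), 0)
  data.frame(station_id = rep(geo$stations$station_id, times = length(odates)),
             date = rep(odates, each = nrow(geo$stations)),
             pm25 = as.numeric(obs))
}

#' Simulate the 48-h numerical smoke forecast
#'
#' For each issue date and grid cell the forecast's daily means equal
#' the truth multiplied by a near-fire bias and log-normal noise: the
#' bias is `forecast_bias` within one decay length of an episode centre
#' active on the forecast day (emulating near-fire overestimation by
#' dispersion models) and 1 elsewhere. Hourly values are recovered from
#' the daily means with a fixed diurnal shape whose mean is exactly 1
#' (see [firework_hourly()]).
#'
#' @param cfg a [scenario_config()].
#' @param geo geography.
#' @param fields truth fields.
#' @return data frame `cell_id`, `issue_date`, `day0`, `day1` of daily
#'   means.
#' @export
simulate_firework <- function(cfg, geo, fields) {
  set.seed(cfg$seed + 3L)
  issues <- seq(cfg$predictor_start, cfg$eval_end, by = "day")
  nc <- nrow(geo$cells)
  eps <- fields$episodes
  bias_on <- function(d) {
    # cells within one decay length of an episode centre active on d
    b <- rep(1, nc)
    if (is.null(eps)) return(b)
    off <- as.integer(d - eps$start) + 1L
    live <- which(off >= 1L & off <= eps$duration)
    for (i in live) {
      d2 <- (geo$cells$x_km - eps$x_km[i])^2 + (geo$cells$y_km - eps$y_km[i])^2
      b[d2 <= cfg$decay_length_km^2] <- cfg$forecast_bias
    }
    b
  }
  out <- vector("list", length(issues))
  for (j in seq_along(issues)) {
    d <- issues[j]
    i0 <- match(d, fields$dates); i1 <- match(d + 1L, fields$dates)
    noise0 <- exp(stats::rnorm(nc, 0, cfg$forecast_noise_sd))
    noise1 <- exp(stats::rnorm(nc, 0, cfg$forecast_noise_sd))
    out[[j]] <- data.frame(
      cell_id = geo$cells$cell_id, issue_date = d,
      day0 = fields$cell_pm[, i0] * bias_on(d) * noise0,
      day1 = fields$cell_pm[, i1] * bias_on(d + 1L) * noise1,
      row.names = NULL)
  }
  do.call(rbind, out)
}

# fixed diurnal weights, mean exactly 1 over 24 h
diurnal_weights <- function() 1 + 0.3 * sin(2 * pi * ((1:24) - 9) / 24)

#' Hourly values of one 48-h forecast issue
#'
#' Expands the daily means of the numerical forecast for one cell and
#' issue date into 48 hourly values using a fixed diurnal shape with
#' unit mean, so [firework_daily()] recovers the daily means exactly.
#'
#' @param firework daily forecast table (`cell_id`, `issue_date`,
#'   `day0`, `day1`).
#' @param cell_id,issue_date the issue to expand.
#' @return numeric vector of 48 non-negative values.
#' @export
firework_hourly <- function(firework, cell_id, issue_date) {
  row <- firework[firework$cell_id == cell_id &
                    firework$issue_date == as_date(issue_date), ]
  if (nrow(row) != 1L) stop("no unique forecast issue for that cell/date",
                            call. = FALSE)
  w <- diurnal_weights()
  c(row$day0 * w, row$day1 * w)
}

#' Simulate daily dispensation counts
#'
#' Counts are Poisson (optionally negative-binomial) with mean
#' \deqn{\lambda = \mathrm{base\_rate} \cdot \frac{\mathrm{pop}}{10^4}
#'   \cdot \mathrm{dow}(d) \cdot \mathrm{hol}(d)
#'   \cdot e^{\beta \cdot \mathrm{PM}(h, d)},}
#' i.e. a weekday-dependent base rate per 10,000 residents, a holiday
#' closure multiplier, and a log-linear PM2.5 response.
#'
#' @param cfg a [scenario_config()].
#' @param hsda_exposure data frame `hsda_id`, `date`, `pm25`: the truth
#'   population-weighted exposure per health area.
#' @param populations named numeric vector of health-area populations.
#' @return data frame `hsda_id`, `date`, `count`.
#' @export
simulate_dispensations <- function(cfg, hsda_exposure, populations) {
  set.seed(cfg$seed + 4L)
  hol <- scenario_holidays(cfg)
  wd <- weekday_of(hsda_exposure$date)            # 0 = Sunday
  dow_i <- ifelse(wd == 0L, 7L, wd)               # config is Monday..Sunday
  lambda <- cfg$base_rate *
    populations[as.character(hsda_exposure$hsda_id)] / 1e4 *
    cfg$dow_multipliers[dow_i] *
    ifelse(hsda_exposure$date %in% hol, cfg$holiday_multiplier, 1) *
    exp(cfg$beta_pm * hsda_exposure$pm25)
  if (any(lambda > 1e7)) stop("count mean overflow: lambda > 1e7", call. = FALSE)
  counts <- if (cfg$overdispersion > 0)
    stats::rnbinom(length(lambda), size = cfg$overdispersion, mu = lambda)
  else stats::rpois(length(lambda), lambda)
  data.frame(hsda_id = hsda_exposure$hsda_id, date = hsda_exposure$date,
             count = counts, row.names = NULL)
}

#' Generate a complete synthetic scenario
#'
#' Composes the geography, truth field, monitors, predictor points,
#' numerical forecast and dispensation counts into one bundle holding
#' everything the forecasting pipeline consumes, plus the generating
#' parameters. Deterministic given the config's seeds.
#'
#' @param cfg a [scenario_config()].
#' @return list of class `scenario_bundle`: `cfg`, `geography`,
#'   `fields` (truth), `observations`, `firework` (daily means),
#'   `exposure` (capped population-weighted historic series),
#'   `exposure_truth` (uncapped), `indicators`, `holidays`.
#' @export
make_scenario <- function(cfg = scenario_config()) {
  validate_scenario_config(cfg)
  geo <- simulate_geography(cfg)
  fields <- simulate_smoke_fields(cfg, geo)
  observations <- simulate_observations(cfg, geo, fields)
  firework <- simulate_firework(cfg, geo, fields)
  exposure <- hsda_exposure_series(fields$cell_pm, geo$das, geo$cells, cap = 150)
  exposure_truth <- hsda_exposure_series(fields$cell_pm, geo$das, geo$cells,
                                         cap = Inf)
  pops <- stats::setNames(geo$hsdas$population, geo$hsdas$hsda_id)
  indicators <- simulate_dispensations(cfg, exposure_truth, pops)
  structure(list(cfg = cfg, geography = geo, fields = fields,
                 observations = observations, firework = firework,
                 exposure = exposure, exposure_truth = exposure_truth,
                 indicators = indicators, holidays = scenario_holidays(cfg)),
            class = "scenario_bundle")
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat(sprintf("<scenario_bundle> %d health areas, %d DAs, %d stations, %d cells\n",
              nrow(x$geography$hsdas), nrow(x$geography$das),
              nrow(x$geography$stations), nrow(x$geography$cells)))
  cat(sprintf("  truth %s..%s; evaluation %s..%s; seed %d\n",
              format(min(x$fields$dates)), format(max(x$fields$dates)),
              format(x$cfg$eval_start), format(x$cfg$eval_end), x$cfg$seed))
  invisible(x)
}
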