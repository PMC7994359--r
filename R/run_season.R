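# Season driver: trains the two forests on pre-evaluation data, then
# walks issue dates through the evaluation window producing blended
# PM2.5 and dispensation forecasts, and verifies both against
# observations.

#' Train the blend and health models for a scenario
#'
#' The blend model trains on monitor-station rows from the start of the
#' predictor record to the day before the evaluation window; the health
#' model trains on all health-area dates before the evaluation window
#' (subject to the 15 ug/m3 inclusion rule and low-exposure sampling).
#' Seeds are derived from the scenario seed at fixed offsets so the
#' whole train-forecast path is reproducible.
#'
#' @param bundle a `scenario_bundle` (or equivalent list of inputs).
#' @param seed base seed; defaults to the bundle's scenario seed.
#' @param blend_trees,health_trees forest sizes (defaults 1000).
#' @return list with `blend` and `health` models and the training
#'   tables.
#' @export
train_season_models <- function(bundle, seed = bundle$cfg$seed,
                                blend_trees = 1000, health_trees = 1000) {
  cfg <- bundle$cfg
  geo <- bundle$geography
  blend_dates <- seq(cfg$predictor_start + 1L, cfg$eval_start - 1L, by = "day")
  blend_rows <- build_blend_table(geo$stations, bundle$observations,
                                  bundle$fields$predictors, bundle$firework,
                                  geo$cells, blend_dates)
  blend <- fit_blend_model(blend_rows, n_trees = blend_trees, seed = seed + 10L)
  ind_train <- bundle$indicators[bundle$indicators$date < cfg$eval_start, ]
  health_rows <- build_health_table(ind_train, bundle$exposure,
                                    seed = seed + 11L,
                                    holidays = bundle$holidays)
  health <- fit_health_model(health_rows, n_trees = health_trees,
                             seed = seed + 12L)
  list(blend = blend, health = health,
       blend_rows = blend_rows, health_rows = health_rows)
}

#' Run a full evaluation season
#'
#' For every issue date in the evaluation window: assemble predictor
#' rows on the populated grid cells, predict the day0 blended PM2.5,
#' average with the numerical forecast's day1 means for the day1 blend,
#' extract each health area's worst-case (maximum) and minimum cell
#' values, forecast dispensation counts with the substitution scheme,
#' and finally verify PM2.5 forecasts against the uncapped
#' station-comparator series and count forecasts against observed
#' counts.
#'
#' Only data available at issue time are used: predictors are lagged
#' one day, the count history ends the day before the issue date, and
#' the numerical forecast is the morning issue itself.
#'
#' @param bundle a `scenario_bundle`.
#' @param models optional output of [train_season_models()]; trained on
#'   the fly if omitted.
#' @param pm_scale multiplier applied to the blended PM2.5 forecasts
#'   before they enter the health model (1 for normal operation; used
#'   to probe robustness of the count forecasts to exposure
#'   mis-prediction).
#' @param out_dir optional directory; when given, forecast and
#'   evaluation tables are written there as commented CSV/JSON.
#' @return list of class `season_run`: forecasts, comparator series,
#'   per-area evaluation tables and province summaries, plus the models
#'   and bundle.
#' @export
run_season <- function(bundle, models = NULL, pm_scale = 1, out_dir = NULL) {
  cfg <- bundle$cfg
  geo <- bundle$geography
  if (is.null(models)) models <- train_season_models(bundle)
  pcells <- geo$cells[geo$cells$populated, ]
  pcell_hsda <- geo$cell_hsda[geo$cells$populated]
  issues <- eval_dates(cfg)
  hsdas <- sort(geo$hsdas$hsda_id)
  pops <- stats::setNames(geo$hsdas$population, geo$hsdas$hsda_id)
  exp_hist <- bundle$exposure
  pm_rows <- list(); ind_rows <- list(); skipped <- character()
  for (ii in seq_along(issues)) {
    d <- issues[ii]
    res <- tryCatch({
      cp <- build_cell_predictors(pcells, geo$stations, bundle$observations,
                                  bundle$fields$predictors, bundle$firework,
                                  d)
      day0 <- predict_day0(models$blend, cp)
      fw <- bundle$firework[bundle$firework$issue_date == d, ]
      fw1 <- fw$day1[match(cp$cell_id, fw$cell_id)]
      day1 <- blend_day1(day0, fw1)
      chs <- pcell_hsda[match(cp$cell_id, pcells$cell_id)]
      pm_d <- do.call(rbind, lapply(hsdas, function(h) {
        sel <- chs == h
        if (!any(sel)) return(NULL)
        data.frame(hsda_id = h, issue_date = d,
                   day0 = hsda_forecast_exposure(day0[sel]),
                   day1 = hsda_forecast_exposure(day1[sel]),
                   min0 = min(day0[sel]), min1 = min(day1[sel]))
      }))
      ind_d <- do.call(rbind, lapply(seq_len(nrow(pm_d)), function(i) {
        h <- pm_d$hsda_id[i]
        hist <- bundle$indicators[bundle$indicators$hsda_id == h &
                                    bundle$indicators$date < d,
                                  c("date", "count")]
        lag <- exp_hist$pm25[exp_hist$hsda_id == h & exp_hist$date == d - 1L]
        fc <- forecast_indicator(models$health, hist,
                                 list(day0 = pm_scale * pm_d$day0[i],
                                      day1 = pm_scale * pm_d$day1[i]),
                                 lag, d, bundle$holidays)
        data.frame(hsda_id = h, issue_date = d,
                   day0 = fc$day0, day1 = fc$day1)
      }))
      list(pm = pm_d, ind = ind_d)
    }, error = function(e) {
      message("issue date ", format(d), " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) { skipped <- c(skipped, format(d)); next }
    pm_rows[[length(pm_rows) + 1L]] <- res$pm
    ind_rows[[length(ind_rows) + 1L]] <- res$ind
  }
  pm_forecasts <- do.call(rbind, pm_rows)
  indicator_forecasts <- do.call(rbind, ind_rows)
  comparator <- station_comparator_series(geo$stations, bundle$observations,
                                          geo$das)
  pm_obs <- data.frame(hsda_id = comparator$hsda_id, date = comparator$date,
                       value = comparator$pm25)
  ind_obs <- data.frame(hsda_id = bundle$indicators$hsda_id,
                        date = bundle$indicators$date,
                        value = bundle$indicators$count)
  pm_eval <- evaluate_forecasts(
    pm_forecasts[pm_forecasts$hsda_id %in% unique(pm_obs$hsda_id), ],
    pm_obs, pops, indicator = FALSE)
  ind_eval <- evaluate_forecasts(indicator_forecasts, ind_obs, pops,
                                 indicator = TRUE)
  run <- structure(list(
    bundle = bundle, models = models, pm_scale = pm_scale,
    pm_forecasts = pm_forecasts, indicator_forecasts = indicator_forecasts,
    comparator = comparator, skipped = skipped,
    evaluation = list(pm = pm_eval, indicator = ind_eval),
    summary = list(pm = summarize_evaluation(pm_eval),
                   indicator = summarize_evaluation(ind_eval))
  ), class = "season_run")
  if (!is.null(out_dir)) write_season_run(run, out_dir)
  run
}

#' @export
print.season_run <- function(x, ...) {
  nh <- length(unique(x$indicator_forecasts$hsda_id))
  cat(sprintf("<season_run> %d issue dates, %d health areas%s\n",
              length(unique(x$indicator_forecasts$issue_date)), nh,
              if (length(x$skipped)) sprintf(" (%d skipped)", length(x$skipped))
              else ""))
  s <- x$summary$indicator
  cat(sprintf("  indicator (both horizons): pop-weighted IOA %.3f, RMSE %.2f, within-20%% %.0f%%\n",
              s$pw[["ioa"]], s$pw[["rmse"]], s$pw[["pct_within20"]]))
  s <- x$summary$pm
  cat(sprintf("  PM2.5     (both horizons): pop-weighted IOA %.3f, RMSE %.2f ug/m3\n",
              s$pw[["ioa"]], s$pw[["rmse"]]))
  invisible(x)
}

#' Assemble the daily report for one health area
#'
#' The report mirrors a two-sided layout: the 21 days preceding the
#' issue date on the left (observed monitor PM2.5, the day0 forecasts
#' issued on those days, observed and forecast counts) and the upcoming
#' two days on the right (the range of blended PM2.5 over the area's
#' populated cells — whose maximum is exactly the value fed to the
#' health model — plus the count forecasts). At the start of the
#' forecast record the history window is shorter and flagged.
#'
#' @param run a `season_run`.
#' @param hsda_id health area.
#' @param issue_date issue date (must have forecasts in `run`).
#' @return list of class `daily_report`.
#' @export
build_daily_report <- function(run, hsda_id, issue_date) {
  issue_date <- as_date(issue_date)
  pm <- run$pm_forecasts[run$pm_forecasts$hsda_id == hsda_id, ]
  ind <- run$indicator_forecasts[run$indicator_forecasts$hsda_id == hsda_id, ]
  today_pm <- pm[pm$issue_date == issue_date, ]
  today_ind <- ind[ind$issue_date == issue_date, ]
  if (nrow(today_pm) == 0L || nrow(today_ind) == 0L)
    stop("no forecasts issued for area ", hsda_id, " on ", format(issue_date),
         call. = FALSE)
  hdates <- seq(issue_date - 21L, issue_date - 1L, by = "day")
  hdates <- hdates[hdates >= min(pm$issue_date)]
  comp <- run$comparator[run$comparator$hsda_id == hsda_id, ]
  obs_counts <- run$bundle$indicators[run$bundle$indicators$hsda_id == hsda_id, ]
  history <- data.frame(
    date = hdates,
    pm_obs = round(comp$pm25[match(hdates, comp$date)], 1),
    pm_fc_day0 = round(pm$day0[match(hdates, pm$issue_date)], 1),
    count_obs = obs_counts$count[match(hdates, obs_counts$date)],
    count_fc_day0 = round(ind$day0[match(hdates, ind$issue_date)], 1))
  structure(list(
    hsda_id = hsda_id, issue_date = issue_date,
    history = history,
    history_flagged = nrow(history) < 21L,
    today = list(pm_range = round(c(min = today_pm$min0, max = today_pm$day0), 1),
                 count = round(today_ind$day0, 1)),
    tomorrow = list(pm_range = round(c(min = today_pm$min1, max = today_pm$day1), 1),
                    count = round(today_ind$day1, 1))
  ), class = "daily_report")
}

#' @export
print.daily_report <- function(x, ...) {
  cat(sprintf("<daily_report> area %s, issued %s%s\n", x$hsda_id,
              format(x$issue_date),
              if (x$history_flagged) sprintf(" [history %d/21 days]",
                                             nrow(x$history)) else ""))
  cat(sprintf("  today:    PM %.1f-%.1f ug/m3, %.1f dispensations\n",
              x$today$pm_range[["min"]], x$today$pm_range[["max"]], x$today$count))
  cat(sprintf("  tomorrow: PM %.1f-%.1f ug/m3, %.1f dispensations\n",
              x$tomorrow$pm_range[["min"]], x$tomorrow$pm_range[["max"]],
              x$tomorrow$count))
  invisible(x)
}
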