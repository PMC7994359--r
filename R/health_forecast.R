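# Syndromic health forecasting: reliever-inhaler dispensation counts
# forecast from PM2.5 exposure plus temporal features with a random
# forest, using the forecast-substitution scheme at issue time.
#
# Feature row for one health area and date:
#   pm_day0  ug/m3   population-weighted exposure on the date (variable 1)
#   pm_lag1  ug/m3   exposure on the day before (variable 2)
#   dow12    count   trailing same-weekday mean, 12 weeks, holiday-aware
#   dow4     count   trailing same-weekday mean, 4 weeks, holiday-aware
#   week     1-53    ISO week of year

health_predictor_names <- c("pm_day0", "pm_lag1", "dow12", "dow4", "week")

weekday_of <- function(d) as.POSIXlt(d)$wday  # 0 = Sunday ... 6 = Saturday

# internal: trailing same-weekday mean with holiday handling.
# Returns list(value, n_used, flagged).
trailing_dow <- function(series, date, k_weeks, holidays) {
  date <- as_date(date)
  sd_ <- as_date(series$date)
  lookback <- date - 14L * k_weeks  # extend to at most 2k weeks
  ok <- weekday_of(sd_) == weekday_of(date) & sd_ < date & sd_ >= lookback &
    !(sd_ %in% holidays)
  cand <- series$count[ok][order(sd_[ok], decreasing = TRUE)]
  n <- min(length(cand), k_weeks)
  if (n == 0L) stop("no qualifying same-weekday dates before ", format(date),
                    call. = FALSE)
  list(value = mean(cand[seq_len(n)]), n_used = n, flagged = n < k_weeks)
}

# vectorised trailing means for every row of one health area's series:
# returns data frame with dow12/dow4 (NA where no qualifying date)
trailing_features_hsda <- function(ind, holidays) {
  n <- nrow(ind)
  wd <- weekday_of(ind$date)
  nonhol <- !(ind$date %in% holidays)
  dow12 <- dow4 <- rep(NA_real_, n)
  one <- function(gd, gc, gh, jj, k) {
    idx <- seq_len(jj - 1L)
    el <- idx[gh[idx] & gd[idx] >= gd[jj] - 14L * k]
    if (!length(el)) return(NA_real_)
    mean(gc[el[seq.int(max(1L, length(el) - k + 1L), length(el))]])
  }
  for (w in unique(wd)) {
    g <- which(wd == w)
    o <- g[order(ind$date[g])]
    gd <- ind$date[o]; gc <- ind$count[o]; gh <- nonhol[o]
    for (jj in seq_along(o)) {
      dow12[o[jj]] <- one(gd, gc, gh, jj, 12L)
      dow4[o[jj]] <- one(gd, gc, gh, jj, 4L)
    }
  }
  data.frame(dow12 = dow12, dow4 = dow4)
}

#' Trailing same-weekday mean, holiday aware
#'
#' The mean dispensation count on the most recent `k_weeks` dates that
#' share `date`'s day of week, lie strictly before it, and are not
#' holidays. Because pharmacies largely close on holidays, holiday
#' counts would bias the weekday trend downward; skipped holidays extend
#' the lookback, to at most `2 * k_weeks` weeks. If fewer than `k_weeks`
#' qualifying dates exist in that window the mean of those available is
#' returned with a warning; none at all is an error.
#'
#' @param series data frame `date`, `count` for one health area.
#' @param date the date the mean is computed for (itself excluded).
#' @param k_weeks number of weeks (4 for the short-term trend, 12 for
#'   the long-term trend).
#' @param holidays `Date` vector of holiday dates.
#' @export
trailing_dow_mean <- function(series, date, k_weeks, holidays = as.Date(character())) {
  r <- trailing_dow(series, date, k_weeks, holidays)
  if (r$flagged)
    warning(sprintf("only %d of %d qualifying same-weekday dates before %s",
                    r$n_used, k_weeks, format(date)), call. = FALSE)
  r$value
}

#' Assemble the health-model training table
#'
#' One row per health area and date with the five features and the
#' observed count as target. For training efficiency the table keeps
#' every date whose population-weighted exposure exceeds `threshold`
#' (15 ug/m3 by default — the smoke-affected dates that carry the
#' exposure signal) plus a seeded random sample of fraction
#' `low_sample_frac` of the remaining low-exposure dates. Dates without
#' an exposure lag or without at least one qualifying same-weekday
#' history date are skipped.
#'
#' @param indicator data frame `hsda_id`, `date`, `count`.
#' @param exposure data frame `hsda_id`, `date`, `pm25`
#'   (population-weighted historic series).
#' @param threshold exposure inclusion threshold (ug/m3), default 15.
#' @param low_sample_frac sampled fraction of low-exposure dates,
#'   default 0.25.
#' @param seed integer RNG seed for the low-exposure sample (required).
#' @param holidays `Date` vector for the trailing means.
#' @return data frame of feature rows with `target`.
#' @export
build_health_table <- function(indicator, exposure, threshold = 15,
                               low_sample_frac = 0.25, seed,
                               holidays = as.Date(character())) {
  if (missing(seed)) stop("`seed` must be supplied explicitly", call. = FALSE)
  stopifnot_scalar_num(threshold, "threshold", min = 0)
  if (low_sample_frac < 0 || low_sample_frac > 1)
    stop("`low_sample_frac` must be in [0, 1]", call. = FALSE)
  indicator$date <- as_date(indicator$date)
  exposure$date <- as_date(exposure$date)
  rows <- list()
  for (h in sort(unique(indicator$hsda_id))) {
    ind <- indicator[indicator$hsda_id == h, ]
    ind <- ind[order(ind$date), ]
    exp_h <- exposure[exposure$hsda_id == h, ]
    pm <- exp_h$pm25[match(ind$date, exp_h$date)]
    pm_lag <- exp_h$pm25[match(ind$date - 1L, exp_h$date)]
    tr <- trailing_features_hsda(ind, holidays)
    keep <- !is.na(pm) & !is.na(pm_lag) & !is.na(tr$dow12) & !is.na(tr$dow4)
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      hsda_id = h, date = ind$date[keep],
      pm_day0 = pm[keep], pm_lag1 = pm_lag[keep],
      dow12 = tr$dow12[keep], dow4 = tr$dow4[keep],
      week = week_of_year(ind$date[keep]),
      target = ind$count[keep], low = pm[keep] <= threshold)
  }
  if (!length(rows)) stop("no usable training rows", call. = FALSE)
  tbl <- do.call(rbind, rows)
  set.seed(seed)
  keep_low <- stats::runif(nrow(tbl)) <= low_sample_frac
  tbl <- tbl[!tbl$low | keep_low, , drop = FALSE]
  if (nrow(tbl) == 0L) stop("no rows retained after sampling", call. = FALSE)
  tbl$low <- NULL
  rownames(tbl) <- NULL
  tbl
}

#' Fit the health-forecasting random forest
#'
#' Regression forest of observed dispensation counts on the five
#' features, 1,000 trees and two candidate variables per split by
#' default, with out-of-bag RMSE and pseudo-R2 retained as for
#' [fit_blend_model()].
#'
#' @param rows training table from [build_health_table()].
#' @param n_trees,vars_per_split forest hyperparameters.
#' @param seed integer RNG seed (required).
#' @return object of class `health_model`.
#' @export
fit_health_model <- function(rows, n_trees = 1000, vars_per_split = 2, seed) {
  fit_forest(rows, health_predictor_names, n_trees, vars_per_split, seed,
             class = "health_model", min_rows = 50)
}

#' Forecast dispensation counts for today and tomorrow
#'
#' Applies the forecast-substitution scheme: the day0 (today) forecast
#' replaces the current-day exposure feature with the blended day0
#' PM2.5 forecast, keeping yesterday's observed exposure as the lag
#' feature; the day1 (tomorrow) forecast replaces the current-day
#' feature with the blended day1 forecast and the lag feature with the
#' blended day0 forecast. Trailing day-of-week means and the week of
#' year are recomputed for each horizon's own date from the observed
#' count history (which ends the day before `issue_date`, so no future
#' information is used).
#'
#' @param model a `health_model`.
#' @param history data frame `date`, `count`: observed counts for one
#'   health area up to `issue_date - 1`.
#' @param pm_fc list or one-row data frame with `day0`, `day1`: the
#'   blended PM2.5 forecasts for this health area (worst-case cell
#'   maximum).
#' @param pm_obs_lag1 yesterday's observed population-weighted exposure
#'   (ug/m3).
#' @param issue_date forecast issue date.
#' @param holidays `Date` vector for the trailing means.
#' @return list of class `forecast_pair`: `issue_date`, `day0`, `day1`
#'   (non-negative ensemble means), `kind = "indicator"`.
#' @export
forecast_indicator <- function(model, history, pm_fc, pm_obs_lag1,
                               issue_date, holidays = as.Date(character())) {
  stopifnot(inherits(model, "health_model"))
  if (is.null(pm_fc$day0) || is.null(pm_fc$day1) ||
      is.na(pm_fc$day0) || is.na(pm_fc$day1))
    stop("missing PM2.5 forecast", call. = FALSE)
  issue_date <- as_date(issue_date)
  if (any(as_date(history$date) >= issue_date))
    stop("`history` must end before `issue_date`", call. = FALSE)
  feats <- function(d, pm0, pm1) {
    data.frame(pm_day0 = pm0, pm_lag1 = pm1,
               dow12 = trailing_dow(history, d, 12L, holidays)$value,
               dow4 = trailing_dow(history, d, 4L, holidays)$value,
               week = week_of_year(d))
  }
  x0 <- feats(issue_date, pm_fc$day0, pm_obs_lag1)
  x1 <- feats(issue_date + 1L, pm_fc$day1, pm_fc$day0)
  p <- pmax(as.numeric(stats::predict(model$forest, rbind(x0, x1))), 0)
  structure(list(issue_date = issue_date, day0 = p[1], day1 = p[2],
                 kind = "indicator"), class = "forecast_pair")
}

#' @export
print.forecast_pair <- function(x, ...) {
  cat(sprintf("<forecast_pair %s> issued %s: day0 %.1f, day1 %.1f\n",
              x$kind, format(x$issue_date), x$day0, x$day1))
  invisible(x)
}
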