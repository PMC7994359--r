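# Blended PM2.5 forecasting: a random forest over six observation- and
# model-based predictors, out-of-bag verification, and the day+1
# averaging rule.
#
# Predictor vector for one location-date (units):
#   pm25_lag1  ug/m3   yesterday's 24-h mean at the nearest monitor
#   aod        --      yesterday's nearest satellite AOD within 50 km
#   frp        MW      yesterday's mean fire radiative power within 100 km
#   hms        0/1     yesterday's smoke-plume presence at the grid cell
#   vi         1-100   yesterday's venting index at the nearest VI station
#   firework   ug/m3   today's daily-mean numerical smoke forecast

#' Collapse one 48-h hourly forecast into day0/day1 daily means
#'
#' The numerical smoke forecast issues 48 hourly PM2.5 values each
#' morning; the day0 (today) forecast is the mean of hours 1-24 and the
#' day1 (tomorrow) forecast the mean of hours 25-48.
#'
#' @param hourly numeric vector of exactly 48 non-negative values.
#' @return named numeric `c(day0 = , day1 = )`.
#' @export
firework_daily <- function(hourly) {
  if (length(hourly) != 48L)
    stop("`hourly` must contain exactly 48 values", call. = FALSE)
  if (anyNA(hourly) || any(hourly < 0))
    stop("`hourly` values must be non-negative and non-missing", call. = FALSE)
  c(day0 = mean(hourly[1:24]), day1 = mean(hourly[25:48]))
}

#' Daily means for an hourly forecast table
#'
#' Vectorised form of [firework_daily()] for a long hourly table as read
#' from `firework.csv`.
#'
#' @param hourly_df data frame `cell_id`, `issue_date`, `hour` (1-48),
#'   `pm25`.
#' @return data frame `cell_id`, `issue_date`, `day0`, `day1`.
#' @export
firework_daily_table <- function(hourly_df) {
  if (any(hourly_df$pm25 < 0)) stop("forecast values must be >= 0", call. = FALSE)
  horizon <- ifelse(hourly_df$hour <= 24, "day0", "day1")
  agg <- stats::aggregate(pm25 ~ cell_id + issue_date + horizon,
                          data = cbind(hourly_df, horizon = horizon), FUN = mean)
  wide <- stats::reshape(agg, idvar = c("cell_id", "issue_date"),
                         timevar = "horizon", direction = "wide")
  names(wide) <- sub("^pm25\\.", "", names(wide))
  wide$issue_date <- as_date(wide$issue_date)
  wide[order(wide$issue_date, wide$cell_id), c("cell_id", "issue_date", "day0", "day1")]
}

# subset the predictor tables to one (lag) date
predictors_on <- function(predictors, lag_date) {
  lapply(predictors, function(tbl) tbl[tbl$date == lag_date, , drop = FALSE])
}

# assemble one predictor row for a location; `pred_day` is the output of
# predictors_on(): aod/frp/vi with id,x,y,value columns; hms with
# cell_id,flag
predictor_row <- function(loc, nearest_cell_id, fw_day0, pm25_lag1, pred_day,
                          aod_radius = 50, frp_radius = 100) {
  hms <- pred_day$hms$flag[match(nearest_cell_id, pred_day$hms$cell_id)]
  data.frame(
    pm25_lag1 = pm25_lag1,
    aod = nearest_value(loc, pred_day$aod, aod_radius),
    frp = radius_mean(loc, pred_day$frp, frp_radius),
    hms = if (length(hms) == 0L || is.na(hms)) 0 else as.numeric(hms),
    vi = nearest_value(loc, pred_day$vi),
    firework = fw_day0
  )
}

#' Assemble the blend-model training table
#'
#' One row per monitor station and date with the six predictors and the
#' observed 24-h mean PM2.5 as target. Predictors pm25_lag1/aod/frp/
#' hms/vi are taken on the day before the target date; the numerical
#' forecast covariate is the day0 daily mean issued on the target date.
#' Targets are truncated at the 150 ug/m3 cap for consistency with the
#' historic exposure model. Rows lacking a target, the lag-1 monitor
#' value, the venting index, or the forecast covariate are dropped;
#' missing AOD is imputed with the training-set median, which is
#' recorded in the `imputation` attribute and reused at prediction time.
#'
#' @param stations data frame `station_id`, `x_km`, `y_km`.
#' @param observations data frame `station_id`, `date`, `pm25`.
#' @param predictors list of long tables: `aod`, `frp`, `vi` (columns
#'   `date`, `id`, `x`, `y`, `value`) and `hms` (`date`, `cell_id`,
#'   `flag`).
#' @param firework data frame `cell_id`, `issue_date`, `day0`, `day1`.
#' @param cells data frame `cell_id`, `x_km`, `y_km` (for the hms and
#'   forecast lookup at each station).
#' @param dates `Date` vector of target dates.
#' @param cap target truncation limit, default 150.
#' @return data frame of training rows with attribute `imputation`.
#' @export
build_blend_table <- function(stations, observations, predictors, firework,
                              cells, dates, cap = 150) {
  dates <- as_date(dates)
  obs_key <- paste(observations$station_id, observations$date)
  obs_at <- function(sid, d) {
    v <- observations$pm25[match(paste(sid, d), obs_key)]
    v
  }
  st_cell <- cells$cell_id[assign_nearest(stations, cells)]
  fw_key <- paste(firework$cell_id, firework$issue_date)
  rows <- list()
  for (d in seq_along(dates)) {
    day <- dates[d]; lag <- day - 1L
    fw0 <- firework$day0[match(paste(st_cell, day), fw_key)]
    pred_day <- predictors_on(predictors, lag)
    for (s in seq_len(nrow(stations))) {
      target <- obs_at(stations$station_id[s], day)
      lag1 <- obs_at(stations$station_id[s], lag)
      if (is.na(target) || is.na(lag1) || is.na(fw0[s])) next
      pr <- predictor_row(c(stations$x_km[s], stations$y_km[s]),
                          st_cell[s], fw0[s], lag1, pred_day)
      if (is.na(pr$vi)) next
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(station_id = stations$station_id[s], date = day),
        pr, data.frame(target = cap_pm(target, cap)))
    }
  }
  if (!length(rows)) stop("no complete training rows", call. = FALSE)
  tbl <- do.call(rbind, rows)
  med <- stats::median(tbl$aod, na.rm = TRUE)
  tbl$aod[is.na(tbl$aod)] <- med
  attr(tbl, "imputation") <- c(aod = med)
  tbl
}

blend_predictor_names <- c("pm25_lag1", "aod", "frp", "hms", "vi", "firework")

#' Fit the blended-forecast random forest
#'
#' Regression forest of the observed 24-h PM2.5 on the six predictors,
#' with 1,000 trees and three candidate variables per split by default.
#' Out-of-bag (OOB) predictions — for each row, the average over trees
#' that did not sample it — are retained and used for the model's RMSE
#' and pseudo-R2 (fraction of target variance explained). Reproducible
#' given `seed`.
#'
#' @param rows training table from [build_blend_table()].
#' @param n_trees,vars_per_split forest size and per-split predictor
#'   subset (defaults 1000 and 3).
#' @param seed integer RNG seed (required).
#' @return object of class `blend_model`.
#' @export
fit_blend_model <- function(rows, n_trees = 1000, vars_per_split = 3, seed) {
  fit_forest(rows, blend_predictor_names, n_trees, vars_per_split, seed,
             class = "blend_model", min_rows = 50)
}

# shared forest fitting for the blend and health models
fit_forest <- function(rows, predictors, n_trees, vars_per_split, seed,
                       class, min_rows) {
  if (missing(seed)) stop("`seed` must be supplied explicitly", call. = FALSE)
  if (!all(predictors %in% names(rows)))
    stop("missing predictor columns: ",
         paste(setdiff(predictors, names(rows)), collapse = ", "), call. = FALSE)
  y <- rows$target
  if (length(y) < min_rows)
    warning(sprintf("only %d training rows; forest may be unstable", length(y)),
            call. = FALSE)
  if (length(y) == 0L) stop("no training rows", call. = FALSE)
  if (stats::sd(y) == 0) stop("degenerate constant target", call. = FALSE)
  x <- rows[predictors]
  set.seed(seed)
  forest <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                       mtry = vars_per_split)
  oob <- data.frame(target = y, oob_pred = as.numeric(forest$predicted))
  m <- compute_oob_metrics(oob)
  imp <- attr(rows, "imputation")
  if (is.null(imp) && "aod" %in% predictors)
    imp <- c(aod = stats::median(rows$aod, na.rm = TRUE))
  structure(list(
    forest = forest,
    n_trees = n_trees, vars_per_split = vars_per_split, seed = seed,
    imputation = imp,
    oob = oob, oob_rmse = m[["rmse"]], oob_pseudo_r2 = m[["pseudo_r2"]],
    training_summary = list(n_rows = length(y),
                            target_mean = mean(y), target_sd = stats::sd(y)),
    version = 1L
  ), class = c(class, "smokecast_forest"))
}

compute_oob_metrics <- function(oob) {
  bad <- !is.finite(oob$oob_pred)
  if (any(bad)) {
    warning(sum(bad), " rows had no out-of-bag predictions; excluded",
            call. = FALSE)
    oob <- oob[!bad, ]
  }
  mse <- mean((oob$oob_pred - oob$target)^2)
  # population variance of the target, per the variance-explained definition
  vpop <- mean((oob$target - mean(oob$target))^2)
  c(rmse = sqrt(mse), pseudo_r2 = 1 - mse / vpop)
}

#' Out-of-bag verification metrics of a fitted forest
#'
#' RMSE over the retained out-of-bag predictions and the pseudo-R2
#' (1 - OOB mean squared error / population variance of the target).
#' pseudo-R2 can be negative for a model worse than the target mean; it
#' is reported unclipped.
#'
#' @param model a `blend_model` or `health_model`.
#' @return named numeric `c(rmse = , pseudo_r2 = )`.
#' @export
oob_metrics <- function(model) {
  stopifnot(inherits(model, "smokecast_forest"))
  compute_oob_metrics(model$oob)
}

#' @export
print.smokecast_forest <- function(x, ...) {
  cat(sprintf("<%s> %d trees, %d vars/split, %d rows, seed %d\n",
              class(x)[1], x$n_trees, x$vars_per_split,
              x$training_summary$n_rows, x$seed))
  cat(sprintf("  OOB RMSE %.2f, pseudo-R2 %.3f\n", x$oob_rmse, x$oob_pseudo_r2))
  invisible(x)
}

#' Day0 blended PM2.5 prediction
#'
#' Ensemble-mean prediction for one or more predictor rows, floored at 0
#' and capped at 150 ug/m3. Missing AOD is imputed with the median
#' recorded at training; a missing forecast covariate is an error.
#'
#' @param model a `blend_model`.
#' @param newdata data frame with the six predictor columns.
#' @param cap reporting cap (default 150).
#' @export
predict_day0 <- function(model, newdata, cap = 150) {
  stopifnot(inherits(model, "blend_model"))
  if (anyNA(newdata$firework))
    stop("missing numerical forecast covariate", call. = FALSE)
  if (!is.null(model$imputation) && anyNA(newdata$aod))
    newdata$aod[is.na(newdata$aod)] <- model$imputation[["aod"]]
  if (anyNA(newdata[blend_predictor_names]))
    stop("predictor rows incomplete after imputation", call. = FALSE)
  p <- as.numeric(stats::predict(model$forest, newdata))
  cap_pm(pmax(p, 0), cap)
}

#' Day1 blended PM2.5 forecast
#'
#' Tomorrow's blended value: the arithmetic mean of today's blended
#' day0 forecast and the numerical forecast's day1 daily mean, computed
#' before capping, then capped at 150 ug/m3.
#'
#' @param day0_blend,firework_day1 non-negative numerics (ug/m3),
#'   vectorised.
#' @param cap reporting cap (default 150).
#' @export
blend_day1 <- function(day0_blend, firework_day1, cap = 150) {
  if (any(day0_blend < 0) || any(firework_day1 < 0))
    stop("inputs must be non-negative", call. = FALSE)
  cap_pm((day0_blend + firework_day1) / 2, cap)
}

#' Predictor rows for grid cells on one issue date
#'
#' Applies the same predictor definitions as [build_blend_table()] at
#' grid-cell centroids for forecast application: yesterday's value from
#' the nearest monitor, nearest AOD within 50 km, mean FRP within
#' 100 km, the cell's own plume flag, the nearest venting index, and the
#' cell's day0 numerical forecast.
#'
#' @inheritParams build_blend_table
#' @param issue_date single `Date`.
#' @return data frame of cells with predictor columns (cells without a
#'   forecast covariate are dropped).
#' @export
build_cell_predictors <- function(cells, stations, observations, predictors,
                                  firework, issue_date) {
  issue_date <- as_date(issue_date)
  lag <- issue_date - 1L
  obs_lag <- observations[observations$date == lag, ]
  st_pts <- data.frame(id = stations$station_id,
                       x = stations$x_km, y = stations$y_km,
                       value = obs_lag$pm25[match(stations$station_id,
                                                  obs_lag$station_id)])
  st_pts <- st_pts[!is.na(st_pts$value), ]
  fw <- firework[firework$issue_date == issue_date, ]
  fw0 <- fw$day0[match(cells$cell_id, fw$cell_id)]
  pred_day <- predictors_on(predictors, lag)

  # vectorised nearest/radius lookups over all cells at once; ties in
  # the nearest lookups resolve to the lowest identifier, as in
  # nearest_value()
  d2_to <- function(px, py)
    outer(cells$x_km, px, "-")^2 + outer(cells$y_km, py, "-")^2
  nearest_of <- function(pts, max_radius = NULL) {
    if (nrow(pts) == 0L) return(rep(NA_real_, nrow(cells)))
    pts <- pts[order(pts$id), , drop = FALSE]
    D2 <- d2_to(pts$x, pts$y)
    j <- max.col(-D2, ties.method = "first")
    v <- pts$value[j]
    if (!is.null(max_radius))
      v[D2[cbind(seq_len(nrow(cells)), j)] > max_radius^2] <- NA_real_
    v
  }
  pm_lag1 <- nearest_of(st_pts)
  aod <- nearest_of(pred_day$aod, 50)
  vi <- nearest_of(pred_day$vi)
  frp <- if (nrow(pred_day$frp) == 0L) rep(0, nrow(cells)) else {
    inr <- d2_to(pred_day$frp$x, pred_day$frp$y) <= 100^2
    n_in <- rowSums(inr)
    ifelse(n_in > 0, as.numeric(inr %*% pred_day$frp$value) / pmax(n_in, 1), 0)
  }
  hms_flag <- pred_day$hms$flag[match(cells$cell_id, pred_day$hms$cell_id)]
  out <- data.frame(cell_id = cells$cell_id, issue_date = issue_date,
                    pm25_lag1 = pm_lag1, aod = aod, frp = frp,
                    hms = ifelse(is.na(hms_flag), 0, as.numeric(hms_flag)),
                    vi = vi, firework = fw0, row.names = NULL)
  out <- out[!is.na(out$firework) & !is.na(out$pm25_lag1) & !is.na(out$vi), ]
  if (nrow(out) == 0L)
    stop("no cells with complete predictors on ", format(issue_date), call. = FALSE)
  out
}
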