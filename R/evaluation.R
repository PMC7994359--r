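# Forecast verification: RMSE, index of agreement, within-tolerance
# fraction, rates, percent change, population-weighted summaries.

check_paired <- function(pred, obs, min_n = 1L) {
  if (length(pred) != length(obs))
    stop("`pred` and `obs` must have the same length", call. = FALSE)
  if (length(pred) < min_n)
    stop(sprintf("need at least %d paired values", min_n), call. = FALSE)
  if (anyNA(pred) || anyNA(obs))
    stop("paired series must not contain missing values; align and drop first",
         call. = FALSE)
  invisible(NULL)
}

#' Root mean square error
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\sum_i (P_i - O_i)^2 / n}} for predictions
#' \eqn{P} against observations \eqn{O}.
#'
#' @param pred,obs numeric vectors of equal length, same units.
#' @export
rmse <- function(pred, obs) {
  check_paired(pred, obs, 1L)
  sqrt(sum((pred - obs)^2) / length(obs))
}

#' Index of agreement
#'
#' Willmott's index of agreement,
#' \deqn{d = 1 - \frac{\sum_i (P_i - O_i)^2}
#'                   {\sum_i (|P_i - \bar O| + |O_i - \bar O|)^2},}
#' bounded in \[0, 1\]: 0 is no agreement, 1 perfect agreement. The
#' potential-error denominator is centred on the observed mean
#' \eqn{\bar O}, so the index is not symmetric in \eqn{P} and \eqn{O}.
#' When the denominator is zero (both series constant and equal) the
#' agreement is perfect and 1 is returned.
#'
#' @param pred,obs numeric vectors, length >= 2.
#' @export
ioa <- function(pred, obs) {
  check_paired(pred, obs, 2L)
  obar <- mean(obs)
  num <- sum((pred - obs)^2)
  den <- sum((abs(pred - obar) + abs(obs - obar))^2)
  if (den == 0) return(1)
  1 - num / den
}

#' Percent of forecasts within a fractional tolerance of the observation
#'
#' The share of days on which \eqn{|P_i - O_i| \le f\,O_i}, boundary
#' inclusive, expressed in percent. A forecast for a zero observation
#' counts as within tolerance only if it is exactly zero (zero counts
#' occur on holiday closures).
#'
#' @param pred,obs numeric vectors of equal length.
#' @param frac fractional tolerance, default 0.2 (within 20 percent).
#' @export
pct_within <- function(pred, obs, frac = 0.2) {
  check_paired(pred, obs, 1L)
  stopifnot_scalar_num(frac, "frac", min = 0)
  hit <- ifelse(obs == 0, pred == 0, abs(pred - obs) <= frac * obs)
  100 * mean(hit)
}

#' Express a count (or count error) as a rate per 10,000 population
#'
#' @param value dispensation count or RMSE in dispensations.
#' @param population persons, > 0.
#' @export
rate_per_10k <- function(value, population) {
  if (any(population <= 0)) stop("`population` must be > 0", call. = FALSE)
  value * 1e4 / population
}

#' Percent change relative to a reference value
#'
#' @param current,reference numeric; `reference` must be > 0.
#' @export
percent_change <- function(current, reference) {
  if (any(reference <= 0)) stop("`reference` must be > 0", call. = FALSE)
  100 * (current - reference) / reference
}

#' Population-weighted summary of a per-area metric
#'
#' Used to aggregate per-health-area verification metrics (IOA, RMSE,
#' within-20 percent) into one province-level figure, each area weighted
#' by its population.
#'
#' @param values named or unnamed numeric vector of per-area metrics.
#' @param populations matching positive numeric vector.
#' @export
pop_weighted_metric <- function(values, populations) {
  if (!is.null(names(values)) && !is.null(names(populations)))
    populations <- populations[names(values)]
  pop_weighted_mean(values, populations)
}

#' Pearson correlation
#'
#' Sample Pearson correlation between two series, e.g. health-area
#' population against the within-20 percent fraction. Requires n >= 3
#' and non-degenerate variance in both series.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @export
pearson <- function(x, y) {
  check_paired(x, y, 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}

#' Per-health-area verification table
#'
#' Scores paired forecast/observation series for each health area and
#' horizon. `forecasts` holds one row per (hsda_id, issue_date) with
#' `day0` and `day1` columns; `observed` holds the reference series
#' (`hsda_id`, `date`, `value`). The day0 forecast issued on date d is
#' paired with the observation on d; the day1 forecast with the
#' observation on d + 1. Horizons are scored separately and pooled
#' (`both`), matching how a two-a-day forecast product is reported.
#'
#' @param forecasts data frame `hsda_id`, `issue_date`, `day0`, `day1`.
#' @param observed data frame `hsda_id`, `date`, `value`.
#' @param populations named numeric vector of health-area populations.
#' @param indicator logical; if `TRUE` also report RMSE per 10,000.
#' @return data frame: `hsda_id`, `horizon`, `n`, `rmse`, `ioa`,
#'   `pct_within20`, `rmse_per_10k`, `population`.
#' @export
evaluate_forecasts <- function(forecasts, observed, populations, indicator = FALSE) {
  score <- function(p, o, h, horizon, n_pop) {
    r <- rmse(p, o)
    data.frame(hsda_id = h, horizon = horizon, n = length(p),
               rmse = r, ioa = ioa(p, o), pct_within20 = pct_within(p, o),
               rmse_per_10k = if (indicator) rate_per_10k(r, n_pop) else NA_real_,
               population = n_pop, row.names = NULL)
  }
  out <- lapply(sort(unique(forecasts$hsda_id)), function(h) {
    fc <- forecasts[forecasts$hsda_id == h, ]
    ob <- observed[observed$hsda_id == h, ]
    o0 <- ob$value[match(fc$issue_date, ob$date)]
    o1 <- ob$value[match(fc$issue_date + 1L, ob$date)]
    keep0 <- !is.na(o0); keep1 <- !is.na(o1)
    n_pop <- unname(populations[as.character(h)])
    rbind(score(fc$day0[keep0], o0[keep0], h, "day0", n_pop),
          score(fc$day1[keep1], o1[keep1], h, "day1", n_pop),
          score(c(fc$day0[keep0], fc$day1[keep1]),
                c(o0[keep0], o1[keep1]), h, "both", n_pop))
  })
  do.call(rbind, out)
}

#' Province-level summary of a verification table
#'
#' Population-weighted aggregates of the per-area metrics plus the
#' Pearson correlations of each metric with health-area population.
#'
#' @param eval_tbl output of [evaluate_forecasts()].
#' @param horizon which horizon to summarize (default `"both"`).
#' @return list with `pw` (population-weighted rmse/ioa/pct_within20),
#'   `range` per metric, and `cor_population` correlations (NA when
#'   fewer than 3 areas).
#' @export
summarize_evaluation <- function(eval_tbl, horizon = "both") {
  tb <- eval_tbl[eval_tbl$horizon == horizon, ]
  pw <- function(v) pop_weighted_metric(v, tb$population)
  safe_cor <- function(v) {
    if (nrow(tb) < 3 || stats::sd(v) == 0 || stats::sd(tb$population) == 0)
      return(NA_real_)
    pearson(tb$population, v)
  }
  metrics <- c("rmse", "ioa", "pct_within20",
               if (!all(is.na(tb$rmse_per_10k))) "rmse_per_10k")
  list(
    horizon = horizon,
    n_areas = nrow(tb),
    pw = vapply(metrics, function(m) pw(tb[[m]]), numeric(1)),
    range = vapply(metrics, function(m) range(tb[[m]]), numeric(2)),
    cor_population = vapply(metrics, function(m) safe_cor(tb[[m]]), numeric(1))
  )
}
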