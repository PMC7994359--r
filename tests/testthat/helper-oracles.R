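# naive element-by-element metric oracles, independent of the package's
# vectorised implementations

o_rmse <- function(p, o) {
  s <- 0
  for (i in seq_along(p)) s <- s + (p[i] - o[i])^2
  sqrt(s / length(p))
}

o_ioa <- function(p, o) {
  m <- sum(o) / length(o)
  num <- 0; den <- 0
  for (i in seq_along(p)) {
    num <- num + (p[i] - o[i])^2
    den <- den + (abs(p[i] - m) + abs(o[i] - m))^2
  }
  1 - num / den
}

o_pct <- function(p, o, frac = 0.2) {
  k <- 0
  for (i in seq_along(p)) {
    k <- k + if (o[i] == 0) (p[i] == 0) else (abs(p[i] - o[i]) <= frac * o[i])
  }
  100 * k / length(p)
}

o_cor <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# pooled same-weekday (4-week trailing mean) baseline RMSE and the
# model's pooled RMSE over both horizons, for one season run
baseline_comparison <- function(run, bundle) {
  sse_model <- 0; sse_base <- 0; n <- 0
  for (h in unique(run$indicator_forecasts$hsda_id)) {
    fc <- run$indicator_forecasts[run$indicator_forecasts$hsda_id == h, ]
    hist <- bundle$indicators[bundle$indicators$hsda_id == h, c("date", "count")]
    bl <- vapply(seq_len(nrow(fc)), function(i) {
      hh <- hist[hist$date < fc$issue_date[i], ]
      c(trailing_dow_mean(hh, fc$issue_date[i], 4, bundle$holidays),
        trailing_dow_mean(hh, fc$issue_date[i] + 1, 4, bundle$holidays))
    }, numeric(2))
    o0 <- hist$count[match(fc$issue_date, hist$date)]
    o1 <- hist$count[match(fc$issue_date + 1, hist$date)]
    sse_model <- sse_model + sum((c(fc$day0, fc$day1) - c(o0, o1))^2)
    sse_base <- sse_base + sum((c(bl[1, ], bl[2, ]) - c(o0, o1))^2)
    n <- n + 2 * nrow(fc)
  }
  c(model = sqrt(sse_model / n), baseline = sqrt(sse_base / n))
}

# blended day0 RMSE at the monitors vs the raw numerical forecast's,
# over the evaluation window of a bundle with a trained blend model
blend_vs_raw_rmse <- function(bundle, blend) {
  cfg <- bundle$cfg
  geo <- bundle$geography
  ev_rows <- build_blend_table(geo$stations, bundle$observations,
                               bundle$fields$predictors, bundle$firework,
                               geo$cells,
                               seq(cfg$eval_start, cfg$eval_end, by = "day"))
  obs_key <- paste(bundle$observations$station_id, bundle$observations$date)
  obs <- bundle$observations$pm25[match(paste(ev_rows$station_id, ev_rows$date),
                                        obs_key)]
  c(blend = rmse(predict_day0(blend, ev_rows), obs),
    raw = rmse(ev_rows$firework, obs))
}
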