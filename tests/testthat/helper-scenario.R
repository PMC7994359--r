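# Shared scenario fixtures, generated in code and memoised so expensive
# objects are built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# small 2-area scenario with a 30-day evaluation window, for fast
# structural checks
tiny_cfg <- function(seed = 7, ...) {
  base <- list(seed = seed, n_hsdas = 2, das_per_hsda = 12,
               n_stations_per_hsda = 2, n_vi_stations = 3,
               extent_km = 50, start_date = "2017-10-01",
               predictor_start = "2018-06-01",
               eval_start = "2018-07-15", eval_end = "2018-08-13",
               episodes_per_year = 2, n_aod_points = 30)
  do.call(scenario_config, utils::modifyList(base, list(...)))
}

# small 4-area scenario with the full 63-day evaluation window, for the
# cardinality/report/leakage checks
tiny63_cfg <- function(seed = 7, ...) {
  base <- list(seed = seed, n_hsdas = 4, das_per_hsda = 12,
               n_stations_per_hsda = 2, n_vi_stations = 4,
               extent_km = 60, start_date = "2017-06-01",
               predictor_start = "2018-05-01",
               eval_start = "2018-07-15", eval_end = "2018-09-15",
               episodes_per_year = 2, n_aod_points = 30)
  do.call(scenario_config, utils::modifyList(base, list(...)))
}

tiny63_bundle <- function() memo("tiny63_bundle", make_scenario(tiny63_cfg()))

tiny63_models <- function() memo("tiny63_models", {
  suppressWarnings(train_season_models(tiny63_bundle()))
})

tiny63_run <- function() memo("tiny63_run", {
  run_season(tiny63_bundle(), models = tiny63_models())
})

# random paired series for metric oracle checks
random_paired <- function(n) {
  list(p = stats::runif(n, 0, 50), o = stats::runif(n, 0, 50))
}
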