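# File interfaces: delimited-text scenario round-trip, commented output
# tables, model persistence, and YAML configuration.
#
# Every output file starts with comment lines recording the tool
# version, a hash of the generating configuration, and the seeds, so a
# run directory is self-describing.

pkg_version <- function() as.character(utils::packageVersion("smokecast"))

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(lapply(cfg, function(x)
    if (inherits(x, "Date")) format(x) else x)), tmp)
  unname(tools::md5sum(tmp))
}

output_header <- function(cfg = NULL) {
  c(sprintf("# smokecast %s", pkg_version()),
    if (!is.null(cfg)) sprintf("# config_hash %s", config_hash(cfg)),
    if (!is.null(cfg$seed)) sprintf("# seed %d", cfg$seed),
    if (!is.null(cfg$geo_seed)) sprintf("# geo_seed %d", cfg$geo_seed))
}

write_csv_commented <- function(df, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(cfg), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_commented <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a scenario bundle to a directory of delimited-text files
#'
#' Emits the plain-text interface consumed by the pipeline:
#' `stations.csv`, `observations.csv`, `das.csv`, `cells.csv`,
#' `hsdas.csv`, `vi_stations.csv`, `cell_pm.csv` (long truth field),
#' `aod.csv`, `frp.csv`, `hms.csv`, `vi.csv`, `firework.csv` (hourly,
#' 48 rows per cell-issue), `indicators.csv`, `exposure.csv`,
#' `holidays.csv` and `scenario.yaml` (the generating configuration,
#' including all seeds). A partial write aborts and removes the
#' directory.
#'
#' @param bundle a `scenario_bundle`.
#' @param dir target directory (created; must not already contain a
#'   scenario).
#' @export
write_scenario <- function(bundle, dir) {
  created <- !dir.exists(dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(dir, recursive = TRUE))
  cfg <- bundle$cfg
  geo <- bundle$geography
  w <- function(df, name) write_csv_commented(df, file.path(dir, name), cfg)
  w(geo$stations, "stations.csv")
  w(geo$das, "das.csv")
  w(geo$cells, "cells.csv")
  w(geo$hsdas, "hsdas.csv")
  w(geo$vi_stations, "vi_stations.csv")
  w(data.frame(station_id = bundle$observations$station_id,
               date = format(bundle$observations$date),
               pm25 = bundle$observations$pm25), "observations.csv")
  cp <- bundle$fields$cell_pm
  w(data.frame(cell_id = rep(rownames(cp), times = ncol(cp)),
               date = rep(colnames(cp), each = nrow(cp)),
               pm25 = as.numeric(cp)), "cell_pm.csv")
  for (nm in c("aod", "frp", "vi"))
    w(bundle$fields$predictors[[nm]], paste0(nm, ".csv"))
  w(bundle$fields$predictors$hms, "hms.csv")
  hours <- diurnal_weights()
  fw <- bundle$firework
  w(data.frame(cell_id = rep(fw$cell_id, each = 48L),
               issue_date = rep(format(fw$issue_date), each = 48L),
               hour = rep(1:48, times = nrow(fw)),
               pm25 = as.numeric(t(cbind(outer(fw$day0, hours),
                                         outer(fw$day1, hours))))),
    "firework.csv")
  w(bundle$indicators, "indicators.csv")
  w(bundle$exposure, "exposure.csv")
  w(data.frame(date = format(bundle$holidays)), "holidays.csv")
  writeLines(c(output_header(cfg),
               yaml::as.yaml(list(scenario = lapply(unclass(cfg), function(x)
                 if (inherits(x, "Date")) format(x) else x)))),
             file.path(dir, "scenario.yaml"))
  ok <- TRUE
  invisible(dir)
}

#' Read a scenario directory back into a bundle
#'
#' Inverse of [write_scenario()]: reconstructs the bundle (truth matrix,
#' predictor tables, daily forecast means from the hourly file,
#' exposure and indicator series) from the delimited-text files.
#'
#' @param dir directory written by [write_scenario()].
#' @return a `scenario_bundle`.
#' @export
read_scenario <- function(dir) {
  rd <- function(name) read_csv_commented(file.path(dir, name))
  ycfg <- yaml::read_yaml(file.path(dir, "scenario.yaml"))$scenario
  ycfg <- lapply(ycfg, function(x) if (is.list(x)) unlist(x) else x)
  ycfg$da_population_range <- as.integer(ycfg$da_population_range)
  ycfg$holidays <- if (!is.null(ycfg$holidays)) as.Date(ycfg$holidays)
  cfg <- do.call(scenario_config, ycfg[!vapply(ycfg, is.null, logical(1))])
  cells <- rd("cells.csv")
  cpm_long <- rd("cell_pm.csv")
  dates <- sort(unique(as.Date(cpm_long$date)))
  cell_pm <- matrix(NA_real_, nrow = nrow(cells), ncol = length(dates),
                    dimnames = list(cells$cell_id, format(dates)))
  cell_pm[cbind(match(cpm_long$cell_id, cells$cell_id),
                match(as.Date(cpm_long$date), dates))] <- cpm_long$pm25
  fix_date <- function(df, col = "date") { df[[col]] <- as.Date(df[[col]]); df }
  pred <- list(aod = fix_date(rd("aod.csv")), frp = fix_date(rd("frp.csv")),
               hms = fix_date(rd("hms.csv")), vi = fix_date(rd("vi.csv")))
  das <- rd("das.csv")
  da_cell <- assign_nearest(das, cells)
  cell_hsda <- rep(NA_integer_, nrow(cells))
  for (ci in unique(da_cell)) {
    sel <- da_cell == ci
    tab <- tapply(das$population[sel], das$hsda_id[sel], sum)
    cell_hsda[ci] <- as.integer(names(tab)[which.max(tab)])
  }
  geo <- list(cells = cells, das = das, hsdas = rd("hsdas.csv"),
              stations = rd("stations.csv"),
              vi_stations = rd("vi_stations.csv"),
              da_cell = da_cell, cell_hsda = cell_hsda)
  structure(list(
    cfg = cfg, geography = geo,
    fields = list(dates = dates, cell_pm = cell_pm, episodes = NULL,
                  predictors = pred),
    observations = fix_date(rd("observations.csv")),
    firework = firework_daily_table(fix_date(rd("firework.csv"), "issue_date")),
    exposure = fix_date(rd("exposure.csv")),
    exposure_truth = NULL,
    indicators = fix_date(rd("indicators.csv")),
    holidays = as.Date(rd("holidays.csv")$date)
  ), class = "scenario_bundle")
}

#' Persist a fitted model bundle
#'
#' Saves the model (with its seed, hyperparameters, imputation medians
#' and out-of-bag metrics) as a versioned serialized bundle.
#'
#' @param model a `blend_model` or `health_model` (or a list of them).
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format_version = 1L, smokecast = pkg_version(),
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (is.null(x$format_version) || x$format_version != 1L)
    stop("unrecognized model bundle format", call. = FALSE)
  x$model
}

#' Write the output tables of a season run
#'
#' Emits `pm_forecasts.csv`, `indicator_forecasts.csv`,
#' `evaluation.csv` (per-area, per-horizon verification for both PM2.5
#' and the indicator) and `summary.json` (population-weighted
#' aggregates and correlations with population) into `dir`.
#' Concentrations and count forecasts are printed with one decimal.
#'
#' @param run a `season_run`.
#' @param dir output directory (created if needed).
#' @export
write_season_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$bundle$cfg
  round1 <- function(df, cols) { df[cols] <- lapply(df[cols], round, 1); df }
  write_csv_commented(
    round1(run$pm_forecasts, c("day0", "day1", "min0", "min1")),
    file.path(dir, "pm_forecasts.csv"), cfg)
  write_csv_commented(
    round1(run$indicator_forecasts, c("day0", "day1")),
    file.path(dir, "indicator_forecasts.csv"), cfg)
  ev <- rbind(cbind(series = "pm25", run$evaluation$pm),
              cbind(series = "indicator", run$evaluation$indicator))
  write_csv_commented(ev, file.path(dir, "evaluation.csv"), cfg)
  jsonlite::write_json(
    list(smokecast = pkg_version(), config_hash = config_hash(cfg),
         seed = cfg$seed, pm_scale = run$pm_scale,
         skipped_issue_dates = run$skipped,
         pm25 = run$summary$pm, indicator = run$summary$indicator),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Write a daily report as JSON
#'
#' @param report a `daily_report`.
#' @param path file path.
#' @export
write_daily_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, Date = "ISO8601")
  invisible(path)
}

#' Run a season from a YAML configuration file
#'
#' The configuration carries a `scenario:` block (passed to
#' [scenario_config()]) and an optional `output: dir`. The scenario is
#' generated, models are trained, the season is run and, when an output
#' directory is configured, all artifacts are written there.
#'
#' @param config_path path to a YAML file.
#' @return a `season_run`, invisibly.
#' @export
run_season_from_config <- function(config_path) {
  conf <- yaml::read_yaml(config_path)
  cfg <- do.call(scenario_config, conf$scenario %||% list())
  bundle <- make_scenario(cfg)
  run <- run_season(bundle, out_dir = conf$output$dir %||% NULL)
  invisible(run)
}
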