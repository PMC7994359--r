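# Bundled reference data

#' 2018 smoke-season summary for British Columbia's health areas
#'
#' Published descriptive figures for the 16 Health Service Delivery
#' Areas of British Columbia over the 63-day 2018 smoke period (15
#' July - 15 September), with the same period of the mild 2016 season
#' for context: 2018 population, season-mean population-weighted PM2.5
#' from the observation-based exposure model for 2018 and 2016
#' (ug/m3), total reliever-inhaler dispensations in 2018, and the
#' percent increase over 2016 dispensations.
#'
#' Useful as a realistic worked example for the aggregation and
#' evaluation helpers: for instance,
#' `pop_weighted_mean(x$pm25_2018, x$population_2018)` reproduces the
#' province-wide season mean of 22.0 ug/m3.
#'
#' @return data frame with columns `hsda_id`, `name`,
#'   `population_2018`, `pm25_2018`, `pm25_2016`,
#'   `dispensations_2018`, `pct_increase_2016`.
#' @export
hsda_summary_2018 <- function() {
  utils::read.csv(system.file("extdata", "bc_hsda_summary_2018.csv",
                              package = "smokecast"),
                  stringsAsFactors = FALSE)
}
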