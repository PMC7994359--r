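# internal helpers: argument checks, dates, holidays

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  if (x < min)
    stop(sprintf("`%s` must be >= %s", name, format(min)), call. = FALSE)
  invisible(x)
}

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

#' ISO-8601 week of year
#'
#' Week numbering by the ISO-8601 convention: weeks start on Monday and
#' week 1 is the week containing the year's first Thursday. Computed
#' arithmetically (nearest-Thursday rule), so it is locale-independent.
#' Note that dates at the edges of a calendar year can belong to week 1
#' of the following year or week 52/53 of the preceding one.
#'
#' @param date a `Date` vector (or anything coercible with `as.Date()`).
#' @return integer vector of week numbers in 1..53.
#' @examples
#' week_of_year(as.Date("2018-01-01"))  # 1
#' week_of_year(as.Date("2018-12-31"))  # 1 (ISO week 1 of 2019)
#' @export
week_of_year <- function(date) {
  d <- as_date(date)
  wd <- as.integer(format(d, "%u"))        # 1 = Monday ... 7 = Sunday
  thursday <- d - wd + 4L
  jan1 <- as.Date(paste0(format(thursday, "%Y"), "-01-01"))
  as.integer(as.numeric(thursday - jan1) %/% 7L + 1L)
}

# Western (Gregorian) Easter Sunday, anonymous computus
easter_sunday <- function(year) {
  a <- year %% 19; b <- year %/% 100; c <- year %% 100
  d <- b %/% 4; e <- b %% 4; f <- (b + 8) %/% 25
  g <- (b - f + 1) %/% 3
  h <- (19 * a + b - d - g + 15) %% 30
  i <- c %/% 4; k <- c %% 4
  l <- (32 + 2 * e + 2 * i - h - k) %% 7
  m <- (a + 11 * h + 22 * l) %/% 451
  month <- (h + l - 7 * m + 114) %/% 31
  day <- ((h + l - 7 * m + 114) %% 31) + 1
  as.Date(sprintf("%04d-%02d-%02d", year, month, day))
}

nth_weekday <- function(year, month, weekday, n) {
  # weekday: 1 = Monday; n-th occurrence in the month
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  off <- (weekday - as.integer(format(first, "%u"))) %% 7
  first + off + 7 * (n - 1)
}

#' Statutory holiday calendar
#'
#' Holidays on which most pharmacies close, for one or more years, after
#' the British Columbia statutory calendar: New Year's Day, Family Day
#' (3rd Monday of February), Good Friday, Victoria Day (last Monday
#' before May 25), Canada Day, BC Day (1st Monday of August), Labour Day
#' (1st Monday of September), Thanksgiving (2nd Monday of October),
#' Remembrance Day, Christmas Day and Boxing Day. Users with a different
#' jurisdiction can supply any `Date` vector wherever a holiday calendar
#' is accepted.
#'
#' @param years integer vector of calendar years.
#' @return sorted `Date` vector.
#' @export
stat_holidays <- function(years) {
  out <- lapply(years, function(y) {
    c(as.Date(sprintf("%04d-01-01", y)),
      nth_weekday(y, 2, 1, 3),
      easter_sunday(y) - 2,
      {vd <- as.Date(sprintf("%04d-05-25", y))
       vd - ((as.integer(format(vd, "%u")) - 1) %% 7) - 7 * (format(vd, "%u") == "1")},
      as.Date(sprintf("%04d-07-01", y)),
      nth_weekday(y, 8, 1, 1),
      nth_weekday(y, 9, 1, 1),
      nth_weekday(y, 10, 1, 2),
      as.Date(sprintf("%04d-11-11", y)),
      as.Date(sprintf("%04d-12-25", y)),
      as.Date(sprintf("%04d-12-26", y)))
  })
  sort(unique(do.call(c, out)))
}

euclid_dist <- function(x0, y0, x, y) sqrt((x - x0)^2 + (y - y0)^2)
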