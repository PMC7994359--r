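# Geography and exposure assembly: nearest-neighbour predictor lookup,
# population weighting, health-area aggregation, and the reporting cap.
#
# All coordinates are planar, in kilometres, with Euclidean distance.
# Projecting real geography onto a plane is the caller's responsibility.

#' Value at the nearest point
#'
#' Returns the value attached to the point closest to `location`,
#' optionally restricted to a maximum search radius (e.g. nearest
#' satellite aerosol optical depth retrieval within 50 km). Distances are
#' Euclidean on planar km coordinates. Ties are broken deterministically
#' by the lowest point identifier.
#'
#' @param location numeric length-2, `c(x, y)` in km.
#' @param points data frame with columns `id`, `x`, `y`, `value`.
#' @param max_radius search radius in km, or `NULL` for unlimited.
#' @return the value of the qualifying nearest point, or `NA_real_` if no
#'   point lies within `max_radius` (or `points` is empty).
#' @export
nearest_value <- function(location, points, max_radius = NULL) {
  if (!is.null(max_radius)) stopifnot_scalar_num(max_radius, "max_radius", min = 0)
  if (is.null(points) || nrow(points) == 0L) return(NA_real_)
  d <- euclid_dist(location[1], location[2], points$x, points$y)
  ok <- if (is.null(max_radius)) rep(TRUE, length(d)) else d <= max_radius
  if (!any(ok)) return(NA_real_)
  d[!ok] <- Inf
  # order by distance then identifier so exact ties resolve to lowest id
  i <- order(d, points$id)[1L]
  points$value[i]
}

#' Mean of point values within a radius
#'
#' Arithmetic mean of the values of all points within `radius` km of
#' `location`, boundary inclusive. Returns 0 when no point qualifies:
#' used for fire radiative power, where absence of detected fire within
#' range means no radiative power rather than missing data.
#'
#' @inheritParams nearest_value
#' @param radius search radius in km, must be positive.
#' @export
radius_mean <- function(location, points, radius) {
  stopifnot_scalar_num(radius, "radius", min = 0)
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  if (is.null(points) || nrow(points) == 0L) return(0)
  d <- euclid_dist(location[1], location[2], points$x, points$y)
  ok <- d <= radius
  if (!any(ok)) return(0)
  mean(points$value[ok])
}

#' Population-weighted mean
#'
#' The exposure assigned to a health area: each member dissemination
#' area's value weighted by its resident population,
#' \eqn{\sum v_i p_i / \sum p_i}.
#'
#' @param values numeric vector of per-area values.
#' @param populations positive numeric vector, same length.
#' @export
pop_weighted_mean <- function(values, populations) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (length(values) != length(populations))
    stop("`values` and `populations` must have the same length", call. = FALSE)
  if (any(populations <= 0)) stop("populations must be > 0", call. = FALSE)
  sum(values * populations) / sum(populations)
}

#' Worst-case exposure for a health area
#'
#' The maximum forecast value over the *populated* grid cells of a health
#' area (cells containing at least one dissemination-area centroid).
#' The maximum is used instead of the population-weighted average so the
#' downstream health forecast reflects the worst-case scenario.
#'
#' @param cell_values numeric vector of per-cell values.
#' @param populated logical vector marking populated cells (default all).
#' @export
hsda_forecast_exposure <- function(cell_values, populated = rep(TRUE, length(cell_values))) {
  if (length(cell_values) != length(populated))
    stop("`cell_values` and `populated` must have the same length", call. = FALSE)
  v <- cell_values[populated]
  if (length(v) == 0L) stop("no populated cells in this health area", call. = FALSE)
  max(v)
}

#' Cap PM2.5 at the model's reporting limit
#'
#' Gridded exposure estimates and blended forecasts are capped at
#' 150 ug/m3, the upper limit of the historic training data for the
#' observation-based exposure model. Idempotent and order-preserving
#' below the cap.
#'
#' @param value non-negative numeric vector (ug/m3).
#' @param cap the cap (ug/m3), default 150.
#' @export
cap_pm <- function(value, cap = 150) {
  stopifnot_scalar_num(cap, "cap", min = 0)
  if (any(value < 0, na.rm = TRUE)) stop("PM2.5 values must be >= 0", call. = FALSE)
  pmin(value, cap)
}

#' Assign each dissemination area to its nearest grid cell
#'
#' A dissemination area takes the value of the grid cell whose centroid
#' is nearest its own centroid (ties to the lowest `cell_id`).
#'
#' @param das data frame with `da_id`, `x_km`, `y_km`.
#' @param cells data frame with `cell_id`, `x_km`, `y_km`.
#' @return integer vector: for each row of `das`, the row index into
#'   `cells` of its assigned cell.
#' @export
assign_nearest <- function(das, cells) {
  ord <- order(cells$cell_id %||% cells[[1]])
  cx <- cells$x_km[ord]; cy <- cells$y_km[ord]
  idx <- vapply(seq_len(nrow(das)), function(i) {
    d <- euclid_dist(das$x_km[i], das$y_km[i], cx, cy)
    which.min(d)  # first minimum = lowest id after ordering
  }, integer(1))
  ord[idx]
}

#' Daily population-weighted exposure series per health area
#'
#' Builds the health-area exposure series from a daily gridded PM2.5
#' field: each dissemination area inherits its nearest cell's value
#' (capped), and the health-area value is the population-weighted mean
#' over member dissemination areas.
#'
#' @param cell_pm numeric matrix, cells x dates, `dimnames` giving
#'   `cell_id` and ISO dates.
#' @param das data frame: `da_id`, `x_km`, `y_km`, `population`, `hsda_id`.
#' @param cells data frame: `cell_id`, `x_km`, `y_km`, rows matching
#'   `rownames(cell_pm)`.
#' @param cap reporting cap applied to cell values before weighting
#'   (`Inf` to disable).
#' @return long data frame `hsda_id`, `date`, `pm25`, `kind`.
#' @export
hsda_exposure_series <- function(cell_pm, das, cells, cap = 150) {
  stopifnot(identical(as.character(cells$cell_id), rownames(cell_pm)))
  da_cell <- assign_nearest(das, cells)
  capped <- pmin(cell_pm, cap)
  hsdas <- sort(unique(das$hsda_id))
  out <- lapply(hsdas, function(h) {
    sel <- das$hsda_id == h
    w <- das$population[sel]
    m <- capped[da_cell[sel], , drop = FALSE]
    data.frame(hsda_id = h,
               date = as.Date(colnames(cell_pm)),
               pm25 = as.numeric(crossprod(m, w)) / sum(w),
               kind = "population_weighted",
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Station-based comparator exposure series per health area
#'
#' The observation series the PM2.5 forecasts are verified against: a
#' daily weighted mean of the regulatory monitors inside each health
#' area. By default each station is weighted by the total population of
#' the dissemination areas for which it is the nearest station
#' (`weights = "population"`); `weights = "equal"` gives the simple mean
#' of stations. The series is *not* capped — monitors retain
#' observations above 150 ug/m3, which is what makes them a fair
#' reference for underprediction.
#'
#' Health areas containing no station are dropped with a warning (they
#' cannot be evaluated against monitors), not an error.
#'
#' @param stations data frame `station_id`, `x_km`, `y_km`, `hsda_id`.
#' @param observations data frame `station_id`, `date`, `pm25`.
#' @param das data frame `da_id`, `x_km`, `y_km`, `population`, `hsda_id`.
#' @param weights `"population"` or `"equal"`.
#' @return long data frame `hsda_id`, `date`, `pm25`, `kind`.
#' @export
station_comparator_series <- function(stations, observations, das,
                                      weights = c("population", "equal")) {
  weights <- match.arg(weights)
  hsdas <- sort(unique(das$hsda_id))
  no_station <- setdiff(hsdas, unique(stations$hsda_id))
  if (length(no_station))
    warning("health areas without stations excluded from comparator: ",
            paste(no_station, collapse = ", "), call. = FALSE)
  # station weight = population of DAs for which it is the nearest station
  st_xy <- data.frame(cell_id = stations$station_id,
                      x_km = stations$x_km, y_km = stations$y_km)
  da_st <- assign_nearest(das, st_xy)
  wpop <- vapply(seq_len(nrow(stations)), function(i)
    sum(das$population[da_st == i]), numeric(1))
  out <- lapply(intersect(hsdas, unique(stations$hsda_id)), function(h) {
    sid <- stations$station_id[stations$hsda_id == h]
    w <- switch(weights,
                population = wpop[match(sid, stations$station_id)],
                equal = rep(1, length(sid)))
    obs <- observations[observations$station_id %in% sid, ]
    if (all(w == 0)) w <- rep(1, length(sid))  # no DA nearest to any: fall back
    obs$w <- w[match(obs$station_id, sid)]
    agg <- stats::aggregate(cbind(num = pm25 * w, den = w) ~ date, data = obs, FUN = sum)
    data.frame(hsda_id = h, date = as_date(agg$date),
               pm25 = agg$num / agg$den, kind = "station_comparator",
               row.names = NULL)
  })
  do.call(rbind, out)
}
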