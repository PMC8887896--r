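# Sleep locations from GPS, tree assignment, travel distance, twilight.

#' Infer an individual's nightly sleep location from GPS
#'
#' The sleep location is the componentwise median of the first
#' `n_required` GPS fixes of the calendar morning that occur before the
#' cutoff time (animals remain stationary at the sleep site until then).
#' Mornings with fewer than `n_required` qualifying fixes are excluded.
#'
#' @param gps Data frame `individual_id`, `timestamp` (POSIXct), `lon`,
#'   `lat` for one individual, time-sorted.
#' @param date Calendar date (`Date`) of the morning.
#' @param cutoff Local clock cutoff (default `"06:15"`).
#' @param n_required Number of fixes to median (default 10).
#' @return List `location = c(lon, lat)` and `excluded = FALSE`, or
#'   `excluded = TRUE` with `reason = "lt_10_fixes"`.
#' @export
infer_sleep_location <- function(gps, date, cutoff = "06:15",
                                 n_required = 10) {
  t0 <- as.numeric(local_midnight(date))
  t1 <- t0 + hm_to_min(cutoff) * 60
  tt <- as.numeric(gps$timestamp)
  sel <- which(tt >= t0 & tt < t1)
  if (length(sel) < n_required) {
    return(list(excluded = TRUE, reason = "lt_10_fixes", location = NULL))
  }
  sel <- sel[order(tt[sel])][seq_len(n_required)]
  list(excluded = FALSE, reason = "none",
       location = c(lon = stats::median(gps$lon[sel]),
                    lat = stats::median(gps$lat[sel])))
}

#' Assign a sleep location to a tree crown
#'
#' A location inside a crown polygon is assigned to that tree; otherwise
#' it is assigned to the nearest crown if within `max_dist` meters of its
#' boundary, and excluded beyond that. Nearest-crown ties break to the
#' smallest tree id.
#'
#' @param location `c(lon, lat)`.
#' @param tree_map A `tree_map`.
#' @param max_dist Maximum distance to the nearest crown in meters
#'   (default 10).
#' @return List `tree_id` (or `NA`), `distance` (m; 0 if inside),
#'   `excluded`, `reason`.
#' @export
assign_sleep_tree <- function(location, tree_map, max_dist = 10) {
  if (!length(tree_map$trees)) stop("empty tree map", call. = FALSE)
  p <- local_project(location[1], location[2],
                     tree_map$site_lon, tree_map$site_lat)
  ids <- sort(names(tree_map$trees))
  d <- vapply(ids, function(id) {
    dist_point_polygon(p$x, p$y, tree_map$trees[[id]])
  }, numeric(1))
  best <- which.min(d)  # first minimum = smallest id on ties
  if (d[best] > max_dist) {
    return(list(tree_id = NA_character_, distance = unname(d[best]),
                excluded = TRUE, reason = "gt_10m_from_crown"))
  }
  list(tree_id = ids[best], distance = unname(d[best]),
       excluded = FALSE, reason = "none")
}

#' Daily travel distance from 5 m discretized GPS
#'
#' To keep accumulated GPS jitter from inflating the distance, a fix is
#' retained only when at least `resolution` meters from the last retained
#' fix; the travel distance is the summed distance between consecutive
#' retained fixes (projected planar meters). Days whose fixes start after
#' `must_start_by` or end before `must_end_by` are excluded.
#'
#' @param gps Data frame `individual_id`, `timestamp`, `lon`, `lat` for
#'   one individual-day, time-sorted.
#' @param date Calendar date of the day.
#' @param resolution Discretization radius in meters (default 5).
#' @param must_start_by,must_end_by Coverage rule clock times (defaults
#'   07:30 and 17:00).
#' @param ref Optional `c(lon, lat)` projection origin; defaults to the
#'   first fix.
#' @return List `distance_m` (or `NA`), `excluded`, `reason`,
#'   `n_retained`.
#' @export
discretized_travel_distance <- function(gps, date, resolution = 5,
                                        must_start_by = "07:30",
                                        must_end_by = "17:00",
                                        ref = NULL) {
  t0 <- as.numeric(local_midnight(date))
  tt <- as.numeric(gps$timestamp)
  day_sel <- tt >= t0 & tt < t0 + 86400
  g <- gps[day_sel, ]
  if (!nrow(g)) {
    return(list(distance_m = NA_real_, excluded = TRUE,
                reason = "no_fixes", n_retained = 0L))
  }
  tt <- as.numeric(g$timestamp)
  if (min(tt) > t0 + hm_to_min(must_start_by) * 60) {
    return(list(distance_m = NA_real_, excluded = TRUE,
                reason = "first_fix_late", n_retained = 0L))
  }
  if (max(tt) < t0 + hm_to_min(must_end_by) * 60) {
    return(list(distance_m = NA_real_, excluded = TRUE,
                reason = "last_fix_early", n_retained = 0L))
  }
  if (is.null(ref)) ref <- c(g$lon[1], g$lat[1])
  p <- local_project(g$lon, g$lat, ref[1], ref[2])
  x <- p$x; y <- p$y
  keep_x <- x[1]; keep_y <- y[1]
  total <- 0
  last_x <- x[1]; last_y <- y[1]
  n_ret <- 1L
  for (i in seq_along(x)[-1]) {
    d <- sqrt((x[i] - last_x)^2 + (y[i] - last_y)^2)
    if (d >= resolution) {
      total <- total + d
      last_x <- x[i]; last_y <- y[i]
      n_ret <- n_ret + 1L
    }
  }
  list(distance_m = total, excluded = FALSE, reason = "none",
       n_retained = n_ret)
}

# --- Solar position / twilight -------------------------------------------
# NOAA solar equations (fractional-year Fourier forms for declination and
# the equation of time). Accuracy ~1 min, sufficient for twilight anchors.

noaa_solar <- function(date, hour_utc = 12) {
  doy <- as.integer(format(date, "%j"))
  yr <- as.integer(format(date, "%Y"))
  ndays <- if ((yr %% 4 == 0 && yr %% 100 != 0) || yr %% 400 == 0) 366 else 365
  g <- 2 * pi / ndays * (doy - 1 + (hour_utc - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  list(eqtime = eqtime, decl = decl)
}

# hour angle (degrees) at which the sun reaches `zenith` degrees
solar_hour_angle <- function(lat, decl, zenith) {
  latr <- lat * pi / 180
  zr <- zenith * pi / 180
  cosha <- (cos(zr) - sin(latr) * sin(decl)) / (cos(latr) * cos(decl))
  if (cosha < -1 || cosha > 1) return(NA_real_)
  acos(cosha) * 180 / pi
}

#' Astronomical twilight (and sun-crossing) times for a site
#'
#' Computes the local times at which the sun crosses a given depression
#' angle below the horizon - by default 18 degrees, i.e. the end of
#' evening astronomical twilight and the start of morning astronomical
#' twilight - using the standard NOAA solar-position equations.
#'
#' @param date Calendar `Date`.
#' @param lon,lat Site coordinates in degrees.
#' @param tz_offset_hours Local timezone offset from UTC in hours
#'   (default +3, the study-site zone).
#' @param depression Solar depression angle in degrees below the horizon
#'   (18 = astronomical twilight; 0.833 approximates sunrise/sunset).
#' @return List `date`, `morning_astro_start`, `evening_astro_end`
#'   (POSIXct, site-local). Errors when the sun never reaches the
#'   depression angle on that date (high latitudes).
#' @export
#' @examples
#' tw <- compute_twilight(as.Date("2012-08-15"), 36.87, 0.29)
#' format(tw$evening_astro_end, tz = "Etc/GMT-3")
compute_twilight <- function(date, lon, lat, tz_offset_hours = 3,
                             depression = 18) {
  sol <- noaa_solar(date, hour_utc = 12 - tz_offset_hours)
  zenith <- 90 + depression
  ha <- solar_hour_angle(lat, sol$decl, zenith)
  if (is.na(ha)) {
    stop("twilight undefined at this latitude/date", call. = FALSE)
  }
  # solar noon in local minutes
  snoon <- 720 - 4 * lon - sol$eqtime + tz_offset_hours * 60
  morning <- snoon - 4 * ha
  evening <- snoon + 4 * ha
  mid <- local_midnight(date)
  list(date = date,
       morning_astro_start = mid + morning * 60,
       evening_astro_end = mid + evening * 60)
}

#' Build the per-night sleep assignment table
#'
#' Applies [infer_sleep_location()] and [assign_sleep_tree()] to every
#' individual and night.
#'
#' @param gps GPS data frame (`individual_id`, `timestamp`, `lon`,
#'   `lat`).
#' @param tree_map A `tree_map`.
#' @param dates Vector of morning `Date`s; night n ends on `dates[n]`.
#' @param cutoff,n_required,max_dist See [infer_sleep_location()] and
#'   [assign_sleep_tree()].
#' @return Data frame: `individual_id`, `night`, `date`, `lon`, `lat`,
#'   `tree_id`, `distance_m`, `excluded`, `exclusion_reason`.
#' @export
assign_sleep_trees <- function(gps, tree_map, dates, cutoff = "06:15",
                               n_required = 10, max_dist = 10) {
  out <- list()
  for (id in unique(gps$individual_id)) {
    g <- gps[gps$individual_id == id, ]
    for (n in seq_along(dates)) {
      loc <- infer_sleep_location(g, dates[n], cutoff, n_required)
      if (loc$excluded) {
        out[[length(out) + 1L]] <- data.frame(
          individual_id = id, night = n, date = dates[n],
          lon = NA_real_, lat = NA_real_, tree_id = NA_character_,
          distance_m = NA_real_, excluded = TRUE,
          exclusion_reason = loc$reason)
        next
      }
      asg <- assign_sleep_tree(loc$location, tree_map, max_dist)
      out[[length(out) + 1L]] <- data.frame(
        individual_id = id, night = n, date = dates[n],
        lon = loc$location[1], lat = loc$location[2],
        tree_id = asg$tree_id, distance_m = asg$distance,
        excluded = asg$excluded, exclusion_reason = asg$reason)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
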