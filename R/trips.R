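# GPS track regularisation, filtering, and central-place trip segmentation.

check_fixes <- function(fixes) {
  if (!is.data.frame(fixes) || !all(c("time", "lon", "lat") %in% names(fixes)))
    stop("fixes must be a data.frame with columns time, lon, lat")
  invisible(fixes)
}

#' Interpolate a GPS track onto a regular time lattice
#'
#' Standardises fixes to exact multiples of `interval` seconds from the
#' first fix, interpolating longitude and latitude linearly in time (adequate
#' at the sub-40-km scales of a central-place forager). No extrapolation is
#' performed beyond the last fix.
#'
#' @param fixes Data.frame with columns `time` (POSIXct), `lon`, `lat`;
#'   at least two rows, strictly increasing times.
#' @param interval Target cadence in seconds (default 300 s = 5 min, the
#'   nominal GPS programming).
#' @return A data.frame with the same columns on the regular lattice.
#' @export
interpolate_track <- function(fixes, interval = 300) {
  check_fixes(fixes)
  if (nrow(fixes) < 2L) stop("need at least 2 fixes to interpolate")
  t <- as.numeric(fixes$time)
  dt <- diff(t)
  if (any(dt == 0)) stop("duplicate timestamps in track")
  if (any(dt < 0)) stop("timestamps must be strictly increasing")
  grid <- seq(0, floor((t[length(t)] - t[1]) / interval) * interval, by = interval)
  data.frame(time = fixes$time[1] + grid,
             lon = stats::approx(t, fixes$lon, xout = t[1] + grid)$y,
             lat = stats::approx(t, fixes$lat, xout = t[1] + grid)$y)
}

#' Remove unrealistic-velocity fixes from a track
#'
#' Forward-pass speed filter: walking the track in time order, any fix whose
#' great-circle speed from the last retained fix exceeds `vmax` is removed,
#' and subsequent speeds are computed from the retained predecessor. The
#' first fix is never removed. After filtering, no consecutive pair of fixes
#' exceeds `vmax`.
#'
#' @inheritParams interpolate_track
#' @param vmax Maximum plausible speed in m/s (default 10 m/s).
#' @return The filtered data.frame.
#' @export
speed_filter <- function(fixes, vmax = 10) {
  check_fixes(fixes)
  n <- nrow(fixes)
  if (n < 2L) return(fixes)
  t <- as.numeric(fixes$time)
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  keep <- logical(n)
  keep[1L] <- TRUE
  last <- 1L
  for (i in 2:n) {
    d_m <- haversine_km(fixes$lon[last], fixes$lat[last],
                        fixes$lon[i], fixes$lat[i]) * 1000
    if (d_m / (t[i] - t[last]) <= vmax) {
      keep[i] <- TRUE
      last <- i
    }
  }
  fixes[keep, , drop = FALSE]
}

#' Segment a regularised track into central-place foraging trips
#'
#' Drops fixes within `buffer` metres of the colony, splits the remainder
#' into maximal temporally contiguous runs (a gap longer than one sampling
#' interval splits trips), and discards runs lasting `min_duration` hours or
#' less.
#'
#' @inheritParams interpolate_track
#' @param colony Numeric `(lon, lat)` of the colony.
#' @param buffer Colony exclusion radius in metres (default 250 m).
#' @param min_duration Minimum trip duration in hours (default 1 h;
#'   trips of exactly this duration are discarded).
#' @param interval Sampling interval in seconds used to detect gaps.
#' @return A list of `"foraging_trip"` objects; each holds the trip's fixes
#'   and its metrics (see [trip_metrics()]).
#' @export
segment_trips <- function(fixes, colony, buffer = 250, min_duration = 1,
                          interval = 300) {
  check_fixes(fixes)
  assert_colony(colony)
  d_m <- haversine_km(fixes$lon, fixes$lat, colony[1], colony[2]) * 1000
  at_sea <- fixes[d_m >= buffer, , drop = FALSE]
  if (nrow(at_sea) == 0L) return(list())
  t <- as.numeric(at_sea$time)
  run <- cumsum(c(1, diff(t) > interval))
  trips <- list()
  for (r in unique(run)) {
    f <- at_sea[run == r, , drop = FALSE]
    dur_h <- (as.numeric(f$time[nrow(f)]) - as.numeric(f$time[1])) / 3600
    if (dur_h <= min_duration || nrow(f) < 2L) next
    trips[[length(trips) + 1L]] <- new_foraging_trip(f, colony)
  }
  trips
}

new_foraging_trip <- function(fixes, colony) {
  structure(list(fixes = fixes, colony = colony,
                 metrics = trip_metrics_impl(fixes, colony)),
            class = "foraging_trip")
}

trip_metrics_impl <- function(fixes, colony) {
  n <- nrow(fixes)
  step_km <- haversine_km(fixes$lon[-n], fixes$lat[-n], fixes$lon[-1], fixes$lat[-1])
  range_km <- haversine_km(fixes$lon, fixes$lat, colony[1], colony[2])
  c(duration_h = (as.numeric(fixes$time[n]) - as.numeric(fixes$time[1])) / 3600,
    cum_dist_km = sum(step_km),
    max_range_km = max(range_km))
}

#' Trip-level movement metrics
#'
#' Duration (h, last minus first fix), cumulative distance (km, summed
#' great-circle distance between consecutive fixes) and maximum range (km,
#' farthest great-circle distance from the colony).
#'
#' @param trip A `"foraging_trip"` from [segment_trips()], or a fix
#'   data.frame (in which case `colony` is required).
#' @param colony Numeric `(lon, lat)`; taken from the trip object if absent.
#' @return Named numeric vector `duration_h`, `cum_dist_km`, `max_range_km`.
#' @export
trip_metrics <- function(trip, colony = NULL) {
  if (inherits(trip, "foraging_trip")) return(trip$metrics)
  check_fixes(trip)
  if (nrow(trip) < 2L) stop("need at least 2 fixes for trip metrics")
  assert_colony(colony)
  trip_metrics_impl(trip, colony)
}

#' @export
print.foraging_trip <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Foraging trip: %d fixes, %.2f h, %.1f km cumulative, %.1f km max range\n",
              nrow(x$fixes), m["duration_h"], m["cum_dist_km"], m["max_range_km"]))
  invisible(x)
}

#' Process one bird's raw GPS table into foraging trips
#'
#' Applies the pipeline order used throughout the package: speed filter on
#' the raw fixes, interpolation onto the regular lattice, then colony-buffer
#' removal and trip segmentation.
#'
#' @inheritParams segment_trips
#' @param vmax Speed-filter threshold (m/s).
#' @return A list of `"foraging_trip"` objects.
#' @export
process_gps_table <- function(fixes, colony, vmax = 10, interval = 300,
                              buffer = 250, min_duration = 1) {
  if (nrow(fixes) < 2L) return(list())
  f <- speed_filter(fixes, vmax = vmax)
  f <- interpolate_track(f, interval = interval)
  segment_trips(f, colony, buffer = buffer, min_duration = min_duration,
                interval = interval)
}

#' Tabulate trips from a set of per-bird GPS tables
#'
#' @param gps_tables Named list of fix data.frames (one per bird).
#' @inheritParams process_gps_table
#' @return A data.frame with one row per trip: `bird_id`, `trip_id`,
#'   `start`, `end`, `duration_h`, `cum_dist_km`, `max_range_km`. The
#'   `"foraging_trip"` objects are attached as attribute `"trips"`.
#' @export
trips_table <- function(gps_tables, colony, vmax = 10, interval = 300,
                        buffer = 250, min_duration = 1) {
  rows <- list()
  objs <- list()
  for (bird in names(gps_tables)) {
    trips <- process_gps_table(gps_tables[[bird]], colony, vmax = vmax,
                               interval = interval, buffer = buffer,
                               min_duration = min_duration)
    for (k in seq_along(trips)) {
      tr <- trips[[k]]
      m <- tr$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        bird_id = bird, trip_id = sprintf("%s_t%02d", bird, k),
        start = tr$fixes$time[1], end = tr$fixes$time[nrow(tr$fixes)],
        duration_h = unname(m["duration_h"]),
        cum_dist_km = unname(m["cum_dist_km"]),
        max_range_km = unname(m["max_range_km"]))
      objs[[length(objs) + 1L]] <- tr
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bird_id = character(0), trip_id = character(0),
               start = as.POSIXct(character(0), tz = "UTC"),
               end = as.POSIXct(character(0), tz = "UTC"),
               duration_h = numeric(0), cum_dist_km = numeric(0),
               max_range_km = numeric(0))
  attr(out, "trips") <- objs
  out
}
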