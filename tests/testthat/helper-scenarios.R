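# Small scenarios for fast tests: same behavioural structure as the
# defaults, scaled-down tagging effort and trip durations.

small_good <- function(seed = 101L, ...) {
  args <- utils::modifyList(list(seed = seed, n_birds = 2L,
                                 n_trips_per_bird = 2L,
                                 trip_duration_mean = 4), list(...))
  do.call(scenario_good, args)
}

small_poor <- function(seed = 202L, ...) {
  args <- utils::modifyList(list(seed = seed, n_birds = 2L,
                                 n_trips_per_bird = 2L,
                                 trip_duration_mean = 6), list(...))
  do.call(scenario_poor, args)
}

# A regular-lattice GPS fixture: `legs` excursions from the colony with
# the given durations (h), separated by dwells at the colony.
lattice_track <- function(colony, durations_h, dwell_h = 1, interval = 300,
                          speed_kmh = 6) {
  t <- 0
  rows <- list(data.frame(t = 0, x = 0, y = 0))
  for (d in durations_h) {
    n <- round(d * 3600 / interval)
    half <- floor(n / 2)
    step <- speed_kmh * interval / 3600
    out_x <- cumsum(rep(step, half))
    xs <- c(out_x, rev(out_x)[seq_len(n - half - 1)], 0)
    rows[[length(rows) + 1L]] <- data.frame(t = t + seq_len(n) * interval,
                                            x = xs, y = 0)
    t <- t + n * interval
    nd <- round(dwell_h * 3600 / interval)
    rows[[length(rows) + 1L]] <- data.frame(t = t + seq_len(nd) * interval,
                                            x = 0, y = 0)
    t <- t + nd * interval
  }
  df <- do.call(rbind, rows)
  ll <- pengkrill:::local_xy_to_lonlat(df$x, df$y, colony)
  data.frame(time = as.POSIXct("2020-01-01", tz = "UTC") + df$t,
             lon = ll[, "lon"], lat = ll[, "lat"])
}

test_colony <- c(-59.22, -62.30)
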