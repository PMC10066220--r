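# Synthetic-data generator: central-place foraging tracks, dive profiles
# with wiggles, Thomas-process krill fields, environmental grids and
# breeding counts, under named season scenarios.

#' Simulate one central-place foraging trip (GPS fix table)
#'
#' Generates an out-and-back correlated random walk that starts and ends at
#' the colony: an outbound phase biased away from the colony, a meandering
#' phase, and a homing phase timed so the realised duration is close to
#' `duration_h`. Straight-line range is capped at the scenario's
#' `max_range_km`. Fixes are at the scenario's nominal cadence; optional
#' gaps (dropped fixes) and displaced outlier fixes exercise the track
#' interpolation and speed filter downstream.
#'
#' @param scenario A [season_scenario()].
#' @param colony Numeric `(lon, lat)` of the colony.
#' @param duration_h Trip duration (h); drawn from the scenario's gamma model
#'   (truncated to \[2, 23\] h) when `NULL`.
#' @param start Start time (`POSIXct`).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A data.frame with columns `time` (POSIXct, UTC), `lon`, `lat`.
#' @export
simulate_track <- function(scenario, colony, duration_h = NULL,
                           start = as.POSIXct("2019-12-20", tz = "UTC"),
                           seed = NULL) {
  assert_colony(colony)
  with_seed(seed, {
    if (is.null(duration_h)) duration_h <- draw_trip_duration(scenario)
    xy <- simulate_track_xy(scenario, duration_h)
    xy <- apply_track_noise(xy, scenario)
    ll <- local_xy_to_lonlat(xy$x, xy$y, colony)
    out <- data.frame(time = start + xy$t_s, lon = ll[, "lon"], lat = ll[, "lat"])
    out[xy$keep, , drop = FALSE]
  })
}

draw_trip_duration <- function(scenario) {
  shp <- scenario$trip_duration_shape
  d <- stats::rgamma(1, shape = shp, scale = scenario$trip_duration_mean / shp)
  min(23, max(2, d))
}

# Core track model in local-plane km. Returns positions, times, and a keep
# mask implementing random fix gaps (trip endpoints always kept).
simulate_track_xy <- function(scenario, duration_h) {
  dt <- scenario$fix_interval_s
  speed_kmh <- scenario$travel_speed_ms * 3.6
  step <- speed_kmh * dt / 3600
  n <- max(2L, round(duration_h * 3600 / dt))
  cap <- min(scenario$max_range_km, max(2 * step, 0.45 * speed_kmh * duration_h))
  x <- y <- numeric(n + ceiling(0.35 * n) + 2L)
  heading <- stats::runif(1, 0, 2 * pi)
  mode <- "out"
  i <- 1L
  repeat {
    i <- i + 1L
    if (i > length(x)) break
    px <- x[i - 1L]; py <- y[i - 1L]
    d0 <- sqrt(px^2 + py^2)
    remaining_s <- (n - i) * dt
    if (mode != "home" && d0 * 1000 / scenario$travel_speed_ms >= 0.9 * remaining_s)
      mode <- "home"
    if (mode == "out" && (d0 > 0.55 * cap || i > n / 2)) mode <- "meander"
    heading <- switch(mode,
      out = (if (d0 < 1e-9) heading else atan2(py, px)) + stats::rnorm(1, 0, 0.25),
      meander = heading + stats::rnorm(1, 0, 0.5),
      home = atan2(-py, -px) + stats::rnorm(1, 0, 0.2))
    nx <- px + step * cos(heading)
    ny <- py + step * sin(heading)
    if (sqrt(nx^2 + ny^2) > cap) {
      heading <- atan2(-py, -px) + stats::rnorm(1, 0, 0.2)
      nx <- px + step * cos(heading)
      ny <- py + step * sin(heading)
    }
    if (mode != "home" && i > 2L && sqrt(nx^2 + ny^2) < 0.3) {
      heading <- (if (d0 < 1e-9) heading else atan2(py, px)) + stats::rnorm(1, 0, 0.2)
      nx <- px + step * cos(heading)
      ny <- py + step * sin(heading)
    }
    if (mode == "home" && sqrt(nx^2 + ny^2) < step) {
      x[i] <- stats::rnorm(1, 0, 0.03); y[i] <- stats::rnorm(1, 0, 0.03)
      break
    }
    x[i] <- nx; y[i] <- ny
  }
  i <- min(i, length(x))
  list(x = x[seq_len(i)], y = y[seq_len(i)], t_s = (seq_len(i) - 1L) * dt,
       keep = rep(TRUE, i))
}

apply_track_noise <- function(xy, scenario) {
  m <- length(xy$x)
  xy$x <- xy$x + stats::rnorm(m, 0, 0.012)
  xy$y <- xy$y + stats::rnorm(m, 0, 0.012)
  if (m > 6L) {
    mid <- 3:(m - 2L)
    out <- mid[stats::runif(length(mid)) < scenario$outlier_rate]
    if (length(out)) {
      ang <- stats::runif(length(out), 0, 2 * pi)
      r <- stats::runif(length(out), 6, 10)
      xy$x[out] <- xy$x[out] + r * cos(ang)
      xy$y[out] <- xy$y[out] + r * sin(ang)
    }
    drop <- mid[stats::runif(length(mid)) < scenario$gap_rate]
    xy$keep[drop] <- FALSE
  }
  xy
}

#' Simulate a single dive profile with an exact number of wiggles
#'
#' Builds a piecewise depth profile on the TDR sample grid: linear descent,
#' a bottom phase at `max_depth` carrying exactly `n_wiggles` upward
#' excursions (local depth minima) of prominence `wiggle_amplitude` on both
#' flanks, and a linear ascent back to the surface. Wiggle apexes fall on
#' exact samples, so a prominence-based wiggle counter with threshold at or
#' below `wiggle_amplitude` recovers `n_wiggles` exactly.
#'
#' @param max_depth Maximum depth (m); must exceed the dive-detection
#'   threshold used downstream.
#' @param bottom_duration Bottom-phase duration (s); must allow at least
#'   `2 * n_wiggles + 1` samples.
#' @param n_wiggles Number of wiggles (non-negative integer).
#' @param wiggle_amplitude Wiggle prominence (m); must be positive and at
#'   most `0.2 * max_depth` so wiggles stay inside the bottom band.
#' @param cadence Sample interval (s); TDRs here record every 1 s.
#' @param descent_rate,ascent_rate Vertical speeds (m/s).
#' @return Numeric vector of depths (m), starting and ending at 0.
#' @export
simulate_dive_profile <- function(max_depth, bottom_duration, n_wiggles,
                                  wiggle_amplitude = 1, cadence = 1,
                                  descent_rate = 1.4, ascent_rate = descent_rate) {
  if (!is.finite(max_depth) || max_depth <= 0) stop("`max_depth` must be positive")
  if (!is.finite(n_wiggles) || n_wiggles < 0 || n_wiggles != round(n_wiggles))
    stop("`n_wiggles` must be a non-negative integer")
  n_wiggles <- as.integer(n_wiggles)
  if (n_wiggles > 0L) {
    if (!is.finite(wiggle_amplitude) || wiggle_amplitude <= 0)
      stop("`wiggle_amplitude` must be positive")
    if (wiggle_amplitude > 0.2 * max_depth)
      stop("`wiggle_amplitude` must not exceed 20% of `max_depth`")
  }
  ramp <- function(rate) {
    d <- seq(rate * cadence, max_depth, by = rate * cadence)
    if (!length(d) || d[length(d)] < max_depth) d <- c(d, max_depth)
    d[length(d)] <- max_depth
    d
  }
  desc <- ramp(descent_rate)
  asc <- rev(ramp(ascent_rate))[-1L]
  B <- max(1L, round(bottom_duration / cadence))
  bottom <- rep(max_depth, B)
  if (n_wiggles > 0L) {
    if (B < 2L * n_wiggles + 1L)
      stop("bottom phase too short for ", n_wiggles, " wiggles")
    k <- 1L
    while (k < 4L && n_wiggles * (2L * (k + 1L) - 1L) + n_wiggles + 1L <= B) k <- k + 1L
    block <- max_depth - wiggle_amplitude * c(seq_len(k - 1L), k, rev(seq_len(k - 1L))) / k
    centers <- round(B * (seq_len(n_wiggles) - 0.5) / n_wiggles)
    for (ctr in centers) bottom[ctr - (k - 1L) + seq_along(block) - 1L] <- block
  }
  c(0, desc, bottom, asc, 0)
}

#' Simulate a krill swarm field along an acoustic transect
#'
#' Draws swarm parents from a Poisson process along the transect, then
#' offspring samples displaced horizontally (Gaussian,
#' `cluster_offspring_sd` km) and vertically (swarm centres Gaussian around
#' `krill_depth_mode`, within-swarm spread `krill_depth_spread`). Per-sample
#' density is lognormal scaled by `krill_biomass_scale`; a biomass scale of
#' zero yields an empty table.
#'
#' @param scenario A [season_scenario()].
#' @param transect_length_nmi Transect length (nautical miles).
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A data.frame with columns `distance_nmi`, `depth_m`, `density`.
#' @export
simulate_krill_field <- function(scenario, transect_length_nmi = 40, seed = NULL) {
  if (!is.finite(transect_length_nmi) || transect_length_nmi <= 0)
    stop("`transect_length_nmi` must be positive")
  empty <- data.frame(distance_nmi = numeric(0), depth_m = numeric(0),
                      density = numeric(0))
  if (scenario$krill_biomass_scale == 0) return(empty)
  with_seed(seed, {
    l_km <- transect_length_nmi * NMI_KM
    n_par <- stats::rpois(1, scenario$cluster_parent_intensity * l_km)
    if (n_par == 0L) return(empty)
    px <- stats::runif(n_par, 0, l_km)
    pz <- stats::rnorm(n_par, scenario$krill_depth_mode, scenario$krill_depth_sd)
    n_off <- stats::rpois(n_par, scenario$cluster_offspring_mean)
    if (sum(n_off) == 0L) return(empty)
    x <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, scenario$cluster_offspring_sd)
    x <- abs(x)                              # reflect at transect ends
    x <- l_km - abs(l_km - x)
    z <- rep(pz, n_off) + stats::rnorm(sum(n_off), 0, scenario$krill_depth_spread)
    z <- pmin(pmax(z, 1), 499)
    dens <- scenario$krill_biomass_scale * stats::rlnorm(sum(n_off), log(20), 0.9)
    data.frame(distance_nmi = x / NMI_KM, depth_m = z, density = dens)
  })
}

# Environmental grid geometry: 5 km lattice on a local plane, covering a
# square that comfortably contains the 75 km extraction radius.
env_grid_xy <- function(half_width_km = 80, cell_km = 5) {
  g <- expand.grid(x = seq(-half_width_km, half_width_km, by = cell_km),
                   y = seq(-half_width_km, half_width_km, by = cell_km))
  g$cell_id <- seq_len(nrow(g))
  g
}

ENV_VARIABLES <- c("chl", "par", "sws", "sic")

env_var_spec <- function(scenario) {
  data.frame(variable = ENV_VARIABLES,
             mean = c(scenario$chl_mean, scenario$par_mean,
                      scenario$wind_mean, scenario$sic_mean),
             sd = c(0.25, 4, 1.2, 0.08),
             lo = c(0, 0, 0, 0), hi = c(Inf, Inf, Inf, 1))
}

simulate_env_grids <- function(scenario, colony, grid = env_grid_xy()) {
  spec <- env_var_spec(scenario)
  ll <- local_xy_to_lonlat(grid$x, grid$y, colony)
  out <- list()
  for (i in seq_len(nrow(spec))) {
    v <- spec$variable[i]
    months <- season_months(scenario$season_label, v)
    for (m in months) {
      val <- stats::rnorm(nrow(grid), spec$mean[i], spec$sd[i])
      val <- pmin(pmax(val, spec$lo[i]), spec$hi[i])
      out[[length(out) + 1L]] <- data.frame(
        variable = v, month = m, cell_id = grid$cell_id,
        lon = ll[, "lon"], lat = ll[, "lat"], value = val)
    }
  }
  do.call(rbind, out)
}

simulate_breeding <- function(scenario) {
  n <- scenario$n_subcolonies
  nests <- 20L + stats::rpois(n, max(0, scenario$nests_mean - 20))
  p <- min(1, scenario$breeding_success_mean / 2)
  chicks <- stats::rbinom(n, 2L * nests, p)
  data.frame(subcolony = sprintf("%s_s%02d", scenario$name, seq_len(n)),
             season = scenario$season_label,
             nests_incubation = nests, chicks_creche = chicks)
}

# Depth availability weight coupling wiggle rate to the trip's target depth.
availability_weight <- function(target, coupling) {
  a <- pmin(pmax(0.3 + 0.7 * (target - 30) / 15, 0.3), 1.5)
  (1 - coupling) + coupling * a
}

draw_trip_target_depth <- function(scenario) {
  bulk <- scenario$dive_depth_mode -
    scenario$trip_depth_mix_prob * scenario$trip_depth_mix_shift
  mu <- bulk + (stats::runif(1) < scenario$trip_depth_mix_prob) *
    scenario$trip_depth_mix_shift
  max(15, stats::rnorm(1, mu, scenario$trip_depth_sd))
}

draw_complete_dive <- function(scenario, target) {
  shp <- scenario$within_dive_depth_shape
  mn <- scenario$within_dive_depth_mean
  depth <- target + stats::rgamma(1, shape = shp, scale = mn / shp) - mn
  depth <- min(133, max(10, depth))
  b <- scenario$bottom_base_s +
    stats::rgamma(1, shape = scenario$bottom_extra_shape,
                  scale = scenario$bottom_extra_mean_s / scenario$bottom_extra_shape)
  rate <- scenario$wiggle_rate_base *
    availability_weight(target, scenario$wiggle_depth_coupling)
  nw <- min(17L, max(2L, stats::rpois(1, rate)))
  amp <- stats::runif(1, scenario$wiggle_amp_min,
                      max(scenario$wiggle_amp_min, min(scenario$wiggle_amp_max, 0.2 * depth)))
  list(profile = simulate_dive_profile(depth, b, nw, amp,
                                       descent_rate = scenario$descent_rate_ms),
       max_depth = depth, n_wiggles = nw, amplitude = amp, complete = TRUE)
}

draw_incomplete_dive <- function(scenario) {
  depth <- stats::runif(1, 5, 12)
  list(profile = simulate_dive_profile(depth, 1, 0L, 1, descent_rate = 2.2),
       max_depth = depth, n_wiggles = 0L, amplitude = NA_real_, complete = FALSE)
}

# Per-bird GPS assembly: trips separated by colony dwells, with realised
# trip windows recorded as ground truth.
simulate_bird_gps <- function(scenario, bird_id) {
  dt <- scenario$fix_interval_s
  rows <- list()
  trips <- list()
  t <- 0
  for (j in seq_len(scenario$n_trips_per_bird)) {
    d <- draw_trip_duration(scenario)
    xy <- simulate_track_xy(scenario, d)
    xy <- apply_track_noise(xy, scenario)
    times <- t + xy$t_s
    rows[[length(rows) + 1L]] <-
      data.frame(t_s = times, x = xy$x, y = xy$y)[xy$keep, , drop = FALSE]
    trips[[j]] <- data.frame(bird_id = bird_id, trip = j,
                             start_s = times[1], end_s = times[length(times)],
                             duration_h = (times[length(times)] - times[1]) / 3600,
                             max_range_km = max(sqrt(xy$x^2 + xy$y^2)))
    t <- times[length(times)] + dt
    dwell_n <- max(2L, round(stats::runif(1, 2, 6) * 3600 / dt))
    rows[[length(rows) + 1L]] <- data.frame(
      t_s = t + (seq_len(dwell_n) - 1L) * dt,
      x = stats::rnorm(dwell_n, 0, 0.012), y = stats::rnorm(dwell_n, 0, 0.012))
    t <- t + dwell_n * dt
  }
  list(fixes = do.call(rbind, rows), trips = do.call(rbind, trips))
}

simulate_bird_tdr <- function(scenario, trips) {
  total_s <- ceiling(max(trips$end_s)) + 600L
  depth <- numeric(total_s + 1L)
  dives <- list()
  for (j in seq_len(nrow(trips))) {
    w0 <- trips$start_s[j] + 900
    w1 <- trips$end_s[j] - 900
    if (w1 - w0 < 600) next
    target <- draw_trip_target_depth(scenario)
    t <- round(w0 + stats::rexp(1, 1 / 30))
    repeat {
      dv <- if (stats::runif(1) < scenario$p_complete)
        draw_complete_dive(scenario, target) else draw_incomplete_dive(scenario)
      len <- length(dv$profile)
      if (t + len > w1) break
      depth[t + seq_len(len)] <- dv$profile
      dives[[length(dives) + 1L]] <- data.frame(
        bird_id = trips$bird_id[j], trip = trips$trip[j], start_s = t,
        duration_s = len - 1L, max_depth = dv$max_depth,
        n_wiggles = dv$n_wiggles, complete = dv$complete,
        trip_target_depth = target)
      surf <- round(20 + stats::rexp(1, 1 / max(1, scenario$surface_mean_s - 20)))
      if (stats::runif(1) < scenario$rest_prob)
        surf <- surf + round(stats::rexp(1, 1 / scenario$rest_mean_s))
      t <- t + len + surf
    }
  }
  drift <- 0.4 + 0.3 * (0:total_s) / total_s
  obs <- pmax(depth + drift + stats::rnorm(total_s + 1L, 0, 0.03), 0)
  list(tdr = data.frame(t_s = 0:total_s, depth_m = obs),
       dives = if (length(dives)) do.call(rbind, dives) else NULL)
}

#' Simulate a full input bundle for one season scenario
#'
#' Generates every pipeline input for a scenario: per-bird GPS fix tables
#' and 1-Hz TDR depth series (with surface drift and sensor noise), the
#' acoustic sample table, monthly environmental grids on a 5 km lattice,
#' breeding counts per sub-colony, and a `truth` record of the realised
#' generating quantities (trip windows, per-dive wiggle counts and
#' completeness) used by recovery tests. Each component draws from its own
#' seed derived from the scenario seed, so identical scenarios give
#' identical bundles regardless of which components are requested.
#'
#' @param scenario A [season_scenario()].
#' @param colony Numeric `(lon, lat)` of the colony.
#' @param transect_length_nmi Acoustic transect length (nautical miles).
#' @param what Components to generate (a subset of
#'   `c("gps", "tdr", "acoustics", "env", "breeding")`). TDR generation
#'   requires the GPS trip truth and implies `"gps"`.
#' @return An object of class `"penguin_bundle"`: a list with elements
#'   `gps_tables`, `tdr_tables` (named by bird), `acoustic_samples`,
#'   `env_grid` (long data.frame), `breeding_counts`, `truth`, `colony`,
#'   `scenario`.
#' @export
simulate_bundle <- function(scenario, colony = c(-59.22, -62.30),
                            transect_length_nmi = 40,
                            what = c("gps", "tdr", "acoustics", "env", "breeding")) {
  assert_colony(colony)
  what <- match.arg(what, several.ok = TRUE)
  if ("tdr" %in% what) what <- union(what, "gps")
  start <- as.POSIXct(paste0(substr(scenario$season_label, 1, 4), "-12-20"),
                      tz = "UTC")
  bundle <- list(gps_tables = list(), tdr_tables = list(),
                 acoustic_samples = NULL, env_grid = NULL,
                 breeding_counts = NULL,
                 truth = list(scenario = unclass(scenario), trips = NULL, dives = NULL),
                 colony = colony, scenario = scenario, start = start,
                 transect_length_nmi = transect_length_nmi)
  if ("gps" %in% what && scenario$n_birds > 0L) {
    with_seed(scenario$seed + 1L, {
      trips <- list()
      for (i in seq_len(scenario$n_birds)) {
        bird <- sprintf("%s_b%02d", scenario$name, i)
        g <- simulate_bird_gps(scenario, bird)
        bundle$gps_tables[[bird]] <- data.frame(
          time = start + g$fixes$t_s,
          lon = local_xy_to_lonlat(g$fixes$x, g$fixes$y, colony)[, "lon"],
          lat = local_xy_to_lonlat(g$fixes$x, g$fixes$y, colony)[, "lat"])
        trips[[i]] <- g$trips
      }
      bundle$truth$trips <- do.call(rbind, trips)
    })
  }
  if ("tdr" %in% what && scenario$n_birds > 0L) {
    with_seed(scenario$seed + 2L, {
      dives <- list()
      for (bird in names(bundle$gps_tables)) {
        tr <- bundle$truth$trips[bundle$truth$trips$bird_id == bird, , drop = FALSE]
        td <- simulate_bird_tdr(scenario, tr)
        bundle$tdr_tables[[bird]] <- data.frame(
          time = start + td$tdr$t_s, depth_m = td$tdr$depth_m)
        if (!is.null(td$dives)) dives[[length(dives) + 1L]] <- td$dives
      }
      bundle$truth$dives <- if (length(dives)) do.call(rbind, dives) else NULL
    })
  }
  if ("acoustics" %in% what)
    bundle$acoustic_samples <- simulate_krill_field(
      scenario, transect_length_nmi, seed = scenario$seed + 3L)
  if ("env" %in% what)
    bundle$env_grid <- with_seed(scenario$seed + 4L,
                                 simulate_env_grids(scenario, colony))
  if ("breeding" %in% what)
    bundle$breeding_counts <- with_seed(scenario$seed + 5L,
                                        simulate_breeding(scenario))
  structure(bundle, class = "penguin_bundle")
}

#' Simulate a pair of contrasting season bundles
#'
#' @param good,poor [season_scenario()] objects with distinct names; they
#'   share the colony and transect geometry.
#' @inheritParams simulate_bundle
#' @return A named list of two [simulate_bundle()] results.
#' @export
simulate_seasons <- function(good = scenario_good(), poor = scenario_poor(),
                             colony = c(-59.22, -62.30), transect_length_nmi = 40,
                             what = c("gps", "tdr", "acoustics", "env", "breeding")) {
  if (identical(good$name, poor$name))
    stop("scenarios must have distinct names")
  out <- list(simulate_bundle(good, colony, transect_length_nmi, what),
              simulate_bundle(poor, colony, transect_length_nmi, what))
  names(out) <- c(good$name, poor$name)
  out
}

#' @export
print.penguin_bundle <- function(x, ...) {
  cat("Synthetic season bundle \"", x$scenario$name, "\" (",
      x$scenario$season_label, ")\n", sep = "")
  cat(sprintf("  %d GPS tables, %d TDR series, %d acoustic samples\n",
              length(x$gps_tables), length(x$tdr_tables),
              if (is.null(x$acoustic_samples)) 0L else nrow(x$acoustic_samples)))
  nt <- if (is.null(x$truth$trips)) 0L else nrow(x$truth$trips)
  nd <- if (is.null(x$truth$dives)) 0L else nrow(x$truth$dives)
  cat(sprintf("  truth: %d trips, %d dives\n", nt, nd))
  invisible(x)
}

#' Write a bundle's input files to disk
#'
#' Writes `gps_<bird>.csv`, `tdr_<bird>.csv`, `acoustic_samples.csv`,
#' `env_<var>_<month>.csv`, `breeding.csv` and `truth.json` (the generating
#' parameters and realised truth tables) under `dir`.
#'
#' @param bundle A [simulate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  for (bird in names(bundle$gps_tables)) {
    g <- bundle$gps_tables[[bird]]
    utils::write.csv(data.frame(timestamp = iso(g$time), lon = g$lon, lat = g$lat),
                     file.path(dir, paste0("gps_", bird, ".csv")), row.names = FALSE)
  }
  for (bird in names(bundle$tdr_tables)) {
    d <- bundle$tdr_tables[[bird]]
    utils::write.csv(data.frame(timestamp = iso(d$time), depth_m = d$depth_m),
                     file.path(dir, paste0("tdr_", bird, ".csv")), row.names = FALSE)
  }
  if (!is.null(bundle$acoustic_samples))
    utils::write.csv(bundle$acoustic_samples,
                     file.path(dir, "acoustic_samples.csv"), row.names = FALSE)
  if (!is.null(bundle$env_grid)) {
    for (v in unique(bundle$env_grid$variable)) {
      for (m in unique(bundle$env_grid$month[bundle$env_grid$variable == v])) {
        sub <- bundle$env_grid[bundle$env_grid$variable == v &
                                 bundle$env_grid$month == m,
                               c("cell_id", "lon", "lat", "value")]
        utils::write.csv(sub, file.path(dir, sprintf("env_%s_%s.csv", v, m)),
                         row.names = FALSE)
      }
    }
  }
  if (!is.null(bundle$breeding_counts))
    utils::write.csv(bundle$breeding_counts, file.path(dir, "breeding.csv"),
                     row.names = FALSE)
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
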