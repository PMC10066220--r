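#' Define a season scenario for the synthetic-data generator
#'
#' A season scenario bundles every parameter the generator needs to emulate
#' one breeding season: biologging effort (birds, trips, trip durations),
#' dive behaviour (depth distributions, completeness, wiggle rates), the
#' krill swarm field (a Thomas cluster process with a controllable vertical
#' mode), gridded environmental means and breeding success. Two presets,
#' [scenario_good()] and [scenario_poor()], encode the contrast between a
#' season with abundant, shallow, aggregated krill and one with scarce,
#' deep, dispersed krill.
#'
#' Depth behaviour is hierarchical: each trip draws a target bottom depth
#' (a two-component normal mixture so a season can have a heavy deep tail
#' while keeping the same mean), and each complete dive adds a gamma
#' deviation around that target. Wiggle counts per complete dive are
#' Poisson with rate `wiggle_rate_base` optionally scaled by a depth
#' "availability" weight (`wiggle_depth_coupling`), then clipped to
#' \[2, 17\]; incomplete dives are shallow V-dives with no wiggles.
#'
#' @param name Scenario label, e.g. `"good"`.
#' @param season_label Season the scenario emulates, e.g. `"2019/20"`
#'   (used for environmental month windows and report labels).
#' @param seed Integer seed; identical scenarios generate identical data.
#' @param n_birds,n_trips_per_bird Tagging effort.
#' @param trip_duration_mean,trip_duration_shape Gamma model of trip
#'   duration (h); draws are truncated to \[2, 23\] h.
#' @param travel_speed_ms Mean ground speed (m/s) of the simulated track.
#' @param max_range_km Hard cap on straight-line range from the colony (km).
#' @param fix_interval_s Nominal GPS cadence (s).
#' @param gap_rate Probability that a non-endpoint GPS fix is dropped
#'   (exercises track interpolation).
#' @param outlier_rate Probability that a mid-trip fix is displaced by
#'   several km (exercises the speed filter).
#' @param p_complete Probability a dive is complete (has a bottom phase).
#' @param dive_depth_mode Season mean of the per-trip target bottom depth (m).
#' @param trip_depth_sd SD of the bulk component of trip target depth (m).
#' @param trip_depth_mix_prob,trip_depth_mix_shift Probability and depth
#'   shift (m) of the deep mixture component; the bulk component is moved so
#'   the season mean stays at `dive_depth_mode`.
#' @param within_dive_depth_shape,within_dive_depth_mean Gamma deviation of
#'   individual complete-dive depth around the trip target (m).
#' @param bottom_base_s,bottom_extra_mean_s,bottom_extra_shape Bottom-phase
#'   duration model: `bottom_base_s` plus a gamma excess (s).
#' @param descent_rate_ms Vertical descent/ascent rate of complete dives (m/s).
#' @param wiggle_rate_base Poisson rate of wiggles per complete dive.
#' @param wiggle_depth_coupling In \[0, 1\]: 0 = flat wiggle rate, 1 = rate
#'   fully scaled by the depth availability weight (deeper trips wiggle more).
#' @param wiggle_amp_min,wiggle_amp_max Uniform range of wiggle amplitude (m).
#' @param surface_mean_s Mean post-dive surface interval (s).
#' @param rest_prob,rest_mean_s Probability and mean duration (s) of a long
#'   surface rest after a dive (creates dive bouts).
#' @param krill_depth_mode Depth of peak krill density (m), in \[20, 150\].
#' @param krill_depth_sd SD of swarm (cluster-centre) depth around the mode (m).
#' @param krill_depth_spread Within-swarm SD of sample depth (m).
#' @param krill_biomass_scale Multiplier on per-sample density.
#' @param cluster_parent_intensity Swarm parents per km of transect.
#' @param cluster_offspring_mean Mean samples per swarm.
#' @param cluster_offspring_sd Horizontal within-swarm SD (km).
#' @param chl_mean,par_mean,wind_mean,sic_mean Environmental grid means
#'   (CHL mg m^-3, PAR mol m^-2 d^-1, SWS m s^-1, SIC fraction).
#' @param n_subcolonies,nests_mean Breeding survey structure.
#' @param breeding_success_mean Expected chicks per nest.
#' @return An object of class `"season_scenario"` (a named list).
#' @seealso [simulate_bundle()], [simulate_seasons()]
#' @export
season_scenario <- function(name,
                            season_label,
                            seed = 1L,
                            n_birds = 17L,
                            n_trips_per_bird = 5L,
                            trip_duration_mean = 10,
                            trip_duration_shape = 12,
                            travel_speed_ms = 1.6,
                            max_range_km = 34.5,
                            fix_interval_s = 300,
                            gap_rate = 0.03,
                            outlier_rate = 0.01,
                            p_complete = 0.85,
                            dive_depth_mode = 38,
                            trip_depth_sd = 5,
                            trip_depth_mix_prob = 0,
                            trip_depth_mix_shift = 10,
                            within_dive_depth_shape = 9,
                            within_dive_depth_mean = 12,
                            bottom_base_s = 36,
                            bottom_extra_mean_s = 20,
                            bottom_extra_shape = 4,
                            descent_rate_ms = 1.4,
                            wiggle_rate_base = 6,
                            wiggle_depth_coupling = 0,
                            wiggle_amp_min = 1.3,
                            wiggle_amp_max = 3,
                            surface_mean_s = 70,
                            rest_prob = 0.06,
                            rest_mean_s = 1200,
                            krill_depth_mode = 45,
                            krill_depth_sd = 12,
                            krill_depth_spread = 5,
                            krill_biomass_scale = 1.5,
                            cluster_parent_intensity = 0.35,
                            cluster_offspring_mean = 45,
                            cluster_offspring_sd = 0.35,
                            chl_mean = 1.4,
                            par_mean = 38,
                            wind_mean = 5.5,
                            sic_mean = 0.55,
                            n_subcolonies = 12L,
                            nests_mean = 60,
                            breeding_success_mean = 1.05) {
  sc <- as.list(environment())
  num <- sc[!(names(sc) %in% c("name", "season_label"))]
  bad <- names(num)[!vapply(num, function(v) is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))]
  if (length(bad)) stop("non-finite scenario parameter(s): ", paste(bad, collapse = ", "))
  nonneg <- c("gap_rate", "outlier_rate", "trip_depth_mix_prob", "wiggle_depth_coupling",
              "rest_prob", "sic_mean", "krill_biomass_scale", "n_birds", "n_trips_per_bird")
  pos <- setdiff(names(num), c(nonneg, "seed", "trip_depth_mix_shift"))
  if (any(unlist(num[pos]) <= 0)) stop("scenario parameters must be positive: ",
                                       paste(pos[unlist(num[pos]) <= 0], collapse = ", "))
  if (any(unlist(num[nonneg]) < 0)) stop("scenario parameters must be non-negative")
  if (krill_depth_mode < 20 || krill_depth_mode > 150)
    stop("`krill_depth_mode` must lie in [20, 150] m")
  for (p in c("p_complete", "trip_depth_mix_prob", "wiggle_depth_coupling", "gap_rate", "outlier_rate", "rest_prob"))
    if (sc[[p]] < 0 || sc[[p]] > 1) stop("`", p, "` must lie in [0, 1]")
  if (sic_mean > 1) stop("`sic_mean` must lie in [0, 1]")
  if (wiggle_amp_min < 1 || wiggle_amp_max < wiggle_amp_min)
    stop("wiggle amplitudes must satisfy 1 <= min <= max")
  sc$seed <- as.integer(seed)
  sc$n_birds <- as.integer(n_birds)
  sc$n_trips_per_bird <- as.integer(n_trips_per_bird)
  sc$n_subcolonies <- as.integer(n_subcolonies)
  structure(sc, class = "season_scenario")
}

#' Preset scenario: favourable season (abundant, shallow, aggregated krill)
#'
#' Emulates a 2019/20-like season: shorter foraging trips, a high frequency
#' of complete dives, moderate capture effort, krill biomass peaking near
#' 45 m in dense aggregations, higher chlorophyll and winter sea ice, and
#' higher breeding success.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [season_scenario()].
#' @return A `"season_scenario"` object.
#' @export
scenario_good <- function(seed = 20L, ...) {
  args <- list(name = "good", season_label = "2019/20", seed = seed)
  do.call(season_scenario, utils::modifyList(args, list(...)))
}

#' Preset scenario: poor season (scarce, deep, dispersed krill)
#'
#' Emulates a 2021/22-like season: longer trips, fewer complete dives, a
#' heavy deep tail in dive depth (same mean as the good season), higher
#' depth-coupled capture effort, krill biomass peaking near 90 m in small
#' dispersed swarms, lower chlorophyll and winter sea ice, windier
#' conditions, and breeding success about 1.4 times lower.
#'
#' @inheritParams scenario_good
#' @return A `"season_scenario"` object.
#' @export
scenario_poor <- function(seed = 22L, ...) {
  args <- list(
    name = "poor", season_label = "2021/22", seed = seed,
    n_birds = 10L,
    trip_duration_mean = 14,
    p_complete = 0.60,
    trip_depth_mix_prob = 0.2,
    trip_depth_mix_shift = 10,
    trip_depth_sd = 4,
    within_dive_depth_shape = 1.8,
    wiggle_rate_base = 13,
    wiggle_depth_coupling = 1,
    surface_mean_s = 45,
    rest_prob = 0.03,
    krill_depth_mode = 90,
    krill_depth_spread = 10,
    krill_biomass_scale = 0.6,
    cluster_parent_intensity = 1.6,
    cluster_offspring_mean = 4,
    cluster_offspring_sd = 2.0,
    chl_mean = 0.7,
    wind_mean = 7.5,
    sic_mean = 0.25,
    breeding_success_mean = 0.75)
  do.call(season_scenario, utils::modifyList(args, list(...)))
}

#' @export
print.season_scenario <- function(x, ...) {
  cat("Season scenario \"", x$name, "\" (", x$season_label, "), seed ", x$seed, "\n", sep = "")
  cat(sprintf("  biologging: %d birds x %d trips, trip duration ~ %.1f h\n",
              x$n_birds, x$n_trips_per_bird, x$trip_duration_mean))
  cat(sprintf("  dives: p(complete) = %.2f, target depth %.0f m, wiggle rate %.1f (coupling %.1f)\n",
              x$p_complete, x$dive_depth_mode, x$wiggle_rate_base, x$wiggle_depth_coupling))
  cat(sprintf("  krill: mode %.0f m, biomass x%.2f, %.2f parents/km, %.0f samples/swarm (sd %.2f km)\n",
              x$krill_depth_mode, x$krill_biomass_scale, x$cluster_parent_intensity,
              x$cluster_offspring_mean, x$cluster_offspring_sd))
  cat(sprintf("  environment: CHL %.2f, PAR %.0f, SWS %.1f, wSIC %.2f; breeding %.2f chicks/nest\n",
              x$chl_mean, x$par_mean, x$wind_mean, x$sic_mean, x$breeding_success_mean))
  invisible(x)
}
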