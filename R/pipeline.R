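# End-to-end orchestration: simulate -> trips -> dives -> acoustics ->
# environment/breeding -> PERMANOVA season contrasts.

PIPELINE_ENDPOINTS <- c(
  "trip_duration", "cum_distance", "freq_complete_dives",
  "mean_dive_duration", "cum_dive_duration", "mean_bottom_depth",
  "max_bottom_depth", "capture_effort", "breeding_success", "nasc",
  "swarm_depth", "aggregation_index", "chl", "par", "wsic", "sws")

#' Expected season-contrast direction map
#'
#' The direction of each endpoint in the contrast season relative to the
#' reference season under the package's default scenarios (a poor krill
#' season against a good one): longer trips, fewer complete dives, deeper
#' maximum dives, higher capture effort, lower breeding success, lower and
#' deeper krill biomass, less aggregated swarms, lower chlorophyll and
#' winter sea ice, more wind; mean dive duration, mean bottom depth and
#' PAR are expected not to differ.
#'
#' @return Named character vector over the 16 report endpoints with values
#'   `"higher"`, `"lower"` or `"ns"`.
#' @export
expected_directions <- function() {
  c(trip_duration = "higher", cum_distance = "higher",
    freq_complete_dives = "lower", mean_dive_duration = "ns",
    cum_dive_duration = "higher", mean_bottom_depth = "ns",
    max_bottom_depth = "higher", capture_effort = "higher",
    breeding_success = "lower", nasc = "lower", swarm_depth = "higher",
    aggregation_index = "lower", chl = "lower", par = "ns",
    wsic = "lower", sws = "higher")
}

endpoint_contrast <- function(values, season, ref, alt, n_perm, seed, alpha,
                              unit) {
  keep <- is.finite(values)
  values <- values[keep]
  season <- season[keep]
  ok <- length(unique(season)) == 2L && all(table(season) >= 2L) &&
    stats::sd(values) > 0
  if (!ok)
    return(data.frame(mean_ref = NA_real_, mean_alt = NA_real_,
                      pseudo_F = NA_real_, df1 = NA_integer_,
                      df2 = NA_integer_, p = NA_real_, n = length(values),
                      direction = "skipped", unit = unit))
  z <- standardize_features(matrix(values, ncol = 1,
                                   dimnames = list(NULL, "value")))
  pm <- permanova(z, season, n_perm = n_perm, seed = seed)
  means <- tapply(values, season, mean)
  dir <- if (pm$p_value >= alpha) "ns" else
    if (means[alt] > means[ref]) "higher" else "lower"
  data.frame(mean_ref = unname(means[ref]), mean_alt = unname(means[alt]),
             pseudo_F = pm$pseudo_f, df1 = pm$df_between, df2 = pm$df_within,
             p = pm$p_value, n = pm$n, direction = dir, unit = unit)
}

process_bundle_biologging <- function(bundle) {
  tt <- trips_table(bundle$gps_tables, bundle$colony,
                    interval = bundle$scenario$fix_interval_s)
  dm <- list()
  for (bird in names(bundle$tdr_tables)) {
    btr <- tt[tt$bird_id == bird, , drop = FALSE]
    if (nrow(btr) == 0L) next
    recs <- process_tdr_table(bundle$tdr_tables[[bird]], btr)
    for (tid in unique(recs$trip_id)) {
      m <- trip_dive_metrics(recs[recs$trip_id == tid, , drop = FALSE])
      m$trip_id <- tid
      dm[[length(dm) + 1L]] <- m
    }
  }
  dives <- if (length(dm)) do.call(rbind, dm) else NULL
  out <- if (!is.null(dives)) merge(tt, dives, by = "trip_id") else tt
  out$season <- rep(bundle$scenario$season_label, nrow(out))
  out
}

process_bundle_acoustics <- function(bundle) {
  grid <- echo_integrate(bundle$acoustic_samples,
                         transect_length_nmi = bundle$transect_length_nmi)
  swarm <- suppressWarnings(swarm_depth_selection(grid, "q1"))
  nasc_by_bin <- tapply(grid$nasc, grid$along_bin, sum)
  list(grid = grid,
       profile = vertical_profile(grid),
       swarm = swarm,
       nasc_by_bin = data.frame(along_bin = as.integer(names(nasc_by_bin)),
                                nasc = as.numeric(nasc_by_bin)),
       aggregation = aggregation_by_depth(grid))
}

process_bundle_env <- function(bundle, radius_km = 75) {
  out <- list()
  for (v in ENV_VARIABLES) {
    sm <- seasonal_means(bundle$env_grid, v, bundle$scenario$season_label)
    out[[v]] <- extract_radius(sm, bundle$colony, radius_km)
  }
  out
}

#' Run the full two-season analysis pipeline
#'
#' Simulates (or reuses) a pair of season bundles, processes GPS tracks
#' into foraging trips, TDR series into per-trip dive metrics,
#' echo-integrates the acoustic samples into NASC grids with vertical
#' profiles, swarm-depth selections and depth-stratified aggregation
#' indices, extracts seasonal environmental means within 75 km of the
#' colony, computes breeding success, and contrasts every endpoint between
#' the seasons with a one-way PERMANOVA (999 permutations by default).
#'
#' @param good,poor [season_scenario()] objects; `good` is the reference
#'   season of the contrast.
#' @param colony Numeric `(lon, lat)`.
#' @param transect_length_nmi Acoustic transect length.
#' @param n_perm Permutations per endpoint.
#' @param seed Optional master seed: overrides the scenario seeds and the
#'   per-endpoint permutation seeds, making the whole run a deterministic
#'   function of (`good`, `poor`, `seed`).
#' @param alpha Significance level used only to label directions.
#' @param bundles Optional pre-simulated [simulate_seasons()] pair to
#'   process instead of simulating.
#' @param out_dir Optional directory; when given, all stage outputs and
#'   the report are written as CSV (plus a JSON configuration echo).
#' @return A `"contrast_report"` data.frame with one row per endpoint:
#'   season means, pseudo-F, dfs, p, direction of the `poor` season
#'   relative to `good`, and the observation unit. Stage outputs are in
#'   attribute `"details"`.
#' @export
run_pipeline <- function(good = scenario_good(), poor = scenario_poor(),
                         colony = c(-59.22, -62.30), transect_length_nmi = 40,
                         n_perm = 999, seed = NULL, alpha = 0.05,
                         bundles = NULL, out_dir = NULL) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    good$seed <- seed
    poor$seed <- seed + 7919L
  }
  if (is.null(bundles))
    bundles <- simulate_seasons(good, poor, colony, transect_length_nmi)
  ref <- bundles[[1]]$scenario$season_label
  alt <- bundles[[2]]$scenario$season_label
  perm_seed <- bundles[[1]]$scenario$seed + 5000L

  bio <- rbind(process_bundle_biologging(bundles[[1]]),
               process_bundle_biologging(bundles[[2]]))
  ac <- lapply(bundles, process_bundle_acoustics)
  env <- lapply(bundles, process_bundle_env)
  breed <- breeding_success(rbind(bundles[[1]]$breeding_counts,
                                  bundles[[2]]$breeding_counts))

  per_season <- function(get_values, unit) {
    v <- s <- NULL
    for (i in 1:2) {
      vals <- get_values(i)
      v <- c(v, vals)
      s <- c(s, rep(bundles[[i]]$scenario$season_label, length(vals)))
    }
    list(values = v, season = s, unit = unit)
  }

  has_dives <- "freq_complete" %in% names(bio)
  ep <- list(
    trip_duration = list(values = bio$duration_h, season = bio$season,
                         unit = "foraging trip (h)"),
    cum_distance = list(values = bio$cum_dist_km, season = bio$season,
                        unit = "foraging trip (km)"),
    freq_complete_dives = if (has_dives)
      list(values = bio$freq_complete, season = bio$season,
           unit = "foraging trip (proportion)"),
    mean_dive_duration = if (has_dives)
      list(values = bio$mean_dive_duration_min, season = bio$season,
           unit = "foraging trip (min)"),
    cum_dive_duration = if (has_dives)
      list(values = bio$cum_dive_duration_min, season = bio$season,
           unit = "foraging trip (min)"),
    mean_bottom_depth = if (has_dives)
      list(values = bio$mean_bottom_depth_m, season = bio$season,
           unit = "foraging trip (m)"),
    max_bottom_depth = if (has_dives)
      list(values = bio$max_bottom_depth_m, season = bio$season,
           unit = "foraging trip (m)"),
    capture_effort = if (has_dives)
      list(values = bio$mean_capture_effort, season = bio$season,
           unit = "foraging trip (wiggles per complete dive)"),
    breeding_success = list(values = breed$success, season = breed$season,
                            unit = "sub-colony (chicks per nest)"),
    nasc = per_season(function(i) ac[[i]]$nasc_by_bin$nasc,
                      "0.5 nmi transect bin (NASC)"),
    swarm_depth = per_season(function(i) ac[[i]]$swarm$depth_m,
                             "swarm cell above Q1 threshold (m)"),
    aggregation_index = per_season(
      function(i) ac[[i]]$aggregation$aggregation_index[
        is.finite(ac[[i]]$aggregation$aggregation_index)],
      "5 m stratum (mean K_iso - pi r^2)"),
    chl = per_season(function(i) env[[i]]$chl$value, "5 km cell (mg m^-3)"),
    par = per_season(function(i) env[[i]]$par$value, "5 km cell (mol m^-2 d^-1)"),
    wsic = per_season(function(i) env[[i]]$sic$value, "5 km cell (fraction)"),
    sws = per_season(function(i) env[[i]]$sws$value, "5 km cell (m s^-1)"))

  rows <- list()
  for (k in seq_along(PIPELINE_ENDPOINTS)) {
    name <- PIPELINE_ENDPOINTS[k]
    e <- ep[[name]]
    if (is.null(e)) {
      rows[[k]] <- data.frame(endpoint = name, mean_ref = NA_real_,
                              mean_alt = NA_real_, pseudo_F = NA_real_,
                              df1 = NA_integer_, df2 = NA_integer_,
                              p = NA_real_, n = 0L, direction = "skipped",
                              unit = "")
      next
    }
    res <- endpoint_contrast(e$values, e$season, ref, alt, n_perm,
                             seed = perm_seed + k, alpha = alpha,
                             unit = e$unit)
    rows[[k]] <- cbind(endpoint = name, res)
  }
  report <- do.call(rbind, rows)
  names(report)[names(report) == "mean_ref"] <- paste0("mean_", bundles[[1]]$scenario$name)
  names(report)[names(report) == "mean_alt"] <- paste0("mean_", bundles[[2]]$scenario$name)
  attr(report, "seasons") <- c(ref = ref, alt = alt)
  attr(report, "alpha") <- alpha
  attr(report, "details") <- list(
    trips = bio, acoustics = ac, env = env, breeding = breed,
    effort_profiles = lapply(split(bio, bio$season), function(b)
      if (has_dives) vertical_effort_profile(b) else NULL),
    scenarios = list(good = good, poor = poor), n_perm = n_perm)
  class(report) <- c("contrast_report", "data.frame")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.contrast_report <- function(x, ...) {
  s <- attr(x, "seasons")
  cat("Season contrast report (", s["alt"], " vs ", s["ref"], ", ",
      attr(x, "details")$n_perm, " permutations)\n\n", sep = "")
  df <- as.data.frame(x)
  df$p <- format.pval(df$p, digits = 3, eps = 1e-4)
  print(df[, setdiff(names(df), "unit")], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Check observed contrast directions against an expected map
#'
#' Directional endpoints pass when the contrast is significant in the
#' expected direction; endpoints expected not to differ (`"ns"`) pass when
#' the contrast is not significant.
#'
#' @param report A [run_pipeline()] report.
#' @param expected Named direction map (default [expected_directions()]).
#' @return Data.frame `endpoint`, `expected`, `observed`, `pass`.
#' @export
effect_direction_check <- function(report, expected = expected_directions()) {
  idx <- match(names(expected), report$endpoint)
  if (anyNA(idx)) stop("expected endpoints missing from report: ",
                       paste(names(expected)[is.na(idx)], collapse = ", "))
  obs <- report$direction[idx]
  data.frame(endpoint = names(expected), expected = unname(expected),
             observed = obs, pass = obs == unname(expected))
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  det <- attr(report, "details")
  utils::write.csv(as.data.frame(report), file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(det$trips, file.path(out_dir, "trip_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(det$breeding, file.path(out_dir, "breeding_success.csv"),
                   row.names = FALSE)
  for (nm in names(det$acoustics)) {
    a <- det$acoustics[[nm]]
    utils::write.csv(as.data.frame(a$grid),
                     file.path(out_dir, sprintf("nasc_grid_%s.csv", nm)),
                     row.names = FALSE)
    utils::write.csv(a$profile,
                     file.path(out_dir, sprintf("vertical_profile_%s.csv", nm)),
                     row.names = FALSE)
    utils::write.csv(a$aggregation,
                     file.path(out_dir, sprintf("aggregation_by_depth_%s.csv", nm)),
                     row.names = FALSE)
  }
  env_rows <- list()
  for (nm in names(det$env))
    for (v in names(det$env[[nm]])) {
      e <- det$env[[nm]][[v]]
      e$variable <- v
      e$season <- nm
      env_rows[[length(env_rows) + 1L]] <- e
    }
  if (length(env_rows))
    utils::write.csv(do.call(rbind, env_rows),
                     file.path(out_dir, "env_seasonal_means.csv"),
                     row.names = FALSE)
  cfg <- list(scenarios = lapply(det$scenarios, unclass), n_perm = det$n_perm,
              alpha = attr(report, "alpha"), seasons = attr(report, "seasons"))
  jsonlite::write_json(cfg, file.path(out_dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
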