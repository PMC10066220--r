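test_that("scenario constructor validates its parameters", {
  expect_s3_class(scenario_good(), "season_scenario")
  expect_error(season_scenario("x", "2019/20", krill_depth_mode = 10), "20, 150")
  expect_error(season_scenario("x", "2019/20", p_complete = 1.4), "0, 1")
  expect_error(season_scenario("x", "2019/20", trip_duration_mean = -1), "positive")
  expect_error(season_scenario("x", "2019/20", chl_mean = NA), "non-finite")
})

test_that("simulated tracks are out-and-back, range-capped and deterministic", {
  sc <- scenario_good()
  tr <- simulate_track(sc, test_colony, seed = 11)
  d_km <- haversine_km(tr$lon, tr$lat, test_colony[1], test_colony[2])
  expect_lt(max(d_km), 35)
  expect_lt(d_km[1], 0.25)                 # starts at the colony
  expect_lt(d_km[nrow(tr)], 0.25)          # and returns to it
  expect_true(all(diff(as.numeric(tr$time)) > 0))
  tr2 <- simulate_track(sc, test_colony, seed = 11)
  expect_identical(tr, tr2)
  expect_error(simulate_track(sc, c(NA, -62)), "finite")
})

test_that("a degenerate near-zero-duration trip is dropped by the trip filter", {
  sc <- scenario_good(gap_rate = 0, outlier_rate = 0)
  tr <- simulate_track(sc, test_colony, duration_h = 0.05, seed = 3)
  trips <- segment_trips(interpolate_track(tr), test_colony)
  expect_length(trips, 0)
})

test_that("simulated dive profiles carry exactly the requested wiggles", {
  prof <- simulate_dive_profile(40, 60, 5, 2)
  recs <- dive_records(prof, zoc = FALSE)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$n_wiggles, 5L)

  flat <- simulate_dive_profile(40, 60, 0)
  expect_equal(dive_records(flat, zoc = FALSE)$n_wiggles, 0L)

  deep <- simulate_dive_profile(133, 60, 3, 2)   # season maximum depth
  expect_equal(max(deep), 133)
  expect_equal(dive_records(deep, zoc = FALSE)$n_wiggles, 3L)

  expect_error(simulate_dive_profile(40, 60, -1, 2), "non-negative")
  expect_error(simulate_dive_profile(40, 60, 3, 0), "positive")
  expect_error(simulate_dive_profile(40, 60, 3, 20), "20%")
  expect_error(simulate_dive_profile(40, 5, 17, 1.5), "too short")
})

test_that("krill fields: depth contrast, empty at zero biomass, deterministic", {
  good <- scenario_good()
  poor <- scenario_poor()
  wmean <- function(sc, seed) {
    s <- simulate_krill_field(sc, 40, seed = seed)
    sum(s$depth_m * s$density) / sum(s$density)
  }
  g <- vapply(1:30, function(k) wmean(good, k), numeric(1))
  p <- vapply(1:30, function(k) wmean(poor, k), numeric(1))
  expect_lt(mean(g), mean(p))              # good-season krill sit shallower

  none <- simulate_krill_field(scenario_good(krill_biomass_scale = 0), 40, seed = 1)
  expect_equal(nrow(none), 0L)

  expect_identical(simulate_krill_field(good, 40, seed = 5),
                   simulate_krill_field(good, 40, seed = 5))
})

test_that("density-weighted sample depth recovers the krill depth mode", {
  sc <- scenario_good(cluster_parent_intensity = 3, cluster_offspring_mean = 60)
  s <- simulate_krill_field(sc, 80, seed = 9)
  expect_gte(nrow(s), 10000)
  wmean <- sum(s$depth_m * s$density) / sum(s$density)
  expect_lt(abs(wmean - sc$krill_depth_mode), 5)
})

test_that("bundles respect scenario contrasts and degenerate cases", {
  ge <- simulate_bundle(scenario_good(), what = c("env", "breeding"))
  pe <- simulate_bundle(scenario_poor(), what = c("env", "breeding"))
  chl <- function(b) mean(b$env_grid$value[b$env_grid$variable == "chl"])
  expect_lt(chl(pe), chl(ge))

  succ <- breeding_success(rbind(ge$breeding_counts, pe$breeding_counts))
  ratio <- season_success_ratio(succ, "2019/20", "2021/22")
  expect_lt(abs(ratio - 1.4), 0.2)         # configured default contrast

  b0 <- simulate_bundle(scenario_good(n_birds = 0L))
  expect_length(b0$gps_tables, 0)
  expect_length(b0$tdr_tables, 0)
  expect_gt(nrow(b0$env_grid), 0)

  expect_error(simulate_seasons(scenario_good(), scenario_good()), "distinct")
})

test_that("identical scenarios write byte-identical CSV bundles", {
  sc <- small_good(seed = 55L, n_trips_per_bird = 1L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(simulate_bundle(sc, what = c("gps", "acoustics", "breeding")), d1)
  write_bundle(simulate_bundle(sc, what = c("gps", "acoustics", "breeding")), d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("TDR truth matches what the dive module later recovers", {
  b <- simulate_bundle(small_good(seed = 77L))
  bird <- names(b$tdr_tables)[1]
  truth <- b$truth$dives[b$truth$dives$bird_id == bird, ]
  recs <- dive_records(b$tdr_tables[[bird]]$depth_m)
  expect_equal(nrow(recs), nrow(truth))
  expect_equal(recs$n_wiggles, truth$n_wiggles)
  expect_equal(recs$complete, truth$complete)
  expect_equal(recs$max_depth, truth$max_depth, tolerance = 0.05)
})
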