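test_that("seasonal month windows follow the austral convention", {
  expect_equal(season_months("2021/22", "sic"),
               c("2021-06", "2021-07", "2021-08", "2021-09"))
  expect_equal(season_months("2019/20", "chl"),
               c("2019-11", "2019-12", "2020-01"))
  expect_error(season_months("bad", "chl"), "4-digit")
})

test_that("radius extraction matches a brute-force scan and is monotone", {
  set.seed(61)
  grid <- as.data.frame(pengkrill:::local_xy_to_lonlat(
    runif(400, -120, 120), runif(400, -120, 120), test_colony))
  at_colony <- data.frame(lon = test_colony[1], lat = test_colony[2])
  grid <- rbind(grid, at_colony)
  out <- extract_radius(grid, test_colony, 75)
  d <- haversine_km(grid$lon, grid$lat, test_colony[1], test_colony[2])
  expect_equal(nrow(out), sum(d <= 75))    # exhaustive oracle
  expect_true(any(out$lon == test_colony[1] & out$lat == test_colony[2]))

  far <- grid[d > 100, , drop = FALSE]
  expect_false(any(paste(out$lon, out$lat) %in% paste(far$lon, far$lat)))

  counts <- vapply(c(25, 50, 75, 100), function(r)
    nrow(extract_radius(grid, test_colony, r)), integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(extract_radius(far, test_colony, 10), "no grid cells")
})

test_that("seasonal means average the window months per cell", {
  env <- expand.grid(month = c("2019-11", "2019-12", "2020-01"), cell_id = 1:4)
  env$variable <- "chl"
  env$lon <- -59 + env$cell_id * 0.01
  env$lat <- -62
  env$value <- 2
  sm <- seasonal_means(env, "chl", "2019/20")
  expect_equal(sm$value, rep(2, 4))        # constant field stays constant

  env$value <- ave(seq_len(nrow(env)), env$cell_id, FUN = seq_along)  # 1,2,3 per cell
  sm2 <- seasonal_means(env, "chl", "2019/20")
  expect_equal(sm2$value, rep(2, 4))

  expect_warning(seasonal_means(env[env$month != "2020-01", ], "chl", "2019/20"),
                 "missing month")
  expect_error(seasonal_means(env, "sic", "2019/20"), "no months")
})

test_that("monthly climatology summarises across years", {
  s <- expand.grid(year = 2005:2022, month = 1:12)
  s$value <- 3
  cl <- monthly_climatology(s)
  expect_equal(nrow(cl), 12L)
  expect_true(all(cl$sd == 0))
  expect_true(all(cl$n_years == 18L))

  two <- data.frame(year = c(2005, 2006), month = 2, value = c(1, 3))
  cl2 <- monthly_climatology(two)
  expect_equal(cl2$mean, 2)
  expect_equal(cl2$sd, sd(c(1, 3)))

  one <- data.frame(year = 2005, month = 7, value = 5)
  expect_true(is.na(monthly_climatology(one)$sd))
  # invariance to year ordering
  shuffled <- two[c(2, 1), ]
  expect_equal(monthly_climatology(shuffled), cl2)
})

test_that("breeding success is chicks per nest, scale-free, with exclusions", {
  rec <- data.frame(subcolony = c("a", "b"), season = "2019/20",
                    nests_incubation = c(100, 50), chicks_creche = c(80, 60))
  bs <- breeding_success(rec)
  expect_equal(bs$success, c(0.8, 1.2))

  scaled <- rec
  scaled$nests_incubation <- rec$nests_incubation * 3
  scaled$chicks_creche <- rec$chicks_creche * 3
  expect_equal(breeding_success(scaled)$success, bs$success)

  withzero <- rbind(rec, data.frame(subcolony = "c", season = "2019/20",
                                    nests_incubation = 0, chicks_creche = 2))
  expect_message(bz <- breeding_success(withzero), "zero nests")
  expect_equal(nrow(bz), 2L)

  expect_error(breeding_success(rec[0, ]), "no breeding records")

  two <- rbind(rec, data.frame(subcolony = c("c", "d"), season = "2021/22",
                               nests_incubation = c(100, 100),
                               chicks_creche = c(50, 50)))
  expect_equal(season_success_ratio(breeding_success(two), "2019/20", "2021/22"),
               2)
  expect_error(season_success_ratio(bs, "2019/20", "1999/00"), "present")
})
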