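# Helper: a surface series with square dives inserted at known offsets.
square_dive_series <- function(n_dives = 3, depth = 40, bottom_s = 60,
                               gap_s = 300, offset = 0) {
  one <- c(seq(2, depth, by = 2), rep(depth, bottom_s), seq(depth - 2, 2, by = -2))
  depths <- numeric(gap_s)
  for (i in seq_len(n_dives)) depths <- c(depths, one, numeric(gap_s))
  depths + offset
}

test_that("zero-offset correction removes constant and drifting baselines", {
  x <- square_dive_series(3, offset = 0.8)
  z <- zero_offset_correct(x, window = 600)
  surf <- z[square_dive_series(3, offset = 0) == 0]
  expect_lt(abs(stats::median(surf)), 0.05)

  clean <- square_dive_series(3, offset = 0)
  expect_lt(max(abs(zero_offset_correct(clean, window = 600) - clean)), 0.01)

  n <- 7200
  drift <- seq(0, 1, length.out = n)       # 0 -> 1 m over 2 h
  base <- c(square_dive_series(5), numeric(n))[1:n]
  z2 <- zero_offset_correct(base + drift, window = 600)
  expect_lt(abs(stats::median(z2[base == 0])), 0.1)

  expect_error(zero_offset_correct(numeric(0)), "empty")
})

test_that("dive detection finds threshold crossings", {
  shallow <- c(0, 1, 2, 1.5, 0)
  expect_equal(nrow(detect_dives(shallow)), 0L)

  x <- square_dive_series(12)
  dd <- detect_dives(x)
  expect_equal(nrow(dd), 12L)
  expect_equal(dd$max_depth, rep(40, 12))
  expect_warning(detect_dives(c(0, 10, 20, 10, 0), cadence = 2), "resampling")
})

test_that("phase segmentation: U, V and triangular dives", {
  u <- c(0, rep(40, 60), 0)
  du <- detect_dives(u)
  seg <- segment_phases(as.list(du[1, ]), attr(du, "depths"))
  expect_equal(seg$bottom_duration_s, 60)
  expect_equal(seg$bottom_mean_depth, 40)

  v <- c(0, 20, 40, 20, 0)
  dv <- detect_dives(v)
  segv <- segment_phases(as.list(dv[1, ]), attr(dv, "depths"))
  expect_equal(segv$bottom_duration_s, 1)  # single-sample maximum

  tri <- c(seq(0, 50, by = 2.5), seq(47.5, 0, by = -2.5))
  dt <- detect_dives(tri)
  segt <- segment_phases(as.list(dt[1, ]), attr(dt, "depths"))
  expect_equal(segt$bottom_duration_s, sum(tri >= 40))   # 0.8 x 50 m band
  # a 3-sample dive is too short for a bottom phase
  tiny <- detect_dives(c(0, 5, 0))
  segs <- segment_phases(as.list(tiny[1, ]), attr(tiny, "depths"))
  expect_true(is.na(segs$bottom_mean_depth) || segs$bottom_duration_s <= 1)
})

test_that("wiggle counting follows the prominence rule", {
  saw <- c(0, rep(40, 5), rep(c(38, 40, 40), 5), 0)   # 5 upward excursions of 2 m
  d <- detect_dives(saw)
  seg <- segment_phases(as.list(d[1, ]), attr(d, "depths"))
  expect_equal(count_wiggles(seg, attr(d, "depths"), min_amplitude = 1), 5L)
  expect_equal(count_wiggles(seg, attr(d, "depths"), min_amplitude = 2), 5L)
  expect_equal(count_wiggles(seg, attr(d, "depths"), min_amplitude = 2.5), 0L)

  flat <- c(0, rep(40, 30), 0)
  df <- detect_dives(flat)
  segf <- segment_phases(as.list(df[1, ]), attr(df, "depths"))
  expect_equal(count_wiggles(segf, attr(df, "depths")), 0L)

  sub <- c(0, rep(40, 3), rep(c(39.6, 40, 40), 4), 0)  # 0.4 m oscillations
  ds <- detect_dives(sub)
  segsub <- segment_phases(as.list(ds[1, ]), attr(ds, "depths"))
  expect_equal(count_wiggles(segsub, attr(ds, "depths"), min_amplitude = 1), 0L)
})

test_that("raising the amplitude threshold never increases the wiggle count", {
  set.seed(12)
  for (k in 1:25) {
    nw <- sample(0:12, 1)
    prof <- simulate_dive_profile(60, 40 + 2 * nw, nw,
                                  wiggle_amplitude = runif(1, 1.2, 3))
    d <- detect_dives(prof)
    seg <- segment_phases(as.list(d[1, ]), attr(d, "depths"))
    counts <- vapply(c(0.5, 1, 1.5, 2, 2.5, 3.5),
                     function(a) count_wiggles(seg, attr(d, "depths"), a),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("completeness classification uses the bottom-duration threshold", {
  u <- detect_dives(c(0, rep(40, 60), 0))
  seg <- segment_phases(as.list(u[1, ]), attr(u, "depths"))
  expect_true(classify_complete(seg))

  v <- detect_dives(c(0, 20, 40, 20, 0))
  segv <- segment_phases(as.list(v[1, ]), attr(v, "depths"))
  expect_false(classify_complete(segv))

  five <- detect_dives(c(0, 20, rep(40, 5), 20, 0))
  seg5 <- segment_phases(as.list(five[1, ]), attr(five, "depths"))
  expect_equal(seg5$bottom_duration_s, 5)
  expect_true(classify_complete(seg5))     # boundary counts as complete
})

test_that("phase partition and bottom-fraction monotonicity hold on simulated dives", {
  set.seed(21)
  for (k in 1:20) {
    prof <- simulate_dive_profile(runif(1, 20, 120), runif(1, 40, 90),
                                  sample(0:8, 1), runif(1, 1.2, 3))
    d <- detect_dives(prof)
    seg <- segment_phases(as.list(d[1, ]), attr(d, "depths"))
    # bottom phase inside the dive: descent before, ascent after
    expect_gte(seg$bottom_start_idx, seg$start_idx)
    expect_lte(seg$bottom_end_idx, seg$end_idx)
    n_desc <- seg$bottom_start_idx - seg$start_idx
    n_asc <- seg$end_idx - seg$bottom_end_idx
    expect_equal(n_desc + seg$bottom_duration_s + n_asc,
                 seg$end_idx - seg$start_idx + 1)
    hi <- segment_phases(as.list(d[1, ]), attr(d, "depths"), bottom_fraction = 0.9)
    expect_lte(hi$bottom_duration_s, seg$bottom_duration_s)
  }
})

test_that("per-trip dive metrics aggregate as specified", {
  mk <- function(dur, depth, wig, comp)
    data.frame(duration_s = dur, bottom_mean_depth = depth,
               bottom_max_depth = depth + 2, n_wiggles = wig, complete = comp)
  dives <- rbind(mk(100, 40, 2, TRUE), mk(110, 42, 4, TRUE),
                 mk(90, 38, 6, TRUE), mk(15, 8, 0, FALSE))
  m <- trip_dive_metrics(dives)
  expect_equal(m$freq_complete, 0.75)
  expect_equal(m$mean_capture_effort, 4)
  expect_equal(m$cum_dive_duration_min, sum(dives$duration_s) / 60)
  expect_equal(m$max_bottom_depth_m, 44)
  expect_equal(m$total_wiggles, 12L)

  empty <- trip_dive_metrics(dives[0, ])
  expect_true(is.na(empty$freq_complete))
  expect_equal(empty$n_dives, 0L)
})

test_that("vertical effort profile bins trips into 5-m strata", {
  tm <- data.frame(mean_bottom_depth_m = c(41, 43, 44), total_wiggles = c(3, 4, 3),
                   n_dives = c(10, 12, 9))
  prof <- vertical_effort_profile(tm)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$stratum_lo, 40)
  expect_equal(prof$total_wiggles, 10)

  expect_equal(nrow(vertical_effort_profile(tm[0, ])), 0L)
})

test_that("synthetic default dives keep wiggles in 2-17 and last under 2 min mostly", {
  b <- simulate_bundle(small_good(seed = 410L))
  truth <- b$truth$dives
  recs <- do.call(rbind, lapply(names(b$tdr_tables), function(bird)
    dive_records(b$tdr_tables[[bird]]$depth_m)))
  wig <- recs$n_wiggles[recs$complete]
  expect_true(all(wig >= 2 & wig <= 17))
  expect_gt(mean(recs$duration_s < 120), 0.5)
  expect_equal(sum(recs$complete), sum(truth$complete))
})
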