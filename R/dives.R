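# TDR dive analysis: surface-offset correction, dive detection, phase
# segmentation, wiggle (capture-effort) counting, and per-trip aggregation.

#' Zero-offset correction of a TDR depth series
#'
#' TDR pressure sensors drift, so the recorded "surface" is offset from zero.
#' The series is split into blocks of `window` seconds; a low quantile of
#' each block estimates the local surface baseline, which is interpolated
#' linearly across the series, subtracted, and the result clipped at zero.
#' Blocks must contain some surface time (at least `quantile` of the block)
#' for the baseline to track the sensor rather than the dives; penguin TDR
#' series satisfy this through post-dive surface intervals.
#'
#' @param depths Numeric vector of depths (m) at 1 Hz.
#' @param window Baseline block length in seconds (default 1800 s).
#' @param quantile Block quantile taken as the surface baseline (default 0.1).
#' @return Corrected depth vector, same length, all values >= 0.
#' @export
zero_offset_correct <- function(depths, window = 1800, quantile = 0.1) {
  if (length(depths) == 0L) stop("empty depth series")
  if (any(!is.finite(depths))) stop("depth series must be finite")
  n <- length(depths)
  if (n <= 2L) return(pmax(depths - min(depths), 0))
  nb <- max(1L, floor(n / window))
  breaks <- round(seq(1L, n + 1L, length.out = nb + 1L))
  mids <- (breaks[-(nb + 1L)] + breaks[-1L] - 1) / 2
  base <- vapply(seq_len(nb), function(b)
    stats::quantile(depths[breaks[b]:(breaks[b + 1L] - 1L)], quantile,
                    names = FALSE, type = 7),
    numeric(1))
  baseline <- if (nb == 1L) rep(base, n) else
    stats::approx(mids, base, xout = seq_len(n), rule = 2)$y
  pmax(depths - baseline, 0)
}

#' Detect dives in a corrected depth series
#'
#' Maximal runs of samples deeper than `threshold` become dives, with start
#' and end at the threshold crossings.
#'
#' @param depths Zero-offset-corrected depth vector (m).
#' @param threshold Dive detection depth (m, default 3).
#' @param cadence Sample interval (s); a non-1 Hz series is resampled to
#'   1 Hz with a warning.
#' @return A data.frame with one row per dive: `dive`, `start_idx`,
#'   `end_idx`, `duration_s`, `max_depth`. Attribute `"depths"` holds the
#'   (possibly resampled) series the indices refer to.
#' @export
detect_dives <- function(depths, threshold = 3, cadence = 1) {
  if (!isTRUE(all.equal(cadence, 1))) {
    warning("resampling depth series from ", cadence, " s to 1 s cadence")
    t0 <- (seq_along(depths) - 1) * cadence
    depths <- stats::approx(t0, depths, xout = 0:floor(max(t0)))$y
  }
  wet <- depths > threshold
  r <- rle(wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  out <- data.frame(dive = seq_along(sel),
                    start_idx = starts[sel], end_idx = ends[sel])
  out$duration_s <- out$end_idx - out$start_idx + 1L
  out$max_depth <- vapply(seq_len(nrow(out)), function(i)
    max(depths[out$start_idx[i]:out$end_idx[i]]), numeric(1))
  attr(out, "depths") <- depths
  out
}

#' Segment a dive into descent, bottom and ascent phases
#'
#' The bottom phase is the contiguous span from the first to the last sample
#' at or deeper than `bottom_fraction` of the dive's maximum depth; descent
#' precedes it and ascent follows. Dives shorter than 3 samples get no
#' bottom phase.
#'
#' @param dive A one-row dive record from [detect_dives()] (list or
#'   data.frame row with `start_idx`, `end_idx`).
#' @param depths The depth series the indices refer to.
#' @param bottom_fraction Fraction of maximum depth defining the bottom band
#'   (default 0.8).
#' @return The dive record with `bottom_start_idx`, `bottom_end_idx`,
#'   `bottom_duration_s` (number of bottom samples times the 1 s cadence),
#'   `bottom_mean_depth` and `bottom_max_depth` added (`NA` when no bottom).
#' @export
segment_phases <- function(dive, depths, bottom_fraction = 0.8) {
  s <- dive$start_idx; e <- dive$end_idx
  d <- depths[s:e]
  if (length(d) < 3L) {
    dive$bottom_start_idx <- NA_integer_
    dive$bottom_end_idx <- NA_integer_
    dive$bottom_duration_s <- 0
    dive$bottom_mean_depth <- NA_real_
    dive$bottom_max_depth <- NA_real_
    return(dive)
  }
  band <- which(d >= bottom_fraction * max(d))
  b0 <- band[1L]; b1 <- band[length(band)]
  dive$bottom_start_idx <- s + b0 - 1L
  dive$bottom_end_idx <- s + b1 - 1L
  dive$bottom_duration_s <- b1 - b0 + 1L
  dive$bottom_mean_depth <- mean(d[b0:b1])
  dive$bottom_max_depth <- max(d[b0:b1])
  dive
}

#' Count wiggles in a dive's bottom phase
#'
#' A wiggle is an upward excursion of the depth trace during the bottom
#' phase: a local depth minimum whose depth drops by at least
#' `min_amplitude` metres on both flanks before the trace rises above it
#' again (a prominence rule). Wiggles proxy prey-capture attempts.
#'
#' @param dive A dive record with phases set (see [segment_phases()]).
#' @param depths The depth series the indices refer to.
#' @param min_amplitude Minimum prominence (m, default 1).
#' @return Integer wiggle count (0 when the dive has no bottom phase).
#' @export
count_wiggles <- function(dive, depths, min_amplitude = 1) {
  if (is.na(dive$bottom_start_idx)) return(0L)
  seg <- depths[dive$bottom_start_idx:dive$bottom_end_idx]
  count_prominent_minima(seg, min_amplitude)
}

# Prominent local minima of `x`: plateaus are compressed to single
# candidates; a candidate at value v counts if, on each flank, the series
# reaches at least v + min_prom (deeper) before dropping strictly below v.
count_prominent_minima <- function(x, min_prom) {
  r <- rle(x)
  v <- r$values
  m <- length(v)
  if (m < 3L) return(0L)
  cand <- which(v[-c(1L, m)] < v[-c(m - 1L, m)] & v[-c(1L, m)] < v[-c(1L, 2L)]) + 1L
  n_ok <- 0L
  for (i in cand) {
    vi <- v[i]
    ok_left <- FALSE
    peak <- vi
    for (j in (i - 1L):1L) {
      if (v[j] > peak) peak <- v[j]
      if (peak - vi >= min_prom) { ok_left <- TRUE; break }
      if (v[j] < vi) break
    }
    if (!ok_left) next
    peak <- vi
    for (j in (i + 1L):m) {
      if (v[j] > peak) peak <- v[j]
      if (peak - vi >= min_prom) { n_ok <- n_ok + 1L; break }
      if (v[j] < vi) break
    }
  }
  n_ok
}

#' Classify a dive as complete
#'
#' A dive is complete when its bottom phase lasts at least `min_bottom_s`
#' seconds, operationalising "a dive with a bottom phase" (prey found).
#'
#' @param dive A dive record with phases set.
#' @param min_bottom_s Completeness threshold in seconds (default 5; the
#'   boundary counts as complete).
#' @return Logical flag.
#' @export
classify_complete <- function(dive, min_bottom_s = 5) {
  isTRUE(dive$bottom_duration_s >= min_bottom_s)
}

#' Full dive analysis of one depth series
#'
#' Convenience wrapper: optional zero-offset correction, dive detection,
#' phase segmentation, wiggle counting and completeness classification.
#'
#' @inheritParams detect_dives
#' @inheritParams segment_phases
#' @inheritParams count_wiggles
#' @inheritParams classify_complete
#' @param zoc Apply [zero_offset_correct()] first?
#' @param zoc_window,zoc_quantile Passed to [zero_offset_correct()].
#' @return A data.frame of dive records (one row per dive) with phase
#'   indices, bottom statistics, `n_wiggles` and `complete`.
#' @export
dive_records <- function(depths, threshold = 3, bottom_fraction = 0.8,
                         min_amplitude = 1, min_bottom_s = 5, zoc = TRUE,
                         zoc_window = 1800, zoc_quantile = 0.1, cadence = 1) {
  if (zoc) depths <- zero_offset_correct(depths, zoc_window, zoc_quantile)
  dd <- detect_dives(depths, threshold = threshold, cadence = cadence)
  depths <- attr(dd, "depths")
  if (nrow(dd) == 0L) {
    dd$bottom_start_idx <- integer(0); dd$bottom_end_idx <- integer(0)
    dd$bottom_duration_s <- numeric(0); dd$bottom_mean_depth <- numeric(0)
    dd$bottom_max_depth <- numeric(0); dd$n_wiggles <- integer(0)
    dd$complete <- logical(0)
    return(dd)
  }
  recs <- lapply(seq_len(nrow(dd)), function(i) {
    dv <- segment_phases(as.list(dd[i, ]), depths, bottom_fraction)
    dv$n_wiggles <- count_wiggles(dv, depths, min_amplitude)
    dv$complete <- classify_complete(dv, min_bottom_s)
    as.data.frame(dv)
  })
  do.call(rbind, recs)
}

#' Aggregate dive records into per-trip dive metrics
#'
#' Frequency of complete dives is taken over all dives and cumulative dive
#' duration sums all dives; dive duration, bottom depths and capture effort
#' (wiggles per dive) are summarised over complete dives only, since wiggles
#' and bottom statistics are defined within bottom phases.
#'
#' @param dives A data.frame of dive records (see [dive_records()]),
#'   typically for one trip.
#' @return A one-row data.frame: `n_dives`, `freq_complete`,
#'   `mean_dive_duration_min`, `cum_dive_duration_min`,
#'   `mean_bottom_depth_m`, `max_bottom_depth_m`, `mean_capture_effort`,
#'   `total_wiggles`. With zero dives all metrics are zero and
#'   `freq_complete` is `NA`.
#' @export
trip_dive_metrics <- function(dives) {
  if (is.null(dives) || nrow(dives) == 0L)
    return(data.frame(n_dives = 0L, freq_complete = NA_real_,
                      mean_dive_duration_min = 0, cum_dive_duration_min = 0,
                      mean_bottom_depth_m = 0, max_bottom_depth_m = 0,
                      mean_capture_effort = 0, total_wiggles = 0L))
  cp <- dives[dives$complete, , drop = FALSE]
  data.frame(
    n_dives = nrow(dives),
    freq_complete = nrow(cp) / nrow(dives),
    mean_dive_duration_min = if (nrow(cp)) mean(cp$duration_s) / 60 else 0,
    cum_dive_duration_min = sum(dives$duration_s) / 60,
    mean_bottom_depth_m = if (nrow(cp)) mean(cp$bottom_mean_depth) else 0,
    max_bottom_depth_m = if (nrow(cp)) max(cp$bottom_max_depth) else 0,
    mean_capture_effort = if (nrow(cp)) mean(cp$n_wiggles) else 0,
    total_wiggles = sum(dives$n_wiggles))
}

#' Vertical distribution of foraging effort across trips
#'
#' Bins each trip's mean bottom depth into depth strata and sums the trip's
#' wiggles within each stratum, giving the depth profile of capture effort
#' that can be compared with the krill vertical distribution.
#'
#' @param trip_metrics A data.frame with columns `mean_bottom_depth_m` and
#'   `total_wiggles` (one row per trip; see [trip_dive_metrics()]).
#' @param bin Stratum height in metres (default 5).
#' @return A data.frame: `stratum_lo`, `stratum_hi`, `n_trips`,
#'   `total_wiggles`, `mean_bottom_depth`. Empty input gives an empty table.
#' @export
vertical_effort_profile <- function(trip_metrics, bin = 5) {
  empty <- data.frame(stratum_lo = numeric(0), stratum_hi = numeric(0),
                      n_trips = integer(0), total_wiggles = numeric(0),
                      mean_bottom_depth = numeric(0))
  if (is.null(trip_metrics) || nrow(trip_metrics) == 0L) return(empty)
  tm <- trip_metrics[is.finite(trip_metrics$mean_bottom_depth_m) &
                       trip_metrics$n_dives > 0, , drop = FALSE]
  if (nrow(tm) == 0L) return(empty)
  lo <- floor(tm$mean_bottom_depth_m / bin) * bin
  agg <- stats::aggregate(cbind(total_wiggles = tm$total_wiggles,
                                n = 1, depth = tm$mean_bottom_depth_m),
                          by = list(stratum_lo = lo), FUN = sum)
  data.frame(stratum_lo = agg$stratum_lo, stratum_hi = agg$stratum_lo + bin,
             n_trips = as.integer(agg$n), total_wiggles = agg$total_wiggles,
             mean_bottom_depth = agg$depth / agg$n)
}

#' Analyse one bird's TDR table and assign dives to trips
#'
#' Runs [dive_records()] on the bird's depth series and labels each dive
#' with the trip (from `trips`) whose time window contains its start.
#' Dives outside any trip window are dropped.
#'
#' @param tdr Data.frame with columns `time` (POSIXct) and `depth_m` at 1 Hz.
#' @param trips Data.frame with `trip_id`, `start`, `end` (see
#'   [trips_table()]), already subset to this bird.
#' @inheritParams dive_records
#' @return Dive-record data.frame with `trip_id` and `start_time` columns.
#' @export
process_tdr_table <- function(tdr, trips, threshold = 3, bottom_fraction = 0.8,
                              min_amplitude = 1, min_bottom_s = 5,
                              zoc_window = 1800, zoc_quantile = 0.1) {
  recs <- dive_records(tdr$depth_m, threshold = threshold,
                       bottom_fraction = bottom_fraction,
                       min_amplitude = min_amplitude,
                       min_bottom_s = min_bottom_s,
                       zoc_window = zoc_window, zoc_quantile = zoc_quantile)
  if (nrow(recs) == 0L) {
    recs$trip_id <- character(0)
    recs$start_time <- as.POSIXct(character(0), tz = "UTC")
    return(recs)
  }
  recs$start_time <- tdr$time[recs$start_idx]
  recs$trip_id <- NA_character_
  for (j in seq_len(nrow(trips))) {
    inside <- recs$start_time >= trips$start[j] & recs$start_time <= trips$end[j]
    recs$trip_id[inside] <- trips$trip_id[j]
  }
  recs[!is.na(recs$trip_id), , drop = FALSE]
}
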