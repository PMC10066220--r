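# Ripley's K with isotropic edge correction, and the depth-stratified
# aggregation index for NASC detection cells.

#' Ripley's K with isotropic edge correction for one depth stratum
#'
#' Estimates \eqn{K_{iso}(r) = \frac{|W|}{n(n-1)} \sum_{i \ne j} w_{ij}
#' \, 1[d_{ij} \le r]} over a rectangular window, where the isotropic edge
#' weight \eqn{w_{ij}} is the inverse of the fraction of the circle of
#' radius \eqn{d_{ij}} centred at point *i* that lies inside the window
#' (computed numerically from `n_arc` equally spaced circle points). The
#' aggregation index is the mean over the radii grid of
#' \eqn{K_{iso}(r) - \pi r^2}: positive values indicate aggregation,
#' values near zero complete spatial randomness, negative values
#' dispersion.
#'
#' @param points Two-column matrix or data.frame of point coordinates (km).
#' @param window Numeric `c(x0, x1, y0, y1)` rectangle containing the points.
#' @param radii Radii grid (km); default 10 radii linearly spaced up to a
#'   quarter of the shorter window side.
#' @param min_points Minimum number of points for a defined index
#'   (default 5); below it `k_iso` and the index are `NA`.
#' @param n_arc Number of circle samples for the numeric arc fraction
#'   (default 360).
#' @return An object of class `"stratum_aggregation"`: a list with
#'   `n_points`, `radii`, `k_iso`, `k_expected` (\eqn{\pi r^2}) and
#'   `aggregation_index`.
#' @export
ripley_k_stratum <- function(points, window, radii = NULL, min_points = 5,
                             n_arc = 360) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("`points` must have two columns (x, y)")
  if (length(window) != 4L || window[2] <= window[1] || window[4] <= window[3])
    stop("`window` must be c(x0, x1, y0, y1) with positive extent")
  n <- nrow(pts)
  if (n > 0 && (any(pts[, 1] < window[1]) || any(pts[, 1] > window[2]) ||
                any(pts[, 2] < window[3]) || any(pts[, 2] > window[4])))
    stop("all points must lie inside the window")
  if (is.null(radii)) {
    side <- min(window[2] - window[1], window[4] - window[3])
    radii <- seq(side / 40, side / 4, length.out = 10)
  }
  radii <- sort(radii)
  area <- (window[2] - window[1]) * (window[4] - window[3])
  if (n < min_points) {
    return(structure(list(n_points = n, radii = radii,
                          k_iso = rep(NA_real_, length(radii)),
                          k_expected = pi * radii^2,
                          aggregation_index = NA_real_, window = window),
                     class = "stratum_aggregation"))
  }
  dm <- as.matrix(stats::dist(pts))
  near <- dm <= max(radii)
  diag(near) <- FALSE
  pair <- which(near, arr.ind = TRUE)       # ordered pairs: weight is centred on i
  k_iso <- numeric(length(radii))
  if (nrow(pair)) {
    d <- dm[pair]
    w <- iso_weights(pts[pair[, 1], 1], pts[pair[, 1], 2], d, window, n_arc)
    for (k in seq_along(radii))
      k_iso[k] <- sum(w[d <= radii[k]])
    k_iso <- k_iso * area / (n * (n - 1))
  }
  structure(list(n_points = n, radii = radii, k_iso = k_iso,
                 k_expected = pi * radii^2,
                 aggregation_index = mean(k_iso - pi * radii^2),
                 window = window),
            class = "stratum_aggregation")
}

# Inverse fraction of each circle (centre (x, y), radius d) inside the
# rectangular window, sampled at n_arc angles. Weights are exactly 1 when
# the whole circle is inside. The fraction is floored at 1/n_arc (the
# paired point itself is inside the window) to avoid infinite weights in
# very elongated windows.
iso_weights <- function(x, y, d, window, n_arc) {
  theta <- (seq_len(n_arc) - 1L) * 2 * pi / n_arc
  ct <- cos(theta); st <- sin(theta)
  m <- length(d)
  frac <- numeric(m)
  chunk <- max(1L, floor(4e6 / n_arc))
  for (s in seq(1L, m, by = chunk)) {
    i <- s:min(m, s + chunk - 1L)
    px <- outer(d[i], ct) + x[i]
    py <- outer(d[i], st) + y[i]
    inside <- px >= window[1] & px <= window[2] & py >= window[3] & py <= window[4]
    frac[i] <- rowMeans(inside)
  }
  1 / pmax(frac, 1 / n_arc)
}

#' @export
print.stratum_aggregation <- function(x, ...) {
  cat(sprintf("Ripley's K stratum aggregation: n = %d, radii %.2f-%.2f km\n",
              x$n_points, min(x$radii), max(x$radii)))
  if (is.na(x$aggregation_index)) {
    cat("  aggregation index undefined (too few points)\n")
  } else {
    lab <- if (x$aggregation_index > 0) "aggregated" else "dispersed"
    cat(sprintf("  mean(K_iso - pi r^2) = %.3f (%s)\n", x$aggregation_index, lab))
  }
  invisible(x)
}

#' Depth-stratified swarm aggregation from a NASC grid
#'
#' For each 5-m stratum, takes the along-transect midpoints of cells with
#' NASC detection (`nasc > detection`), places them on the transect line
#' inside a rectangular corridor window (transect length plus a one-cell
#' buffer by `corridor_width_km`), and computes the isotropic Ripley's K
#' aggregation index. Radii default to 10 values up to three along-track
#' bins (or a quarter of the transect if shorter): krill swarm clustering
#' operates at the scale of a few sampling bins, and the index loses power
#' to between-stratum noise at much longer radii.
#'
#' @param grid A [echo_integrate()] grid.
#' @param detection NASC detection threshold (default 0: any positive cell).
#' @param radii Radii grid (km); default as described above.
#' @param corridor_width_km Window height (km); defaults to one along bin.
#' @param min_points Minimum detections per stratum for a defined index.
#' @return A data.frame with one row per stratum (`depth_bin`,
#'   `depth_mid_m`, `n_points`, `aggregation_index`); the full
#'   `"stratum_aggregation"` objects are attached as attribute `"strata"`.
#' @export
aggregation_by_depth <- function(grid, detection = 0, radii = NULL,
                                 corridor_width_km = NULL, min_points = 5) {
  stopifnot(nrow(grid) > 0)
  bin_km <- attr(grid, "along_bin_nmi") * NMI_KM
  if (is.null(corridor_width_km)) corridor_width_km <- bin_km
  l_km <- max(grid$along_bin) * bin_km
  window <- c(-bin_km, l_km + bin_km, -corridor_width_km / 2, corridor_width_km / 2)
  if (is.null(radii)) {
    rmax <- min(l_km / 4, 3 * bin_km)
    radii <- seq(rmax / 10, rmax, length.out = 10)
  }
  strata <- list()
  rows <- list()
  for (db in sort(unique(grid$depth_bin))) {
    cells <- grid[grid$depth_bin == db & grid$nasc > detection, , drop = FALSE]
    pts <- cbind(x = cells$distance_mid_nmi * NMI_KM, y = rep(0, nrow(cells)))
    sa <- ripley_k_stratum(pts, window, radii = radii, min_points = min_points)
    strata[[as.character(db)]] <- sa
    rows[[length(rows) + 1L]] <- data.frame(
      depth_bin = db, depth_mid_m = grid$depth_mid_m[grid$depth_bin == db][1],
      n_points = sa$n_points, aggregation_index = sa$aggregation_index)
  }
  out <- do.call(rbind, rows)
  attr(out, "strata") <- strata
  out
}
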