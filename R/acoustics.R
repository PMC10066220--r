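# Echo-integration of sample densities into NASC cells, vertical profiles
# and swarm-depth selection.

#' Echo-integrate acoustic samples into a NASC cell grid
#'
#' Sums sample densities into basic sampling units of `along_bin` nautical
#' miles by `depth_bin` metres (half-open bins `[lo, hi)`), covering the
#' transect from 0 to its full length and depths from 0 to `max_depth`.
#' Samples deeper than `max_depth` are dropped and counted.
#'
#' @param samples Data.frame with columns `distance_nmi`, `depth_m`,
#'   `density` (all non-negative).
#' @param along_bin Along-transect bin size (nautical miles, default 0.5).
#' @param depth_bin Depth stratum height (m, default 5).
#' @param max_depth Echo-integration range (m, default 500).
#' @param transect_length_nmi Transect length; defaults to the smallest
#'   whole number of along bins covering the samples.
#' @return An object of class `"nasc_grid"`: a data.frame with one row per
#'   cell (`along_bin`, `depth_bin` 1-based indices, `distance_mid_nmi`,
#'   `depth_mid_m`, `nasc`), with attributes `along_bin_nmi`,
#'   `depth_bin_m`, `n_dropped`.
#' @export
echo_integrate <- function(samples, along_bin = 0.5, depth_bin = 5,
                           max_depth = 500, transect_length_nmi = NULL) {
  stopifnot(all(c("distance_nmi", "depth_m", "density") %in% names(samples)))
  if (nrow(samples) > 0 &&
      (any(samples$density < 0) || any(samples$distance_nmi < 0)))
    stop("sample densities and distances must be non-negative")
  keep <- samples$depth_m < max_depth & samples$depth_m >= 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " sample(s) outside [0, ", max_depth, ") m dropped")
  samples <- samples[keep, , drop = FALSE]
  if (is.null(transect_length_nmi))
    transect_length_nmi <- if (nrow(samples)) ceiling(max(samples$distance_nmi) / along_bin) * along_bin else along_bin
  n_along <- max(1L, ceiling(transect_length_nmi / along_bin - 1e-9))
  n_depth <- ceiling(max_depth / depth_bin)
  grid <- expand.grid(along_bin = seq_len(n_along), depth_bin = seq_len(n_depth))
  grid$distance_mid_nmi <- (grid$along_bin - 0.5) * along_bin
  grid$depth_mid_m <- (grid$depth_bin - 0.5) * depth_bin
  grid$nasc <- 0
  if (nrow(samples)) {
    ai <- pmin(floor(samples$distance_nmi / along_bin) + 1L, n_along)
    di <- floor(samples$depth_m / depth_bin) + 1L
    idx <- (di - 1L) * n_along + ai          # row order of expand.grid
    sums <- tapply(samples$density, idx, sum)
    grid$nasc[as.integer(names(sums))] <- as.numeric(sums)
  }
  structure(grid, class = c("nasc_grid", "data.frame"),
            along_bin_nmi = along_bin, depth_bin_m = depth_bin,
            n_dropped = n_dropped)
}

#' @export
print.nasc_grid <- function(x, ...) {
  cat(sprintf("NASC grid: %d along-track bins x %d depth strata (%g nmi x %g m)\n",
              max(x$along_bin), max(x$depth_bin),
              attr(x, "along_bin_nmi"), attr(x, "depth_bin_m")))
  cat(sprintf("  total NASC %.1f, %d cells with detection\n",
              sum(x$nasc), sum(x$nasc > 0)))
  invisible(x)
}

#' Select depths of high-density swarm cells
#'
#' Returns the depths of cells whose NASC exceeds a density threshold. With
#' `threshold = "q1"` the threshold is the first quartile of the positive
#' cell NASC values (type-7 linear interpolation, R's default quantile
#' convention); a number overrides it.
#'
#' @param grid A [echo_integrate()] grid.
#' @param threshold `"q1"` or a numeric NASC threshold.
#' @return A data.frame of qualifying cells (`along_bin`, `depth_bin`,
#'   `depth_m`, `nasc`) with the realised threshold as attribute
#'   `"threshold"`. Empty (with a warning) when no cell is positive.
#' @export
swarm_depth_selection <- function(grid, threshold = "q1") {
  stopifnot(nrow(grid) > 0)
  pos <- grid$nasc[grid$nasc > 0]
  if (length(pos) == 0L) {
    warning("no cells with positive NASC; empty swarm selection")
    return(structure(data.frame(along_bin = integer(0), depth_bin = integer(0),
                                depth_m = numeric(0), nasc = numeric(0)),
                     threshold = NA_real_))
  }
  thr <- if (identical(threshold, "q1"))
    stats::quantile(pos, 0.25, names = FALSE, type = 7) else as.numeric(threshold)
  sel <- grid[grid$nasc > thr, c("along_bin", "depth_bin", "depth_mid_m", "nasc")]
  names(sel)[3] <- "depth_m"
  rownames(sel) <- NULL
  structure(sel, threshold = thr)
}

#' Vertical NASC profile
#'
#' Mean and standard error of cell NASC per depth stratum, across
#' along-track bins.
#'
#' @param grid A [echo_integrate()] grid.
#' @return Data.frame `depth_bin`, `depth_mid_m`, `mean_nasc`, `se_nasc`
#'   (`NA` with a single along-track bin).
#' @export
vertical_profile <- function(grid) {
  stopifnot(nrow(grid) > 0)
  sp <- split(grid$nasc, grid$depth_bin)
  mids <- tapply(grid$depth_mid_m, grid$depth_bin, function(z) z[1])
  n <- vapply(sp, length, integer(1))
  data.frame(depth_bin = as.integer(names(sp)),
             depth_mid_m = as.numeric(mids),
             mean_nasc = vapply(sp, mean, numeric(1)),
             se_nasc = ifelse(n > 1,
                              vapply(sp, stats::sd, numeric(1)) / sqrt(n),
                              NA_real_),
             row.names = NULL)
}
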