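#' @keywords internal
"_PACKAGE"

# Earth radius (km) used for every great-circle distance in the package.
EARTH_RADIUS_KM <- 6371

NMI_KM <- 1.852

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km, the convention used for
#' all track and grid geometry in this package.
#'
#' @param lon1,lat1 Numeric vectors of origin coordinates (decimal degrees).
#' @param lon2,lat2 Numeric vectors of destination coordinates.
#' @return Numeric vector of distances (km).
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

# Local tangent-plane conversions around a reference point. Adequate for the
# < 100 km scales of a central-place forager and a 75 km environmental radius.
local_xy_to_lonlat <- function(x_km, y_km, origin) {
  km_per_deg <- pi / 180 * EARTH_RADIUS_KM
  lat <- origin[2] + y_km / km_per_deg
  lon <- origin[1] + x_km / (km_per_deg * cos(origin[2] * pi / 180))
  cbind(lon = lon, lat = lat)
}

lonlat_to_local_xy <- function(lon, lat, origin) {
  km_per_deg <- pi / 180 * EARTH_RADIUS_KM
  cbind(x = (lon - origin[1]) * km_per_deg * cos(origin[2] * pi / 180),
        y = (lat - origin[2]) * km_per_deg)
}

assert_colony <- function(colony) {
  if (!is.numeric(colony) || length(colony) != 2L || !all(is.finite(colony)))
    stop("`colony` must be a finite (lon, lat) pair", call. = FALSE)
  invisible(colony)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. With seed = NULL the global stream is
# used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
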