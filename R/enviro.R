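# Environmental grid extraction with seasonal windows, monthly
# climatologies, and breeding success.

#' Month windows for a breeding season
#'
#' Spring–summer variables (CHL, PAR, SWS) are averaged over November to
#' January of the season; fractional sea-ice cover uses June to September
#' of the immediately previous winter (wSIC). Season labels follow the
#' austral convention `"2021/22"`, so the wSIC window for 2021/22 is
#' Jun–Sep 2021 and the summer window Nov 2021 – Jan 2022.
#'
#' @param season_label Season string, e.g. `"2019/20"`.
#' @param variable One of `"chl"`, `"par"`, `"sws"`, `"sic"`.
#' @return Character vector of months, `"YYYY-MM"`.
#' @export
season_months <- function(season_label, variable) {
  y <- suppressWarnings(as.integer(substr(season_label, 1, 4)))
  if (is.na(y)) stop("season label must start with a 4-digit year, e.g. \"2019/20\"")
  variable <- match.arg(tolower(variable), ENV_VARIABLES)
  if (variable == "sic")
    sprintf("%d-%02d", y, 6:9)
  else
    c(sprintf("%d-11", y), sprintf("%d-12", y), sprintf("%d-01", y + 1L))
}

#' Extract grid cells within a radius of the colony
#'
#' Keeps cells whose centres lie within `radius_km` great-circle kilometres
#' of the colony (centre-in-radius rule).
#'
#' @param grid Data.frame with `lon`, `lat` columns (one row per cell).
#' @param colony Numeric `(lon, lat)`.
#' @param radius_km Extraction radius (default 75 km).
#' @return The subset of `grid` within the radius.
#' @export
extract_radius <- function(grid, colony, radius_km = 75) {
  stopifnot(nrow(grid) > 0)
  assert_colony(colony)
  d <- haversine_km(grid$lon, grid$lat, colony[1], colony[2])
  out <- grid[d <= radius_km, , drop = FALSE]
  if (nrow(out) == 0L) stop("no grid cells within ", radius_km, " km of the colony")
  out
}

#' Per-cell seasonal means of an environmental variable
#'
#' Averages a variable's monthly grids over the season's window
#' ([season_months()]): Nov–Jan for CHL, PAR and SWS; Jun–Sep of the
#' previous winter for SIC. Missing months in the window produce a warning
#' and the mean over the available months.
#'
#' @param env Long data.frame with columns `variable`, `month`
#'   (`"YYYY-MM"`), `cell_id`, `lon`, `lat`, `value`.
#' @param variable Variable name.
#' @param season_label Season, e.g. `"2019/20"`.
#' @return Data.frame `cell_id`, `lon`, `lat`, `value` (per-cell mean).
#' @export
seasonal_means <- function(env, variable, season_label) {
  months <- season_months(season_label, variable)
  sub <- env[env$variable == variable & env$month %in% months, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no months of ", variable, " available for ", season_label)
  have <- unique(sub$month)
  if (!all(months %in% have))
    warning("missing month(s) ", paste(setdiff(months, have), collapse = ", "),
            "; averaging over available months")
  agg <- stats::aggregate(value ~ cell_id + lon + lat, data = sub, FUN = mean)
  agg[order(agg$cell_id), c("cell_id", "lon", "lat", "value")]
}

#' Monthly climatology of a long-term series
#'
#' Mean and standard deviation per calendar month across years, describing
#' the long-term seasonal cycle of a variable. Months observed in a single
#' year get an `NA` sd.
#'
#' @param series Data.frame with columns `year`, `month` (1–12), `value`.
#' @return Data.frame `month`, `n_years`, `mean`, `sd`, one row per
#'   observed calendar month, ordered by month.
#' @export
monthly_climatology <- function(series) {
  stopifnot(all(c("year", "month", "value") %in% names(series)))
  if (any(series$month < 1 | series$month > 12)) stop("months must be in 1..12")
  sp <- split(series$value, series$month)
  data.frame(month = as.integer(names(sp)),
             n_years = vapply(sp, length, integer(1)),
             mean = vapply(sp, mean, numeric(1)),
             sd = vapply(sp, function(v) if (length(v) > 1L) stats::sd(v) else NA_real_,
                         numeric(1)),
             row.names = NULL)
}

#' Breeding success per sub-colony
#'
#' Chicks raised per nest: the number of chicks counted at crèche divided
#' by the number of nests at incubation, per sub-colony. Records with zero
#' nests are excluded with a message.
#'
#' @param records Data.frame with columns `subcolony`, `season`,
#'   `nests_incubation`, `chicks_creche`.
#' @return The records with a `success` column added.
#' @export
breeding_success <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("no breeding records")
  stopifnot(all(c("subcolony", "season", "nests_incubation", "chicks_creche")
                %in% names(records)))
  bad <- records$nests_incubation <= 0
  if (any(bad)) {
    message(sum(bad), " record(s) with zero nests excluded")
    records <- records[!bad, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no breeding records with nests > 0")
  records$success <- records$chicks_creche / records$nests_incubation
  records
}

#' Ratio of mean breeding success between two seasons
#'
#' @param success A [breeding_success()] result.
#' @param numerator,denominator Season labels.
#' @return Single number: mean success in `numerator` over mean success in
#'   `denominator`.
#' @export
season_success_ratio <- function(success, numerator, denominator) {
  m <- tapply(success$success, success$season, mean)
  if (!all(c(numerator, denominator) %in% names(m)))
    stop("both seasons must be present in the records")
  unname(m[numerator] / m[denominator])
}
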