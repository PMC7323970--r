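# Derivation of the eight biophysical predictors from daily weather.
#
# Seasonal windows are defined by calendar month-day pairs (authoritative
# over any day-of-year annotation, which drifts with leap years) and
# resolved per calendar year; annual window statistics are averaged across
# the years present, matching a multi-year baseline framing.

#' Define a seasonal date window
#'
#' @param start,end `"mm-dd"` strings; `start` must not fall after `end`
#'   within the calendar year.
#' @param zone which climatic zone the window applies to
#'   (`"north"`, `"south"` or `"both"`).
#' @return an object of class `date_window`.
#' @export
date_window <- function(start, end, zone = c("both", "north", "south")) {
  zone <- match.arg(zone)
  s <- as.Date(paste0("2001-", start))
  e <- as.Date(paste0("2001-", end))
  if (is.na(s) || is.na(e)) stop("dates must be 'mm-dd'")
  if (s > e) stop("window start must not fall after its end")
  structure(list(start = start, end = end, zone = zone),
            class = "date_window")
}

#' Zone-specific growing-season windows
#'
#' North: 24 May to 30 September; south: 1 March to 30 June. The main
#' growing period differs between the unimodal northern and bimodal
#' southern rainfall regimes.
#' @return named list of two [date_window()]s.
#' @export
growing_season_windows <- function() {
  list(north = date_window("05-24", "09-30", "north"),
       south = date_window("03-01", "06-30", "south"))
}

#' Zone-specific sowing-period windows
#'
#' North: 24 May to 30 June; south: 1 March to 30 April.
#' @return named list of two [date_window()]s.
#' @export
sowing_windows <- function() {
  list(north = date_window("05-24", "06-30", "north"),
       south = date_window("03-01", "04-30", "south"))
}

#' The common March-September season window
#' @return a [date_window()] covering 1 March to 30 September for both zones.
#' @export
mar_sep_window <- function() date_window("03-01", "09-30", "both")

# Per-year window statistic of a [lat, lon, time] array, averaged over years.
window_stat_matrix <- function(arr, dates, win, stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  years <- sort(unique(format(dates, "%Y")))
  acc <- 0
  for (y in years) {
    s <- as.Date(paste0(y, "-", win$start))
    e <- as.Date(paste0(y, "-", win$end))
    if (s < min(dates) || e > max(dates))
      stop("window outside the data's date span")
    idx <- which(dates >= s & dates <= e)
    sl <- arr[, , idx, drop = FALSE]
    acc <- acc + if (stat == "sum") rowSums(sl, dims = 2) else rowMeans(sl, dims = 2)
  }
  acc / length(years)
}

# Evaluate a possibly zone-specific window statistic per pixel.
zone_window_stat <- function(arr, dates, windows, zone, stat) {
  if (inherits(windows, "date_window"))
    return(window_stat_matrix(arr, dates, windows, stat))
  if (!all(c("north", "south") %in% names(windows)))
    stop("'windows' must be a date_window or list(north=, south=)")
  n <- window_stat_matrix(arr, dates, windows$north, stat)
  s <- window_stat_matrix(arr, dates, windows$south, stat)
  out <- s
  out[zone == "north"] <- n[zone == "north"]
  out
}

#' Multi-year mean of within-window rainfall sums
#'
#' For each pixel, sums precipitation over the window matching the pixel's
#' zone in each year, then averages the annual sums across years.
#'
#' @param weather a [weather_grid()].
#' @param windows a single [date_window()] or `list(north=, south=)`.
#' @param zone character matrix `[lat, lon]` of `"north"`/`"south"` labels
#'   (ignored for a single window).
#' @return numeric matrix `[lat, lon]`, mm.
#' @export
window_rain_sum <- function(weather, windows, zone = NULL) {
  if (!inherits(windows, "date_window") && is.null(zone))
    stop("zone map required for zone-specific windows")
  zone_window_stat(weather$precip, weather$dates, windows, zone, "sum")
}

#' Multi-year mean of within-window daily mean temperature
#'
#' Daily mean temperature is `(tmax + tmin) / 2`. Per pixel, the mean over
#' the zone-appropriate window is computed per year and averaged.
#'
#' @inheritParams window_rain_sum
#' @return numeric matrix `[lat, lon]`, degrees C.
#' @export
window_temp_mean <- function(weather, windows, zone = NULL) {
  if (!inherits(windows, "date_window") && is.null(zone))
    stop("zone map required for zone-specific windows")
  tmean <- (weather$tmax + weather$tmin) / 2
  zone_window_stat(tmean, weather$dates, windows, zone, "mean")
}

#' Rainfall coefficient of variation, March-September
#'
#' Ratio (in percent) of the standard deviation of the monthly rainfall
#' sums for March through September to their mean, with month-by-year sums
#' pooled across all years (7 x n_years values per pixel).
#'
#' @param weather a [weather_grid()].
#' @param cv_std `"sample"` (n-1 denominator, default) or `"population"`.
#' @return numeric matrix `[lat, lon]`, percent. Pixels with zero mean
#'   monthly rainfall are undefined and returned as `NaN` (with a warning);
#'   exclude them from modelling.
#' @export
rain_cv <- function(weather, cv_std = c("sample", "population")) {
  cv_std <- match.arg(cv_std)
  ym <- format(weather$dates, "%Y-%m")
  mon <- as.integer(format(weather$dates, "%m"))
  keep <- mon >= 3 & mon <= 9
  groups <- unique(ym[keep])
  nlat <- length(weather$lat); nlon <- length(weather$lon)
  sums <- vapply(groups, function(g) {
    idx <- which(ym == g)
    as.vector(rowSums(weather$precip[, , idx, drop = FALSE], dims = 2))
  }, numeric(nlat * nlon))
  sums <- matrix(sums, nrow = nlat * nlon)  # guard the one-pixel case
  mu <- rowMeans(sums)
  s <- apply(sums, 1, sd)
  if (cv_std == "population") {
    n <- ncol(sums)
    s <- s * sqrt((n - 1) / n)
  }
  cv <- 100 * s / mu
  cv[mu == 0] <- NaN
  if (any(mu == 0))
    warning(sprintf("%d pixel(s) with zero mean monthly rainfall: CV undefined",
                    sum(mu == 0)))
  matrix(cv, nlat, nlon)
}

#' Mean diurnal temperature range, March-September
#'
#' Per pixel, the mean of `tmax - tmin` over all days from 1 March to
#' 30 September, computed per year and averaged across years.
#'
#' @param weather a [weather_grid()].
#' @return numeric matrix `[lat, lon]`, degrees C.
#' @export
diurnal_range <- function(weather) {
  if (any(weather$tmax < weather$tmin, na.rm = TRUE))
    stop("tmax < tmin encountered; rejecting input")
  window_stat_matrix(weather$tmax - weather$tmin, weather$dates,
                     mar_sep_window(), "mean")
}

#' Assemble the eight-predictor variable set
#'
#' Computes all eight biophysical predictors on the weather grid and
#' attaches soil organic carbon unchanged from the study region. Pixels
#' outside the crop mask carry `NA` in every field.
#'
#' @param weather a [weather_grid()].
#' @param region a [study_region()] on the same grid.
#' @param cv_std variance convention for [rain_cv()].
#' @return an object of class `agro_vars`: list with `lat`, `lon`, `mask`
#'   and `vars`, a named list of eight `[lat, lon]` matrices in the order
#'   of [agro_variable_names()].
#' @export
assemble_variables <- function(weather, region,
                               cv_std = c("sample", "population")) {
  if (!same_grid(weather, region))
    stop("weather and region grids do not match")
  zone <- region$zone
  v <- list(
    rain_growing_season = window_rain_sum(weather, growing_season_windows(), zone),
    rain_mar_sep = window_rain_sum(weather, mar_sep_window()),
    rain_sowing_month = window_rain_sum(weather, sowing_windows(), zone),
    rain_cv = rain_cv(weather, cv_std),
    dtr_mar_sep = diurnal_range(weather),
    tmean_growing_season = window_temp_mean(weather, growing_season_windows(), zone),
    tmean_mar_sep = window_temp_mean(weather, mar_sep_window()),
    soil_organic_carbon = region$soil_carbon
  )
  v <- lapply(v, function(m) { m[!region$crop_mask] <- NA_real_; m })
  structure(list(lat = weather$lat, lon = weather$lon,
                 mask = region$crop_mask, vars = v),
            class = "agro_vars")
}

#' @export
print.agro_vars <- function(x, ...) {
  cat(sprintf("<agro_vars> %d x %d pixels, %d masked, %d variables\n",
              length(x$lat), length(x$lon), sum(x$mask), length(x$vars)))
  invisible(x)
}

#' Write an assembled variable set as CSV
#'
#' Long format: one row per masked pixel, one column per predictor.
#'
#' @param vars an `agro_vars` object.
#' @param path output path.
#' @export
write_vars_csv <- function(vars, path) {
  idx <- which(vars$mask)
  df <- data.frame(
    lat = vars$lat[((idx - 1) %% length(vars$lat)) + 1],
    lon = vars$lon[((idx - 1) %/% length(vars$lat)) + 1]
  )
  for (nm in names(vars$vars)) df[[nm]] <- vars$vars[[nm]][idx]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
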