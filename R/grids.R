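# In-memory grid containers.
#
# No raster I/O stack is assumed: grids are plain R structures (matrices
# indexed [lat, lon] and arrays [lat, lon, time]) with explicit coordinate
# vectors, plus a long-format CSV round trip for interchange.

#' Construct a daily weather grid
#'
#' Bundles daily precipitation and min/max temperature fields on a regular
#' lat/lon grid. Arrays are indexed `[lat, lon, day]`.
#'
#' @param dates vector of class `Date`, contiguous daily.
#' @param lat,lon numeric coordinate vectors (degrees), strictly monotone.
#' @param precip,tmax,tmin numeric arrays of dim
#'   `c(length(lat), length(lon), length(dates))`; precipitation in mm/day,
#'   temperatures in degrees C.
#' @return an object of class `weather_grid`.
#' @export
weather_grid <- function(dates, lat, lon, precip, tmax, tmin) {
  dates <- as.Date(dates)
  dm <- c(length(lat), length(lon), length(dates))
  for (nm in c("precip", "tmax", "tmin")) {
    a <- get(nm)
    if (!identical(dim(a), as.integer(dm)))
      stop(sprintf("'%s' must have dim [lat=%d, lon=%d, time=%d]",
                   nm, dm[1], dm[2], dm[3]))
  }
  if (length(dates) > 1 && any(diff(dates) != 1))
    stop("'dates' must be contiguous daily")
  if (any(precip < 0, na.rm = TRUE)) stop("precipitation must be >= 0")
  if (any(tmax < tmin, na.rm = TRUE)) stop("tmax must be >= tmin everywhere")
  structure(
    list(dates = dates, lat = lat, lon = lon,
         precip = precip, tmax = tmax, tmin = tmin),
    class = "weather_grid"
  )
}

#' @export
print.weather_grid <- function(x, ...) {
  cat(sprintf("<weather_grid> %d x %d pixels, %d days (%s to %s)\n",
              length(x$lat), length(x$lon), length(x$dates),
              format(min(x$dates)), format(max(x$dates))))
  invisible(x)
}

#' Construct a study region
#'
#' Static, non-weather layers of the study area: the cropland mask that
#' restricts all analysis, a north/south climatic zone label, a district
#' partition (the spatial unit at which yields are reported) and topsoil
#' organic carbon.
#'
#' @param lat,lon coordinate vectors (degrees).
#' @param crop_mask logical matrix `[lat, lon]`; `TRUE` = cropland.
#' @param zone character matrix `[lat, lon]` with values `"north"`/`"south"`.
#' @param districts integer matrix `[lat, lon]`; district id per pixel
#'   (`NA` allowed off-mask).
#' @param soil_carbon numeric matrix `[lat, lon]`, t/ha, non-negative.
#' @return an object of class `study_region`.
#' @export
study_region <- function(lat, lon, crop_mask, zone, districts, soil_carbon) {
  dm <- c(length(lat), length(lon))
  for (nm in c("crop_mask", "zone", "districts", "soil_carbon")) {
    m <- get(nm)
    if (!identical(dim(m), as.integer(dm)))
      stop(sprintf("'%s' must be a [lat x lon] matrix", nm))
  }
  if (any(soil_carbon < 0, na.rm = TRUE)) stop("soil_carbon must be >= 0")
  bad <- crop_mask & (is.na(districts) | is.na(zone))
  if (any(bad))
    stop("every masked pixel needs a district id and a zone label")
  if (!all(zone[crop_mask] %in% c("north", "south")))
    stop("zone labels must be 'north' or 'south'")
  structure(
    list(lat = lat, lon = lon, crop_mask = crop_mask, zone = zone,
         districts = districts, soil_carbon = soil_carbon),
    class = "study_region"
  )
}

#' @export
print.study_region <- function(x, ...) {
  cat(sprintf(
    "<study_region> %d x %d pixels, %d masked, %d districts\n",
    length(x$lat), length(x$lon), sum(x$crop_mask),
    length(unique(x$districts[x$crop_mask]))))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$lat, b$lat)) && isTRUE(all.equal(a$lon, b$lon))
}

#' Write a gridded field as long-format CSV
#'
#' Plain-text interchange for a single `[lat, lon]` matrix: one row per
#' pixel with columns `lat,lon,value`.
#'
#' @param x numeric matrix `[lat, lon]`.
#' @param lat,lon coordinate vectors.
#' @param path output file path.
#' @export
write_grid_csv <- function(x, lat, lon, path) {
  df <- data.frame(
    lat = rep(lat, times = length(lon)),
    lon = rep(lon, each = length(lat)),
    value = as.vector(x)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a gridded field from long-format CSV
#'
#' Inverse of [write_grid_csv()].
#'
#' @param path CSV with columns `lat,lon,value`.
#' @return list with `lat`, `lon` and matrix `values`.
#' @export
read_grid_csv <- function(path) {
  df <- read.csv(path)
  lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  m <- matrix(NA_real_, length(lat), length(lon))
  m[cbind(match(df$lat, lat), match(df$lon, lon))] <- df$value
  list(lat = lat, lon = lon, values = m)
}
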