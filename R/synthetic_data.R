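# Seeded generators emulating the study inputs: daily gridded weather with a
# north (unimodal, peak ~August) vs south (bimodal, peaks ~May and ~October)
# rainfall climatology, a district partition of a cropland mask, a topsoil
# organic-carbon surface, and district yield series driven by a known
# predictor so that downstream parameter-recovery tests have ground truth.

# Deterministic per-component seed stream derived from one root seed, so
# adding a component never perturbs another component's draws.
derive_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% (2^31 - 2)) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Smooth low-frequency random surface, centred to mean 0, range within [-1, 1].
smooth_field <- function(nlat, nlon) {
  yn <- seq(0, 1, length.out = nlat)
  xn <- seq(0, 1, length.out = nlon)
  f <- matrix(0, nlat, nlon)
  for (k in 1:3) {
    fy <- runif(1, 0.5, 1.5); fx <- runif(1, 0.5, 1.5)
    py <- runif(1); px <- runif(1)
    f <- f + outer(sin(2 * pi * (fy * yn + py)),
                   cos(2 * pi * (fx * xn + px))) / k
  }
  f <- f - mean(f)
  mx <- max(abs(f))
  if (mx > 0) f / mx else f
}

default_axes <- function(nlat, nlon, res = 0.05, lat0 = 4.75, lon0 = -3.25) {
  list(lat = lat0 + res * (seq_len(nlat) - 1),
       lon = lon0 + res * (seq_len(nlon) - 1))
}

#' Default weather-generator parameters
#'
#' The stated world of the synthetic climate: the per-zone March-September
#' rainfall total is calibrated to 1246 mm (the national baseline), the
#' diurnal temperature range to 9.9 degrees C, and the seasonal rainfall
#' kernel is unimodal with an August peak in the north and bimodal with
#' May/October peaks in the south. Spatial heterogeneity enters through
#' independent smooth random surfaces on the rainfall base rate, the
#' rainfall seasonal amplitude and the temperature level, so that derived
#' predictors are correlated but not collinear across pixels.
#'
#' @return named list of generator parameters (amounts in mm/day unless
#'   noted): `mar_sep_target` (mm per season; set `NULL` to specify
#'   `base_rate` and `amp` directly), `base_frac` (share of seasonal rain
#'   from the aseasonal base rate), kernel shape (`north_peak`, `north_sd`,
#'   `south_peaks`, `south_sd`, in day-of-year units), `precip_noise_sd`,
#'   relative spatial amplitudes (`base_spatial`, `amp_spatial`),
#'   temperature level/cycle (`tmean`, `tmean_seasonal_amp`,
#'   `tmean_peak_doy`, `tmean_spatial`, `tmean_lat_gradient`, degrees C),
#'   `temp_noise_sd`, diurnal range `dtr` and `dtr_noise_sd` (degrees C),
#'   and `split_lat` (degrees; `NULL` = grid midpoint).
#' @export
default_weather_params <- function() {
  list(
    mar_sep_target = 1246, base_frac = 0.35,
    north_peak = 227, north_sd = 45,
    south_peaks = c(135, 280), south_sd = 35,
    base_rate = NULL, amp = NULL,
    precip_noise_sd = 1.5, base_spatial = 0.35, amp_spatial = 0.35,
    tmean = 25.5, tmean_seasonal_amp = 1.8, tmean_peak_doy = 75,
    tmean_spatial = 1.0, tmean_lat_gradient = 1.5, temp_noise_sd = 0.8,
    dtr = 9.9, dtr_noise_sd = 1.0,
    split_lat = NULL
  )
}

seasonal_kernel <- function(doy, peaks, sd) {
  k <- rep(0, length(doy))
  for (p in peaks) {
    # wrap-around distance on the annual circle
    d <- pmin(abs(doy - p), 365 - abs(doy - p))
    k <- pmax(k, exp(-0.5 * (d / sd)^2))
  }
  k
}

#' Generate a synthetic daily weather grid
#'
#' Daily precipitation is `max(0, base + amplitude * kernel(doy) + noise)`
#' with a single-peak kernel north of `split_lat` and a two-peak kernel
#' south of it; base and amplitude carry smooth random spatial modulation.
#' Temperatures are a seasonal cycle plus a latitudinal gradient and a
#' smooth surface; `tmax`/`tmin` are reconstructed from daily mean and a
#' positive diurnal range, so `tmax >= tmin` holds by construction. When
#' `mar_sep_target` is set, base and amplitude are calibrated analytically
#' so each zone's expected 1 March - 30 September rainfall total equals it.
#'
#' @param nlat,nlon grid dimensions (positive integers).
#' @param years number of calendar years to simulate (>= 1).
#' @param start_year first calendar year (default 2006).
#' @param zone_params parameter overrides, see [default_weather_params()].
#' @param seed integer root seed; identical arguments and seed give
#'   bit-identical grids.
#' @return a [weather_grid()].
#' @export
generate_weather <- function(nlat, nlon, years = 11, start_year = 2006,
                             zone_params = list(), seed = 1) {
  if (nlat < 1 || nlon < 1) stop("grid dimensions must be positive")
  if (years < 1) stop("'years' must be >= 1")
  p <- utils::modifyList(default_weather_params(), zone_params)
  ax <- default_axes(nlat, nlon)
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + years - 1)), by = "day")
  ntime <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  npix <- nlat * nlon

  split_lat <- if (is.null(p$split_lat)) mean(range(ax$lat)) else p$split_lat
  north <- matrix(rep(ax$lat > split_lat, nlon), nlat, nlon)

  kn <- seasonal_kernel(doy, p$north_peak, p$north_sd)
  ks <- seasonal_kernel(doy, p$south_peaks, p$south_sd)

  # calibrate base/amplitude so the expected Mar-Sep sum hits the target,
  # per zone, on a non-leap reference year
  ref_doy <- 1:365
  in_window <- ref_doy >= 60 & ref_doy <= 273  # 1 Mar - 30 Sep, non-leap
  ndays_w <- sum(in_window)
  if (!is.null(p$mar_sep_target)) {
    base <- p$mar_sep_target * p$base_frac / ndays_w
    sk_n <- sum(seasonal_kernel(ref_doy, p$north_peak, p$north_sd)[in_window])
    sk_s <- sum(seasonal_kernel(ref_doy, p$south_peaks, p$south_sd)[in_window])
    amp_n <- p$mar_sep_target * (1 - p$base_frac) / sk_n
    amp_s <- p$mar_sep_target * (1 - p$base_frac) / sk_s
  } else {
    base <- p$base_rate
    amp_n <- amp_s <- p$amp
    if (is.null(base) || is.null(amp_n))
      stop("set 'mar_sep_target' or both 'base_rate' and 'amp'")
  }

  with_seed(derive_seed(seed, "weather"), {
    bfac <- 1 + p$base_spatial * smooth_field(nlat, nlon)
    afac <- 1 + p$amp_spatial * smooth_field(nlat, nlon)
    tfld <- p$tmean_spatial * smooth_field(nlat, nlon)

    zv <- as.numeric(as.vector(north))
    kmat <- outer(zv, kn) + outer(1 - zv, ks)              # npix x ntime
    ampv <- ifelse(zv > 0, amp_n, amp_s) * as.vector(afac)
    mu <- base * as.vector(bfac) + ampv * kmat
    noise <- if (p$precip_noise_sd > 0)
      matrix(rnorm(npix * ntime, 0, p$precip_noise_sd), npix, ntime)
    else 0
    precip <- pmax(0, mu + noise)
    dim(precip) <- c(nlat, nlon, ntime)

    latn <- (ax$lat - mean(range(ax$lat))) / max(diff(range(ax$lat)), 1e-9)
    tpix <- p$tmean + p$tmean_lat_gradient * latn  # north warmer
    tpix <- matrix(rep(tpix, nlon), nlat, nlon) + tfld
    seas <- p$tmean_seasonal_amp * cos(2 * pi * (doy - p$tmean_peak_doy) / 365)
    tmean <- outer(as.vector(tpix), rep(1, ntime)) +
      outer(rep(1, npix), seas)
    if (p$temp_noise_sd > 0)
      tmean <- tmean + matrix(rnorm(npix * ntime, 0, p$temp_noise_sd), npix, ntime)
    dtr <- p$dtr + if (p$dtr_noise_sd > 0)
      matrix(rnorm(npix * ntime, 0, p$dtr_noise_sd), npix, ntime) else 0
    dtr <- pmax(0.2, dtr)
    tmax <- tmean + dtr / 2
    tmin <- tmean - dtr / 2
    dim(tmax) <- dim(tmin) <- c(nlat, nlon, ntime)

    weather_grid(dates, ax$lat, ax$lon, precip, tmax, tmin)
  })
}

#' Generate a synthetic study region
#'
#' Builds a cropland mask, a north/south zone split at `split_lat`, a
#' contiguous-ish district partition (nearest-seed-pixel Voronoi regions on
#' the grid) and a smooth topsoil organic-carbon surface.
#'
#' @param nlat,nlon grid dimensions.
#' @param n_districts number of districts (>= 4, <= number of masked pixels).
#' @param split_lat latitude of the north/south divide; pixels with
#'   `lat > split_lat` are "north". `NULL` = grid midpoint.
#' @param mask_frac fraction of pixels retained in the crop mask (1 = all).
#' @param soil_mean mean topsoil organic carbon, t/ha.
#' @param soil_spatial relative spatial amplitude of the soil surface.
#' @param seed integer root seed.
#' @return a [study_region()].
#' @export
generate_region <- function(nlat, nlon, n_districts = 40, split_lat = NULL,
                            mask_frac = 1, soil_mean = 30, soil_spatial = 0.4,
                            seed = 1) {
  if (nlat < 1 || nlon < 1) stop("grid dimensions must be positive")
  if (n_districts < 4) stop("'n_districts' must be >= 4")
  ax <- default_axes(nlat, nlon)
  npix <- nlat * nlon
  split_lat <- if (is.null(split_lat)) mean(range(ax$lat)) else split_lat

  with_seed(derive_seed(seed, "region"), {
    mask <- matrix(TRUE, nlat, nlon)
    if (mask_frac < 1) {
      drop <- sample.int(npix, round((1 - mask_frac) * npix))
      mask[drop] <- FALSE
    }
    masked_idx <- which(mask)
    if (n_districts > length(masked_idx))
      stop("'n_districts' exceeds the number of masked pixels")

    seeds <- sort(sample(masked_idx, n_districts))
    ri <- ((masked_idx - 1) %% nlat) + 1
    ci <- ((masked_idx - 1) %/% nlat) + 1
    sr <- ((seeds - 1) %% nlat) + 1
    sc <- ((seeds - 1) %/% nlat) + 1
    d2 <- outer(ri, sr, "-")^2 + outer(ci, sc, "-")^2
    assign_d <- max.col(-d2, ties.method = "first")
    districts <- matrix(NA_integer_, nlat, nlon)
    districts[masked_idx] <- assign_d

    zone <- matrix(ifelse(rep(ax$lat > split_lat, nlon), "north", "south"),
                   nlat, nlon)
    soil <- pmax(soil_mean * (1 + soil_spatial * smooth_field(nlat, nlon)) +
                   matrix(rnorm(npix, 0, 1.5), nlat, nlon), 0)
    study_region(ax$lat, ax$lon, mask, zone, districts, soil)
  })
}

#' Ground-truth specification for synthetic yields
#'
#' Declares which derived predictor drives expected yield, through which
#' monotone response, and with how much interannual noise — the oracle
#' against which downstream classification and importance recovery are
#' judged.
#'
#' @param driver name of one of the eight predictors
#'   (see [agro_variable_names()]).
#' @param response deterministic monotone function mapping the driver value
#'   to expected yield (t/ha). Default scales growing-season rainfall at
#'   roughly 1 t/ha per 200 mm.
#' @param noise_sd interannual yield noise standard deviation (t/ha).
#' @return an object of class `truth_spec`.
#' @export
truth_spec <- function(driver = "rain_growing_season",
                       response = function(x) pmax(0, x / 200),
                       noise_sd = 0.25) {
  if (!driver %in% AGRO_VARIABLES)
    stop(sprintf("unknown driver '%s'", driver))
  structure(list(driver = driver, response = response, noise_sd = noise_sd),
            class = "truth_spec")
}

#' Generate synthetic district yield series
#'
#' District mean yield is the truth response evaluated at the district mean
#' of the driving predictor, plus seeded zero-mean Gaussian interannual
#' noise; with `noise_sd = 0` yields are an exact deterministic function of
#' the driver.
#'
#' @param weather a [weather_grid()].
#' @param region a [study_region()] on the same grid.
#' @param truth a [truth_spec()].
#' @param crop crop name recorded in the table.
#' @param seed integer root seed for the noise stream.
#' @return data.frame with columns `district`, `crop`, `year`, `yield_t_ha`.
#' @export
generate_yields <- function(weather, region, truth = truth_spec(),
                            crop = "maize", seed = 1) {
  stopifnot(inherits(truth, "truth_spec"))
  vars <- assemble_variables(weather, region)
  drv <- vars$vars[[truth$driver]]
  ids <- sort(unique(region$districts[region$crop_mask]))
  dmean <- vapply(ids, function(d) {
    mean(drv[region$crop_mask & !is.na(region$districts) &
               region$districts == d], na.rm = TRUE)
  }, numeric(1))
  expected <- truth$response(dmean)
  yrs <- sort(unique(as.integer(format(weather$dates, "%Y"))))

  with_seed(derive_seed(seed, "yields"), {
    out <- expand.grid(district = ids, year = yrs, KEEP.OUT.ATTRS = FALSE)
    out$crop <- crop
    mu <- expected[match(out$district, ids)]
    eps <- if (truth$noise_sd > 0)
      rnorm(nrow(out), 0, truth$noise_sd) else 0
    out$yield_t_ha <- pmax(0, mu + eps)
    out[, c("district", "crop", "year", "yield_t_ha")]
  })
}

recovery_ranges <- function() {
  list(rain_growing_season = c(600, 1200), rain_mar_sep = c(900, 1500),
       rain_sowing_month = c(150, 350), rain_cv = c(30, 90),
       dtr_mar_sep = c(8, 12), tmean_growing_season = c(23, 27),
       tmean_mar_sep = c(24, 28), soil_organic_carbon = c(10, 50))
}

#' Generate labelled samples with a single known class driver
#'
#' Direct sample design for parameter-recovery tests: one predictor (the
#' driver) determines a latent expected yield through a monotone response;
#' the remaining seven predictors are independent draws carrying no signal.
#' The observed latent value is the response plus Gaussian noise and is cut
#' at the quartiles of the noise-free response distribution, so the class
#' is a noisy monotone function of the driver alone and the Bayes-optimal
#' classifier (and its accuracy) follow in closed form from the known cuts
#' and noise standard deviation.
#'
#' The default `noise_sd` of 0.188 t/ha is calibrated once so that the
#' Bayes accuracy for the default driver is approximately 0.85.
#'
#' @param n number of samples.
#' @param driver the driving predictor (see [agro_variable_names()]).
#' @param noise_sd latent noise standard deviation (t/ha).
#' @param seed integer seed.
#' @return data.frame with the eight predictors and `class` (ordered
#'   factor); attributes `cuts` (latent class boundaries), `mu` (noise-free
#'   latent value per sample), `noise_sd` and `response`.
#' @export
generate_recovery_samples <- function(n, driver = "rain_growing_season",
                                      noise_sd = 0.188, seed = 1) {
  rng <- recovery_ranges()
  if (!driver %in% names(rng)) stop(sprintf("unknown driver '%s'", driver))
  response <- default_response(driver)
  with_seed(derive_seed(seed, "recovery"), {
    df <- as.data.frame(lapply(rng, function(r) runif(n, r[1], r[2])))
    mu <- response(df[[driver]])
    cuts <- response(rng[[driver]][1] +
                       c(0.25, 0.5, 0.75) * diff(rng[[driver]]))
    latent <- mu + rnorm(n, 0, noise_sd)
    rank <- 1L + (latent >= cuts[1]) + (latent >= cuts[2]) +
      (latent >= cuts[3])
    df$class <- class_label(rank)
    structure(df, cuts = cuts, mu = mu, noise_sd = noise_sd,
              response = response)
  })
}

#' Write a yield table to CSV
#'
#' @param yields data.frame as returned by [generate_yields()].
#' @param path output path; header is `district,crop,year,yield_t_ha`.
#' @export
write_yield_csv <- function(yields, path) {
  write.csv(yields[, c("district", "crop", "year", "yield_t_ha")], path,
            row.names = FALSE)
  invisible(path)
}

#' Read a yield table from CSV
#'
#' @param path CSV with columns `district,crop,year,yield_t_ha`.
#' @return data.frame.
#' @export
read_yield_csv <- function(path) {
  df <- read.csv(path)
  need <- c("district", "crop", "year", "yield_t_ha")
  if (!all(need %in% names(df)))
    stop("yield CSV must have columns district,crop,year,yield_t_ha")
  df[, need]
}
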