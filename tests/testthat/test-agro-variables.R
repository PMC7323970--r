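# Derivation of the eight predictors from daily weather.

test_that("window rainfall sums follow calendar day counts", {
  w <- make_weather(2, 2, years = 1)  # 1 mm/day, non-leap 2006
  rs <- make_region(2, 2, zone = "south")
  rn <- make_region(2, 2, zone = "north")

  # south growing window 1 Mar - 30 Jun = 31+30+31+30 = 122 days
  expect_equal(window_rain_sum(w, growing_season_windows(), rs$zone),
               matrix(122, 2, 2))
  # north growing window 24 May - 30 Sep = 8+30+31+31+30 = 130 days
  expect_equal(window_rain_sum(w, growing_season_windows(), rn$zone),
               matrix(130, 2, 2))
  # zonally uniform rain: north/south values differ exactly by day count
  mixed <- rs$zone; mixed[1, ] <- "north"
  v <- window_rain_sum(w, growing_season_windows(), mixed)
  expect_equal(v[1, 1] / v[2, 1], 130 / 122)

  # zero precipitation -> 0
  w0 <- make_weather(2, 2, precip_fun = function(d) rep(0, length(d)))
  expect_equal(window_rain_sum(w0, mar_sep_window()), matrix(0, 2, 2))

  # window outside the data span errors
  wpart <- weather_grid(seq(as.Date("2006-01-01"), as.Date("2006-05-31"), by = "day"),
                        lat = 1, lon = 1,
                        precip = array(1, c(1, 1, 151)),
                        tmax = array(25, c(1, 1, 151)),
                        tmin = array(20, c(1, 1, 151)))
  expect_error(window_rain_sum(wpart, mar_sep_window()), "outside")
})

test_that("sowing windows are 38 days north and 61 days south", {
  w <- make_weather(2, 2, years = 1)
  expect_equal(window_rain_sum(w, sowing_windows(),
                               make_region(2, 2, zone = "north")$zone),
               matrix(38, 2, 2))  # 24 May - 30 Jun
  expect_equal(window_rain_sum(w, sowing_windows(),
                               make_region(2, 2, zone = "south")$zone),
               matrix(61, 2, 2))  # 1 Mar - 30 Apr
})

test_that("rainfall CV matches the direct formula and is scale invariant", {
  # monthly sums 100 (Mar-Aug) and 240 (Sep): set daily rate per month
  rate <- function(d) {
    m <- as.integer(format(d, "%m"))
    nd <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[m]
    ifelse(m == 9, 240 / nd, 100 / nd)
  }
  w <- make_weather(2, 2, years = 1, precip_fun = rate)
  x <- c(rep(100, 6), 240)
  expected <- 100 * sqrt(sum((x - mean(x))^2) / 6) / mean(x)
  expect_equal(rain_cv(w), matrix(expected, 2, 2), tolerance = 1e-10)

  # population variant uses n instead of n-1
  exp_pop <- 100 * sqrt(sum((x - mean(x))^2) / 7) / mean(x)
  expect_equal(rain_cv(w, "population"), matrix(exp_pop, 2, 2),
               tolerance = 1e-10)

  # identical monthly sums -> 0%
  flat <- function(d) {
    m <- as.integer(format(d, "%m"))
    nd <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[m]
    100 / nd
  }
  expect_equal(rain_cv(make_weather(2, 2, precip_fun = flat)),
               matrix(0, 2, 2), tolerance = 1e-10)

  # doubling precipitation leaves CV unchanged
  w2 <- make_weather(2, 2, years = 1, precip_fun = function(d) 2 * rate(d))
  expect_equal(rain_cv(w2), rain_cv(w), tolerance = 1e-10)

  # zero rain -> NaN with warning
  w0 <- make_weather(1, 1, precip_fun = function(d) rep(0, length(d)))
  expect_warning(cv0 <- rain_cv(w0), "undefined")
  expect_true(is.nan(cv0[1, 1]))
})

test_that("diurnal range and temperature means behave as arithmetic says", {
  # tmax = tmin -> 0
  w_eq <- make_weather(2, 2, tmax_fun = function(d) rep(25, length(d)),
                       tmin_fun = function(d) rep(25, length(d)))
  expect_equal(diurnal_range(w_eq), matrix(0, 2, 2))

  # constant offset 9.9
  w99 <- make_weather(2, 2, tmax_fun = function(d) rep(29.9, length(d)),
                      tmin_fun = function(d) rep(20, length(d)))
  expect_equal(diurnal_range(w99), matrix(9.9, 2, 2), tolerance = 1e-12)

  # alternating 8 and 12 over the 214-day window -> 10
  alt <- make_weather(2, 2,
    tmax_fun = function(d) 20 + ifelse(seq_along(d) %% 2 == 0, 8, 12),
    tmin_fun = function(d) rep(20, length(d)))
  expect_equal(diurnal_range(alt), matrix(10, 2, 2))

  # constant 24.5 degC -> 24.5 for any window
  w245 <- make_weather(2, 2, tmax_fun = function(d) rep(24.5, length(d)),
                       tmin_fun = function(d) rep(24.5, length(d)))
  zs <- make_region(2, 2, zone = "south")$zone
  expect_equal(window_temp_mean(w245, growing_season_windows(), zs),
               matrix(24.5, 2, 2))
  expect_equal(window_temp_mean(w245, mar_sep_window()), matrix(24.5, 2, 2))

  # linear ramp -> midpoint of the window; +2.2 shift is equivariant
  ramp <- make_weather(1, 1, tmax_fun = function(d) as.numeric(d - d[1]),
                       tmin_fun = function(d) as.numeric(d - d[1]))
  dates <- seq(as.Date("2006-01-01"), as.Date("2006-12-31"), by = "day")
  win <- dates >= as.Date("2006-03-01") & dates <= as.Date("2006-09-30")
  mid <- mean(as.numeric(dates[win] - dates[1]))
  expect_equal(window_temp_mean(ramp, mar_sep_window())[1, 1], mid)
  ramp2 <- make_weather(1, 1, tmax_fun = function(d) as.numeric(d - d[1]) + 2.2,
                        tmin_fun = function(d) as.numeric(d - d[1]) + 2.2)
  expect_equal(window_temp_mean(ramp2, mar_sep_window())[1, 1], mid + 2.2)
})

test_that("zone dispatch uses the window matching each pixel's zone", {
  # rain only during 1 Mar - 30 Jun; north pixels see only the 24 May-30 Jun
  # overlap (38 days), south pixels the whole 122-day window
  rain <- function(d) {
    y <- format(d, "%Y")
    as.numeric(d >= as.Date(paste0(y, "-03-01")) &
                 d <= as.Date(paste0(y, "-06-30")))
  }
  w <- make_weather(2, 2, precip_fun = rain)
  mixed <- matrix(c("north", "south"), 2, 2)  # row 1 north, row 2 south
  v <- window_rain_sum(w, growing_season_windows(), mixed)
  expect_equal(v[1, ], c(38, 38))
  expect_equal(v[2, ], c(122, 122))
})

test_that("assemble_variables composes the per-variable operations and masks", {
  w <- make_weather(3, 3)
  r <- make_region(3, 3, zone = "south", n_districts = 2, soil = 17)
  r$crop_mask[1, 1] <- FALSE
  v <- assemble_variables(w, r)
  expect_named(v$vars, agro_variable_names())
  expect_equal(v$vars$rain_growing_season[2, 2],
               window_rain_sum(w, growing_season_windows(), r$zone)[2, 2])
  expect_equal(v$vars$soil_organic_carbon[2, 2], 17)
  # masked-out pixel carries NA everywhere
  expect_true(all(sapply(v$vars, function(m) is.na(m[1, 1]))))
  # purity
  expect_identical(assemble_variables(w, r), v)
  # grid mismatch errors
  expect_error(assemble_variables(w, make_region(4, 4)), "do not match")
  # growing season is a sub-window of Mar-Sep
  expect_true(all(v$vars$rain_growing_season[r$crop_mask] <=
                    v$vars$rain_mar_sep[r$crop_mask] + 1e-9))
})
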