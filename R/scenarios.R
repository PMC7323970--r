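# Climate-scenario deltas: additive per-GCM changes to the seven
# climate-derived predictors (soil organic carbon is assumed unchanged),
# applied uniformly in space by default (national deltas) or as gridded
# per-pixel delta rasters.

#' Bundled national climate-change deltas for Ghana
#'
#' Projected mid-century (2041-2050 vs 2006-2016) additive changes in the
#' seven climate-derived predictors, summarized nationally for four
#' bias-adjusted general circulation models (GFDL-ESM2M, IPSL-CM5A-LR,
#' HadGEM2-ES, MIROC-ESM-CHEM) under RCP2.6 and RCP8.5. Rainfall deltas in
#' mm, rainfall CV in percentage points, temperatures in degrees C.
#'
#' Note: in the published summary accompanying these per-model values,
#' four RCP8.5 model-mean cells are inconsistent with the arithmetic mean
#' of the per-model rows; [summarize_deltas()] always recomputes means
#' from the per-model values.
#'
#' @return data.frame in long format: `scenario`, `model`, `variable`,
#'   `delta`.
#' @export
ghana_climate_deltas <- function() {
  vars <- c("rain_mar_sep", "rain_sowing_month", "rain_cv",
            "rain_growing_season", "dtr_mar_sep", "tmean_growing_season",
            "tmean_mar_sep")
  rows <- list(
    c("RCP2.6", "GFDL",    52,    2, -2,  30, -0.4, 1.5, 1.3),
    c("RCP2.6", "IPSL",   -43,    3,  3, -14, -0.2, 1.8, 1.5),
    c("RCP2.6", "HADGEM",  -4,   10,  3,  14, -0.3, 2.2, 1.4),
    c("RCP2.6", "MIROC",   58,   21,  6,  41, -0.4, 1.1, 1.3),
    c("RCP8.5", "GFDL",    59,   27,  3,  40, -0.7, 2.1, 2.5),
    c("RCP8.5", "IPSL",  -117,   -3,  2, -29, -0.1, 2.8, 2.6),
    c("RCP8.5", "HADGEM", -13,   10,  3,   7, -0.5, 1.5, 2.5),
    c("RCP8.5", "MIROC",   86,   21,  2,  51, -0.3, 2.3, 1.8)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(scenario = r[1], model = r[2], variable = vars,
               delta = as.numeric(r[3:9]))
  }))
  rownames(out) <- NULL
  out
}

#' Bundled national baseline climate values for Ghana
#'
#' National 2006-2016 baseline values of the seven climate-derived
#' predictors (same units as [ghana_climate_deltas()]).
#'
#' @return named numeric vector over the seven climate variables.
#' @export
ghana_current_climate <- function() {
  c(rain_mar_sep = 1246, rain_sowing_month = 228, rain_cv = 69,
    rain_growing_season = 558, dtr_mar_sep = 9.9,
    tmean_growing_season = 24.5, tmean_mar_sep = 25.7)
}

# Coerce a delta to a named numeric vector over the seven climate
# variables. Accepts a named vector or a long data.frame filtered to one
# scenario x model.
as_delta_vector <- function(delta) {
  if (is.data.frame(delta)) {
    if (nrow(unique(delta[, intersect(c("scenario", "model"), names(delta)),
                          drop = FALSE])) > 1)
      stop("delta data.frame must cover a single scenario x model")
    delta <- setNames(delta$delta, delta$variable)
  }
  miss <- setdiff(CLIMATE_VARIABLES, names(delta))
  if (length(miss) > 0)
    stop(sprintf("delta missing variable(s): %s", paste(miss, collapse = ", ")))
  extra <- setdiff(names(delta), CLIMATE_VARIABLES)
  if (length(extra) > 0)
    stop(sprintf("delta has unknown variable(s): %s",
                 paste(extra, collapse = ", ")))
  delta[CLIMATE_VARIABLES]
}

#' Apply an additive climate delta to baseline predictors
#'
#' Future variable = baseline + delta for the seven climate-derived
#' variables, applied uniformly in space (or per pixel when `delta` holds
#' matrices). Rainfall amounts and rainfall CV are clipped below at 0;
#' soil organic carbon passes through unchanged.
#'
#' @param baseline an `agro_vars` object.
#' @param delta named numeric vector over the seven climate variables, a
#'   one-scenario/one-model slice of [ghana_climate_deltas()], or a named
#'   list of `[lat, lon]` delta matrices for the gridded mode.
#' @return an `agro_vars` object with shifted climate variables.
#' @export
apply_delta <- function(baseline, delta) {
  stopifnot(inherits(baseline, "agro_vars"))
  gridded <- is.list(delta) && !is.data.frame(delta) &&
    all(vapply(delta, is.matrix, logical(1)))
  if (!gridded) delta <- as_delta_vector(delta)
  out <- baseline
  nonneg <- c("rain_growing_season", "rain_mar_sep", "rain_sowing_month",
              "rain_cv")
  for (nm in CLIMATE_VARIABLES) {
    d <- if (gridded) {
      if (is.null(delta[[nm]])) stop(sprintf("delta missing variable(s): %s", nm))
      delta[[nm]]
    } else delta[[nm]]
    v <- baseline$vars[[nm]] + d
    if (nm %in% nonneg) v <- pmax(v, 0)
    out$vars[[nm]] <- v
  }
  out
}

#' Round half away from zero
#'
#' Reporting-precision rounding for delta summaries (base `round()` uses
#' banker's rounding, which does not reproduce half-up-printed tables).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Summarize per-model deltas into multi-model means
#'
#' Per scenario and variable: the arithmetic mean over models and the
#' number of models agreeing in sign with that mean (zero deltas count as
#' agreeing). Means are returned unrounded; use [round_half_up()] at the
#' desired reporting precision.
#'
#' @param deltas long data.frame as from [ghana_climate_deltas()].
#' @return data.frame with `scenario`, `variable`, `mean_delta`,
#'   `n_models`, `n_agree`.
#' @export
summarize_deltas <- function(deltas) {
  if (nrow(deltas) == 0) stop("empty delta table")
  key <- unique(deltas[, c("scenario", "variable")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    d <- deltas$delta[deltas$scenario == key$scenario[i] &
                        deltas$variable == key$variable[i]]
    m <- mean(d)
    data.frame(scenario = key$scenario[i], variable = key$variable[i],
               mean_delta = m, n_models = length(d),
               n_agree = sum(sign(d) == sign(m) | d == 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
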