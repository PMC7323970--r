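# Yield-percentile suitability classes.
#
# District mean yields over the record are quartered at the 25th/50th/75th
# percentiles of the national district-mean distribution; classes are
# half-open from below with the optimal class closed at the 75th percentile
# (y >= q75), and every crop-masked pixel inherits its district's class.

#' Suitability class levels
#'
#' Ordinal labels from least to most suitable; ranks 1-4 map one-to-one to
#' labels (limited=1, marginal=2, moderate=3, optimal=4).
#' @return character vector of the four labels in rank order.
#' @export
suitability_levels <- function() {
  c("limited", "marginal", "moderate", "optimal")
}

#' Convert between class labels and ranks
#'
#' @param x factor/character labels or integer ranks 1-4.
#' @return `class_rank()` gives integer ranks; `class_label()` gives an
#'   ordered factor.
#' @export
class_rank <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  r <- match(as.character(x), suitability_levels())
  if (anyNA(r) && !anyNA(x)) stop("unknown suitability label")
  r
}

#' @rdname class_rank
#' @export
class_label <- function(x) {
  r <- class_rank(x)
  factor(suitability_levels()[r], levels = suitability_levels(),
         ordered = TRUE)
}

#' District mean yield for one crop
#'
#' Arithmetic mean over the years available per district; districts with
#' missing years are averaged over the remaining years and their year count
#' reported.
#'
#' @param yields data.frame with columns `district`, `crop`, `year`,
#'   `yield_t_ha`.
#' @param crop crop to select.
#' @return data.frame with `district`, `mean_yield`, `n_years`.
#' @export
mean_yield <- function(yields, crop) {
  sub <- yields[yields$crop == crop, , drop = FALSE]
  if (nrow(sub) == 0) stop(sprintf("crop '%s' absent from yield table", crop))
  if (anyDuplicated(sub[, c("district", "year")]))
    stop("more than one record per district x year")
  agg <- aggregate(yield_t_ha ~ district, sub,
                   function(x) c(mean(x), length(x)))
  data.frame(district = agg$district,
             mean_yield = agg$yield_t_ha[, 1],
             n_years = as.integer(agg$yield_t_ha[, 2]))
}

#' Percentile thresholds of district mean yields
#'
#' The 25th, 50th and 75th percentiles of the district-mean yield
#' distribution, computed nationally over all districts.
#'
#' @param mean_yields data.frame from [mean_yield()] (or any frame with a
#'   `mean_yield` column).
#' @param type percentile definition: `"linear"` interpolation between
#'   order statistics (default) or `"nearest"` rank.
#' @return object of class `percentile_thresholds`: list with `q25`, `q50`,
#'   `q75` (t/ha).
#' @export
yield_thresholds <- function(mean_yields, type = c("linear", "nearest")) {
  type <- match.arg(type)
  y <- mean_yields$mean_yield
  y <- y[is.finite(y)]
  if (length(y) < 4) stop("need at least 4 districts with finite mean yields")
  qt <- quantile(y, c(0.25, 0.5, 0.75),
                 type = if (type == "linear") 7 else 1, names = FALSE)
  structure(list(q25 = qt[1], q50 = qt[2], q75 = qt[3]),
            class = "percentile_thresholds")
}

#' @export
print.percentile_thresholds <- function(x, ...) {
  cat(sprintf("<percentile_thresholds> q25=%.3f q50=%.3f q75=%.3f t/ha\n",
              x$q25, x$q50, x$q75))
  invisible(x)
}

#' Assign suitability classes from mean yields
#'
#' limited if `y < q25`; marginal if `q25 <= y < q50`; moderate if
#' `q50 <= y < q75`; optimal if `y >= q75`.
#'
#' @param y numeric vector of mean yields (t/ha); `NA` is an error.
#' @param thresholds a [yield_thresholds()] object.
#' @return ordered factor of suitability labels.
#' @export
assign_class <- function(y, thresholds) {
  stopifnot(inherits(thresholds, "percentile_thresholds"))
  if (anyNA(y)) stop("NA yield cannot be classed")
  r <- 1L + (y >= thresholds$q25) + (y >= thresholds$q50) +
    (y >= thresholds$q75)
  class_label(r)
}

#' Rasterize district classes to pixels
#'
#' Every crop-masked pixel inherits its district's suitability class;
#' pixels outside the mask are `NA`.
#'
#' @param district_classes data.frame with columns `district` and `class`
#'   (labels or ranks).
#' @param region a [study_region()].
#' @return integer matrix `[lat, lon]` of ranks 1-4, `NA` off-mask.
#' @export
rasterize_labels <- function(district_classes, region) {
  ranks <- class_rank(district_classes$class)
  ids <- region$districts[region$crop_mask]
  miss <- setdiff(unique(ids), district_classes$district)
  if (length(miss) > 0)
    stop(sprintf("district(s) without a class: %s",
                 paste(miss, collapse = ", ")))
  out <- matrix(NA_integer_, length(region$lat), length(region$lon))
  out[region$crop_mask] <-
    ranks[match(ids, district_classes$district)]
  out
}

#' Class districts for one crop
#'
#' Convenience wrapper: district mean yields, national percentile
#' thresholds, and per-district class assignment in one step.
#'
#' @inheritParams mean_yield
#' @param type percentile definition, see [yield_thresholds()].
#' @return list with `means` (data.frame), `thresholds`
#'   ([yield_thresholds()]) and `classes` (data.frame `district`, `class`).
#' @export
class_districts <- function(yields, crop, type = c("linear", "nearest")) {
  means <- mean_yield(yields, crop)
  thr <- yield_thresholds(means, type)
  cls <- data.frame(district = means$district,
                    class = assign_class(means$mean_yield, thr))
  list(means = means, thresholds = thr, classes = cls)
}
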