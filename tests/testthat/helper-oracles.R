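# Independent brute-force oracles and small fixture builders.

# Constant-or-function weather fixture on a tiny grid. `precip_fun` etc.
# take the Date vector and return per-day values (recycled over pixels).
make_weather <- function(nlat = 2, nlon = 2, years = 1, start_year = 2006,
                         precip_fun = function(d) rep(1, length(d)),
                         tmax_fun = function(d) rep(30, length(d)),
                         tmin_fun = function(d) rep(20, length(d))) {
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + years - 1)),
               by = "day")
  nt <- length(dates)
  lat <- 4.75 + 0.05 * (seq_len(nlat) - 1)
  lon <- -3.25 + 0.05 * (seq_len(nlon) - 1)
  mk <- function(f) {
    a <- aperm(array(f(dates), c(nt, nlat, nlon)), c(2, 3, 1))
    a
  }
  weather_grid(dates, lat, lon, mk(precip_fun), mk(tmax_fun), mk(tmin_fun))
}

# Uniform single-zone region matching make_weather's grid.
make_region <- function(nlat = 2, nlon = 2, zone = "south", n_districts = 1,
                        soil = 30) {
  lat <- 4.75 + 0.05 * (seq_len(nlat) - 1)
  lon <- -3.25 + 0.05 * (seq_len(nlon) - 1)
  npix <- nlat * nlon
  districts <- matrix(rep_len(seq_len(n_districts), npix), nlat, nlon)
  study_region(lat, lon,
               crop_mask = matrix(TRUE, nlat, nlon),
               zone = matrix(zone, nlat, nlon),
               districts = districts,
               soil_carbon = matrix(soil, nlat, nlon))
}

# Brute-force one-vs-rest tally from a confusion matrix: expand to label
# vectors and count TP/FP/TN/FN per class by looping over samples.
oracle_per_class <- function(cm) {
  classes <- rownames(cm)
  ref <- pred <- character(0)
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    ref <- c(ref, rep(classes[i], cm[i, j]))
    pred <- c(pred, rep(classes[j], cm[i, j]))
  }
  n <- length(ref)
  out <- lapply(classes, function(k) {
    tp <- fp <- tn <- fn <- 0
    for (s in seq_len(n)) {
      if (ref[s] == k && pred[s] == k) tp <- tp + 1
      else if (ref[s] != k && pred[s] == k) fp <- fp + 1
      else if (ref[s] == k && pred[s] != k) fn <- fn + 1
      else tn <- tn + 1
    }
    dv <- function(a, b) if (b == 0) NaN else a / b
    sens <- dv(tp, tp + fn); spec <- dv(tn, tn + fp)
    ppv <- dv(tp, tp + fp)
    c(sensitivity = sens, specificity = spec, pos_pred_value = ppv,
      neg_pred_value = dv(tn, tn + fn), precision = ppv, recall = sens,
      f1 = if (is.nan(ppv) || is.nan(sens) || ppv + sens == 0) NaN
           else 2 * ppv * sens / (ppv + sens),
      prevalence = (tp + fn) / n, detection_rate = tp / n,
      detection_prevalence = (tp + fp) / n,
      balanced_accuracy = (sens + spec) / 2)
  })
  do.call(rbind, out)
}

# Exhaustive pairwise rank-statistic multiclass AUC: for each unordered
# class pair, count over all cross-class sample pairs.
oracle_multiclass_auc <- function(reference, scores) {
  classes <- colnames(scores)
  present <- classes[classes %in% reference]
  pairs <- combn(present, 2, simplify = FALSE)
  a_one <- function(ci, cj) {
    si <- scores[reference == ci, ci]
    sj <- scores[reference == cj, ci]
    tot <- 0
    for (a in si) for (b in sj)
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    tot / (length(si) * length(sj))
  }
  mean(vapply(pairs, function(p) (a_one(p[1], p[2]) + a_one(p[2], p[1])) / 2,
              numeric(1)))
}

random_confusion <- function(k = 4, max_count = 20) {
  m <- matrix(sample.int(max_count + 1, k * k, replace = TRUE) - 1L, k, k)
  if (sum(m) == 0) m[1, 1] <- 1L
  dimnames(m) <- list(reference = letters[1:k], predicted = letters[1:k])
  m
}

# Random rank maps sharing a mask, for multi-crop algebra tests.
random_rank_maps <- function(n_maps, nlat = 8, nlon = 8, p_na = 0.2) {
  mask <- matrix(runif(nlat * nlon) > p_na, nlat, nlon)
  lapply(seq_len(n_maps), function(i) {
    m <- matrix(sample(1:4, nlat * nlon, replace = TRUE), nlat, nlon)
    m[!mask] <- NA
    m
  })
}
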