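# Suitability modelling: sample construction, stratified splitting,
# cross-validated tuning of the boosted-tree classifier, and gridded
# prediction. One independent model per crop over the identical
# eight-predictor set.

#' Build labelled training samples from gridded predictors and labels
#'
#' One row per crop-masked pixel with complete predictor values; pixels
#' with any undefined predictor (e.g. rainfall CV at zero-rain pixels) are
#' dropped and counted.
#'
#' @param vars an `agro_vars` object from [assemble_variables()].
#' @param label_map integer matrix of class ranks from [rasterize_labels()].
#' @return data.frame with `pixel` (linear index), the eight predictors and
#'   `class` (ordered factor); attribute `n_dropped` counts pixels removed
#'   for missing predictors.
#' @export
build_samples <- function(vars, label_map) {
  idx <- which(vars$mask & !is.na(label_map))
  df <- data.frame(pixel = idx)
  for (nm in names(vars$vars)) df[[nm]] <- vars$vars[[nm]][idx]
  df$class <- class_label(label_map[idx])
  keep <- stats::complete.cases(df[, names(vars$vars)])
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Stratified random train/test split
#'
#' Splits samples into a model-fitting set and an independent test set,
#' stratified by class so every class appears on both sides (the fitting
#' fraction is applied within each class, with rounding).
#'
#' @param samples data.frame with a `class` column.
#' @param fraction fitting-set fraction, strictly between 0 and 1
#'   (default 0.7).
#' @param seed integer seed; identical seeds give identical splits.
#' @param stratify stratify by class (default `TRUE`); if `FALSE`, a simple
#'   random split.
#' @return list with data.frames `fit` and `test` (disjoint, exhaustive).
#' @export
split_samples <- function(samples, fraction = 0.7, seed = 1,
                          stratify = TRUE) {
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  cls <- as.character(samples$class)
  tab <- table(cls)
  if (any(tab < 2))
    stop("every class needs at least 2 samples to split")
  with_seed(derive_seed(seed, "split"), {
    if (stratify) {
      in_fit <- logical(nrow(samples))
      for (k in names(tab)) {
        rows <- which(cls == k)
        n_fit <- min(max(round(fraction * length(rows)), 1L),
                     length(rows) - 1L)
        in_fit[sample(rows, n_fit)] <- TRUE
      }
    } else {
      n_fit <- min(max(round(fraction * nrow(samples)), 1L),
                   nrow(samples) - 1L)
      in_fit <- logical(nrow(samples))
      in_fit[sample.int(nrow(samples), n_fit)] <- TRUE
    }
    list(fit = samples[in_fit, , drop = FALSE],
         test = samples[!in_fit, , drop = FALSE])
  })
}

#' Default hyperparameter tuning grid
#'
#' Boosting rounds x maximum depth x learning rate. The learning rate
#' stands in as the third tuning axis alongside rounds and depth (it is the
#' standard shrinkage parameter of boosted trees).
#'
#' @return data.frame with columns `nrounds`, `max_depth`, `eta`.
#' @export
default_tuning_grid <- function() {
  expand.grid(nrounds = c(50L, 100L, 200L), max_depth = c(2L, 4L, 6L),
              eta = c(0.05, 0.1, 0.3), KEEP.OUT.ATTRS = FALSE)
}

cv_folds <- function(cls, nfolds) {
  fold <- integer(length(cls))
  for (k in unique(cls)) {
    rows <- which(cls == k)
    fold[rows] <- sample(rep_len(seq_len(nfolds), length(rows)))
  }
  fold
}

#' Tune and fit the suitability classifier
#'
#' Stratified k-fold cross-validated grid search over boosting rounds, tree
#' depth and learning rate, scored by accuracy; the best setting (ties
#' resolved to the first grid row) is refit on the full fitting set.
#'
#' @param fit_samples data.frame from [split_samples()]`$fit` (must contain
#'   the eight predictors and `class`).
#' @param grid tuning grid, see [default_tuning_grid()].
#' @param nfolds number of cross-validation folds (default 5).
#' @param seed integer seed controlling fold assignment.
#' @param features predictor column names (default [agro_variable_names()]).
#' @param lambda,min_child_weight regularization passed to [gbt_fit()].
#' @return object of class `suitability_model`: the fitted `gbt` booster,
#'   the chosen settings, the full cross-validation table, feature and
#'   class order, and the seed.
#' @export
tune_and_fit <- function(fit_samples, grid = default_tuning_grid(),
                         nfolds = 5, seed = 1,
                         features = agro_variable_names(),
                         lambda = 1, min_child_weight = 1) {
  if (nrow(fit_samples) == 0) stop("empty fitting set")
  y <- class_label(fit_samples$class)
  y <- droplevels(factor(as.character(y), levels = suitability_levels()))
  if (nlevels(y) < 2) stop("degenerate single-class fitting set")
  x <- as.matrix(fit_samples[, features, drop = FALSE])

  cv <- grid
  cv$accuracy <- NA_real_
  with_seed(derive_seed(seed, "cv"), {
    fold <- cv_folds(as.character(y), nfolds)
    for (i in seq_len(nrow(grid))) {
      correct <- 0L
      for (f in seq_len(nfolds)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2) next
        m <- gbt_fit(x[tr, , drop = FALSE], y[tr],
                     nrounds = grid$nrounds[i], max_depth = grid$max_depth[i],
                     eta = grid$eta[i], lambda = lambda,
                     min_child_weight = min_child_weight)
        pr <- predict(m, x[!tr, , drop = FALSE])
        correct <- correct + sum(pr == y[!tr])
      }
      cv$accuracy[i] <- correct / length(y)
    }
  })
  best <- which.max(cv$accuracy)  # first max: deterministic tie-break
  booster <- gbt_fit(x, y, nrounds = grid$nrounds[best],
                     max_depth = grid$max_depth[best], eta = grid$eta[best],
                     lambda = lambda, min_child_weight = min_child_weight)
  structure(
    list(booster = booster, settings = grid[best, , drop = FALSE],
         cv = cv, features = features, classes = booster$classes,
         seed = seed),
    class = "suitability_model"
  )
}

#' @export
print.suitability_model <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "<suitability_model> %d classes; rounds=%d depth=%d eta=%g (cv acc %.3f)\n",
    length(x$classes), s$nrounds, s$max_depth, s$eta,
    max(x$cv$accuracy, na.rm = TRUE)))
  invisible(x)
}

#' @export
predict.suitability_model <- function(object, newdata, ...) {
  predict(object$booster, newdata, ...)
}

#' Predict a suitability map from gridded predictors
#'
#' Applies the fitted classifier to every masked pixel with complete
#' predictors; returns the per-pixel class rank (argmax) and one
#' probability layer per class (summing to 1 per pixel).
#'
#' @param model a [tune_and_fit()] model.
#' @param vars an `agro_vars` object (must contain the training features).
#' @param mask optional logical matrix restricting prediction (default:
#'   the variable set's crop mask).
#' @return object of class `suitability_map`: list with `rank` (integer
#'   matrix, `NA` off-mask), `prob` (named list of matrices) and `mask`.
#' @export
predict_map <- function(model, vars, mask = NULL) {
  if (is.null(mask)) mask <- vars$mask
  missing_feat <- setdiff(model$features, names(vars$vars))
  if (length(missing_feat) > 0)
    stop(sprintf("missing predictor band(s): %s",
                 paste(missing_feat, collapse = ", ")))
  xmat <- sapply(model$features, function(nm) vars$vars[[nm]][mask])
  if (!is.matrix(xmat)) xmat <- matrix(xmat, nrow = 1)
  ok <- stats::complete.cases(xmat)
  prob <- predict(model$booster, xmat[ok, , drop = FALSE], type = "prob")
  cls <- max.col(prob, ties.method = "first")

  nlat <- length(vars$lat); nlon <- length(vars$lon)
  rank_m <- matrix(NA_integer_, nlat, nlon)
  pix <- which(mask)[ok]
  rank_m[pix] <- match(model$classes[cls], suitability_levels())
  prob_l <- lapply(seq_along(model$classes), function(k) {
    m <- matrix(NA_real_, nlat, nlon)
    m[pix] <- prob[, k]
    m
  })
  names(prob_l) <- model$classes
  structure(list(rank = rank_m, prob = prob_l, mask = mask),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("<suitability_map> %d x %d pixels, %d labelled\n",
              nrow(x$rank), ncol(x$rank), sum(!is.na(x$rank))))
  invisible(x)
}

#' Serialize / restore a fitted suitability model
#'
#' Single self-describing file (RDS) holding the ensemble, tuned settings,
#' feature order, class order and seed.
#'
#' @param model a `suitability_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "suitability_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "suitability_model")) stop("not a suitability model file")
  m
}
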