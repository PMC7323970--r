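# R interface to the Rcpp multiclass boosted-tree learner.
#
# This is a from-scratch implementation of second-order gradient boosting
# with the softmax objective: per boosting round one depth-limited
# regression tree per class is fit to the loss gradients, exactly as in
# extreme-gradient-boosting practice (leaf weight -G/(H+lambda), gain-based
# exact greedy splits, shrinkage). Split gains are accumulated per feature
# and drive gain importance.

#' Fit a multiclass boosted-tree classifier
#'
#' @param x numeric matrix or data.frame of predictors (no missing values).
#' @param y factor of class labels (>= 2 levels present).
#' @param nrounds number of boosting rounds (trees per class).
#' @param max_depth maximum tree depth.
#' @param eta learning rate (shrinkage) applied to every leaf weight.
#' @param lambda L2 regularization on leaf weights.
#' @param min_child_weight minimum hessian sum per leaf.
#' @return an object of class `gbt`: the tree ensemble, per-feature raw
#'   split gains, class levels and feature names.
#' @export
gbt_fit <- function(x, y, nrounds = 100, max_depth = 4, eta = 0.1,
                    lambda = 1, min_child_weight = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("predictors must not contain missing values")
  y <- as.factor(y)
  classes <- levels(y)
  yi <- as.integer(y) - 1L
  if (length(unique(yi)) < 2)
    stop("degenerate single-class training set")
  fit <- gbt_fit_cpp(x, yi, length(classes), as.integer(nrounds),
                     as.integer(max_depth), eta, lambda, min_child_weight)
  structure(
    list(trees = fit$trees,
         gain = setNames(as.numeric(fit$gain), colnames(x)),
         classes = classes, features = colnames(x),
         params = list(nrounds = nrounds, max_depth = max_depth, eta = eta,
                       lambda = lambda, min_child_weight = min_child_weight)),
    class = "gbt"
  )
}

#' Predict from a boosted-tree classifier
#'
#' @param object a [gbt_fit()] model.
#' @param newdata matrix or data.frame with the training feature columns.
#' @param type `"class"` (argmax label), `"prob"` (softmax probabilities,
#'   rows sum to 1) or `"raw"` (additive margins).
#' @param ... unused.
#' @return factor, or numeric matrix with one column per class.
#' @export
predict.gbt <- function(object, newdata, type = c("class", "prob", "raw"),
                        ...) {
  type <- match.arg(type)
  newdata <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  storage.mode(newdata) <- "double"
  if (anyNA(newdata)) stop("missing predictor values in 'newdata'")
  f <- gbt_margin_cpp(object$trees, newdata, length(object$classes))
  colnames(f) <- object$classes
  if (type == "raw") return(f)
  p <- exp(f - apply(f, 1, max))
  p <- p / rowSums(p)
  if (type == "prob") return(p)
  factor(object$classes[max.col(p, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.gbt <- function(x, ...) {
  cat(sprintf("<gbt> %d classes x %d rounds (depth %d, eta %g), %d features\n",
              length(x$classes), x$params$nrounds, x$params$max_depth,
              x$params$eta, length(x$features)))
  invisible(x)
}
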