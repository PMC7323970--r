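# Confusion-matrix evaluation metrics from first principles: overall
# accuracy, chance-corrected kappa, pairwise-average (Hand-Till) multiclass
# AUC, and eleven one-vs-rest per-class statistics. Undefined ratios (zero
# denominators) are reported as NaN, never silently as 0.

#' Confusion matrix of reference vs predicted labels
#'
#' Rows are the reference class, columns the modelled class, in a fixed
#' class order.
#'
#' @param reference,predicted equal-length label vectors.
#' @param levels class order; defaults to the union of observed labels. A
#'   label outside this set is an error.
#' @return K x K integer matrix of counts with named dimnames.
#' @export
confusion_matrix <- function(reference, predicted, levels = NULL) {
  reference <- as.character(reference)
  predicted <- as.character(predicted)
  if (length(reference) != length(predicted))
    stop("label vectors must have equal length")
  if (is.null(levels)) levels <- sort(unique(c(reference, predicted)))
  if (!all(c(reference, predicted) %in% levels))
    stop("label outside the class set")
  m <- table(factor(reference, levels), factor(predicted, levels))
  out <- matrix(as.integer(m), nrow(m), ncol(m),
                dimnames = list(reference = levels, predicted = levels))
  out
}

#' Overall accuracy
#'
#' Trace of the confusion matrix divided by the total count.
#'
#' @param cm square confusion matrix (rows = reference).
#' @return fraction in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Kappa coefficient
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o` (the overall accuracy) and expected-by-chance agreement
#' `p_e = sum_c row_c * col_c / total^2`; ranges from -1 (systematic
#' disagreement) to 1 (perfect). When `p_e = 1` the ratio is undefined:
#' 1 is returned if agreement is perfect, otherwise 0 with a warning.
#'
#' @param cm square confusion matrix.
#' @return kappa in `[-1, 1]`.
#' @export
kappa_coefficient <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (pe >= 1) {
    if (po == 1) return(1)
    warning("expected agreement is 1; kappa undefined, returning 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

# Two-class rank-statistic AUC of scores s for positives vs negatives;
# ties count 0.5 (midrank construction).
binary_auc <- function(s, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  r <- rank(s)  # midranks handle ties as 0.5
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pairwise-average multiclass AUC (Hand-Till)
#'
#' For each unordered class pair (i, j), restricted to samples of those two
#' classes, `A(i|j)` is the two-class AUC of the class-i score and the pair
#' AUC is `(A(i|j) + A(j|i)) / 2`; the multiclass AUC is the mean over all
#' pairs. Score ties count 0.5.
#'
#' @param reference label vector.
#' @param scores numeric matrix, one probability/score column per class
#'   (column names are the class set).
#' @return AUC in `[0, 1]`.
#' @export
multiclass_auc <- function(reference, scores) {
  scores <- as.matrix(scores)
  classes <- colnames(scores)
  if (is.null(classes)) stop("'scores' needs class column names")
  reference <- as.character(reference)
  if (length(reference) != nrow(scores))
    stop("one score row per sample required")
  present <- intersect(classes, unique(reference))
  if (length(present) < 2) stop("need at least 2 classes present")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  aucs <- vapply(pairs, function(p) {
    sel <- reference %in% p
    if (!all(p %in% reference[sel]))
      stop(sprintf("class pair (%s, %s) has a missing class", p[1], p[2]))
    ref <- reference[sel]
    a_ij <- binary_auc(scores[sel, p[1]], ref == p[1])
    a_ji <- binary_auc(scores[sel, p[2]], ref == p[2])
    (a_ij + a_ji) / 2
  }, numeric(1))
  mean(aucs)
}

#' Per-class one-vs-rest metrics
#'
#' Binarizes the confusion matrix per class and reports sensitivity,
#' specificity, positive/negative prediction value, precision, recall,
#' F1-score, prevalence, detection rate, detection prevalence and balanced
#' accuracy. Zero-denominator ratios are `NaN`; the attribute
#' `n_undefined` counts affected classes.
#'
#' @param cm square confusion matrix (rows = reference).
#' @return data.frame, one row per class, eleven metric columns.
#' @export
per_class_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  div <- function(a, b) ifelse(b == 0, NaN, a / b)
  rows <- lapply(seq_along(classes), function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    sens <- div(tp, tp + fn)
    spec <- div(tn, tn + fp)
    ppv <- div(tp, tp + fp)
    npv <- div(tn, tn + fn)
    f1 <- div(2 * ppv * sens, ppv + sens)
    data.frame(
      class = classes[k],
      sensitivity = sens, specificity = spec,
      pos_pred_value = ppv, neg_pred_value = npv,
      precision = ppv, recall = sens, f1 = f1,
      prevalence = (tp + fn) / total,
      detection_rate = tp / total,
      detection_prevalence = (tp + fp) / total,
      balanced_accuracy = (sens + spec) / 2
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  metric_cols <- setdiff(names(out), "class")
  attr(out, "n_undefined") <-
    sum(apply(is.nan(as.matrix(out[, metric_cols])), 1, any))
  out
}

#' Full evaluation report for one crop
#'
#' @param reference,predicted label vectors (held-out reference and model
#'   prediction).
#' @param scores optional probability matrix for the multiclass AUC.
#' @param levels class order for the confusion matrix.
#' @return list with `confusion`, `overall` (data.frame `oa`, `kappa`,
#'   `auc`) and `per_class`.
#' @export
metrics_report <- function(reference, predicted, scores = NULL,
                           levels = NULL) {
  cm <- confusion_matrix(reference, predicted, levels)
  overall <- data.frame(
    oa = overall_accuracy(cm),
    kappa = kappa_coefficient(cm),
    auc = if (is.null(scores)) NA_real_ else multiclass_auc(reference, scores)
  )
  list(confusion = cm, overall = overall, per_class = per_class_metrics(cm))
}
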