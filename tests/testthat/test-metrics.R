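# Confusion-matrix metrics against brute-force oracles.

test_that("confusion matrix counts reference x predicted pairs", {
  cm <- confusion_matrix(c("A", "B", "B"), c("A", "A", "B"), c("A", "B"))
  expect_equal(cm["A", "A"], 1L)
  expect_equal(cm["B", "A"], 1L)
  expect_equal(cm["B", "B"], 1L)
  expect_equal(cm["A", "B"], 0L)
  expect_equal(overall_accuracy(cm), 2 / 3)

  # perfect prediction -> identity diagonal
  cmp <- confusion_matrix(1:4, 1:4)
  expect_equal(diag(cmp), setNames(rep(1L, 4), as.character(1:4)))
  expect_equal(overall_accuracy(cmp), 1)

  # order invariance
  set.seed(1)
  ref <- sample(letters[1:4], 50, replace = TRUE)
  pred <- sample(letters[1:4], 50, replace = TRUE)
  perm <- sample(50)
  expect_identical(confusion_matrix(ref, pred, letters[1:4]),
                   confusion_matrix(ref[perm], pred[perm], letters[1:4]))

  expect_error(confusion_matrix("A", "C", levels = c("A", "B")), "outside")
  expect_error(confusion_matrix(c("A", "B"), "A"), "equal length")
})

test_that("kappa reproduces its defining cases", {
  expect_equal(kappa_coefficient(diag(3) * 5), 1)
  m <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(kappa_coefficient(m), 0)
  expect_equal(kappa_coefficient(matrix(c(0, 2, 2, 0), 2, 2)), -1)
  # all-off-diagonal accuracy 0
  expect_equal(overall_accuracy(matrix(c(0, 2, 2, 0), 2, 2)), 0)
  expect_error(kappa_coefficient(matrix(0, 2, 2)), "empty")
})

test_that("per-class metrics equal the brute-force one-vs-rest tally", {
  set.seed(11)
  for (i in 1:40) {
    cm <- random_confusion(4)
    got <- per_class_metrics(cm)
    want <- oracle_per_class(cm)
    for (col in colnames(want))
      expect_equal(got[[col]], unname(want[, col]), tolerance = 1e-12,
                   label = sprintf("metric %s (rep %d)", col, i))
  }
})

test_that("per-class metrics handle absent predictions and perfect diagonals", {
  # class never predicted: PPV undefined (NaN), sensitivity 0
  cm <- confusion_matrix(c("a", "a", "b"), c("b", "b", "b"), c("a", "b"))
  pm <- per_class_metrics(cm)
  expect_true(is.nan(pm$pos_pred_value[pm$class == "a"]))
  expect_equal(pm$sensitivity[pm$class == "a"], 0)
  expect_gte(attr(pm, "n_undefined"), 1)

  pmp <- per_class_metrics(diag(4) * 3)
  expect_true(all(pmp$sensitivity == 1 & pmp$specificity == 1 & pmp$f1 == 1))
})

test_that("OA decomposes as prevalence-weighted sensitivity; kappa bounds hold", {
  set.seed(12)
  for (i in 1:40) {
    cm <- random_confusion(sample(2:5, 1))
    pm <- per_class_metrics(cm)
    sens <- ifelse(is.nan(pm$sensitivity), 0, pm$sensitivity)
    expect_equal(overall_accuracy(cm), sum(pm$prevalence * sens),
                 tolerance = 1e-12)
    oa <- overall_accuracy(cm)
    pe <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
    if (pe > 0 && pe < 1 && oa < 1)
      expect_lte(kappa_coefficient(cm), oa + 1e-12)
    off <- sum(cm) - sum(diag(cm))
    expect_equal(isTRUE(all.equal(kappa_coefficient(cm), 1)), off == 0)
  }
})

test_that("multiclass AUC equals the exhaustive pairwise oracle", {
  set.seed(13)
  for (i in 1:30) {
    k <- sample(3:4, 1)
    n <- sample(8:20, 1)
    ref <- sample(letters[1:k], n, replace = TRUE)
    while (length(unique(ref)) < k) ref <- sample(letters[1:k], n, replace = TRUE)
    scores <- matrix(runif(n * k), n, k, dimnames = list(NULL, letters[1:k]))
    # inject ties sometimes
    if (i %% 3 == 0) scores <- round(scores, 1)
    expect_equal(multiclass_auc(ref, scores),
                 oracle_multiclass_auc(ref, scores), tolerance = 1e-12)
  }
})

test_that("multiclass AUC hits its boundary values and monotone invariance", {
  ref <- rep(c("a", "b", "c"), each = 2)
  perfect <- matrix(0, 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  perfect[cbind(1:6, match(ref, c("a", "b", "c")))] <- 1
  expect_equal(multiclass_auc(ref, perfect), 1)

  flat <- matrix(1 / 3, 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(multiclass_auc(ref, flat), 0.5)

  set.seed(14)
  scores <- matrix(runif(18), 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(multiclass_auc(ref, exp(5 * scores)),
               multiclass_auc(ref, scores), tolerance = 1e-12)

  expect_error(multiclass_auc(rep("a", 6), perfect), "2 classes")
})

test_that("random uniform predictions are chance-level (seeded calibration)", {
  set.seed(2024)
  n <- 10000
  ref <- sample(suitability_levels(), n, replace = TRUE)
  pred <- sample(suitability_levels(), n, replace = TRUE)
  cm <- confusion_matrix(ref, pred, suitability_levels())
  expect_lt(abs(kappa_coefficient(cm)), 0.03)
  raw <- matrix(rexp(n * 4), n, 4, dimnames = list(NULL, suitability_levels()))
  scores <- raw / rowSums(raw)
  expect_lt(abs(multiclass_auc(ref, scores) - 0.5), 0.02)
})

test_that("metrics_report bundles the pieces consistently", {
  set.seed(15)
  ref <- sample(c("x", "y"), 30, replace = TRUE)
  pred <- sample(c("x", "y"), 30, replace = TRUE)
  scores <- matrix(runif(60), 30, 2, dimnames = list(NULL, c("x", "y")))
  rep <- metrics_report(ref, pred, scores)
  expect_equal(rep$overall$oa, overall_accuracy(rep$confusion))
  expect_equal(rep$overall$kappa, kappa_coefficient(rep$confusion))
  expect_equal(rep$overall$auc, multiclass_auc(ref, scores))
  expect_equal(nrow(rep$per_class), 2)
})
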