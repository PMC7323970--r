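# Boosted-tree learner, splitting, tuning and gridded prediction.

test_that("stratified split has the right sizes, proportions and determinism", {
  set.seed(21)
  samples <- data.frame(x = rnorm(1000),
                        class = sample(suitability_levels(), 1000,
                                       replace = TRUE, prob = c(.4, .3, .2, .1)))
  parts <- split_samples(samples, 0.7, seed = 5)
  expect_equal(nrow(parts$fit) + nrow(parts$test), 1000)
  expect_equal(nrow(parts$fit), 700, tolerance = 0.003)  # within rounding
  expect_length(intersect(rownames(parts$fit), rownames(parts$test)), 0)
  # per-class fit counts within 1 of fraction * class size
  for (k in unique(samples$class)) {
    nk <- sum(samples$class == k)
    expect_lte(abs(sum(parts$fit$class == k) - 0.7 * nk), 1)
  }
  # determinism
  parts2 <- split_samples(samples, 0.7, seed = 5)
  expect_identical(parts, parts2)
  expect_false(identical(parts, split_samples(samples, 0.7, seed = 6)))

  expect_error(split_samples(samples, 1.2), "fraction")
  expect_error(split_samples(data.frame(class = c("a", "a", "b")), 0.5),
               "at least 2")
})

test_that("the booster fits separable classes perfectly and is deterministic", {
  set.seed(22)
  n <- 300
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- factor(cut(x[, 2], c(-Inf, -0.5, 0.5, Inf), labels = c("lo", "mid", "hi")))
  m1 <- gbt_fit(x, y, nrounds = 40, max_depth = 3, eta = 0.3)
  expect_equal(mean(predict(m1, x) == y), 1)
  m2 <- gbt_fit(x, y, nrounds = 40, max_depth = 3, eta = 0.3)
  expect_identical(m1$trees, m2$trees)
  # probabilities sum to 1
  p <- predict(m1, x, type = "prob")
  expect_equal(rowSums(p), rep(1, n), tolerance = 1e-6)
  expect_error(gbt_fit(x, factor(rep("a", n))), "single-class")
})

test_that("pure-noise predictors give chance-level cross-validated accuracy", {
  set.seed(23)
  n <- 500
  df <- data.frame(matrix(rnorm(n * 8), n, 8,
                          dimnames = list(NULL, agro_variable_names())))
  df$class <- class_label(sample(1:4, n, replace = TRUE,
                                 prob = c(.4, .25, .2, .15)))
  grid <- data.frame(nrounds = 50L, max_depth = 2L, eta = 0.1)
  m <- tune_and_fit(df, grid, nfolds = 3, seed = 23)
  majority <- max(table(df$class)) / n
  expect_lt(abs(max(m$cv$accuracy) - majority), 0.15)
})

test_that("tuning is deterministic and records the chosen settings", {
  s <- generate_recovery_samples(300, seed = 31)
  grid <- expand.grid(nrounds = c(20L, 40L), max_depth = c(2L, 3L), eta = 0.3)
  m1 <- tune_and_fit(s, grid, nfolds = 2, seed = 31)
  m2 <- tune_and_fit(s, grid, nfolds = 2, seed = 31)
  expect_identical(m1$settings, m2$settings)
  expect_identical(m1$cv$accuracy, m2$cv$accuracy)
  expect_true(all(c("nrounds", "max_depth", "eta") %in% names(m1$settings)))
  expect_error(tune_and_fit(s[0, ], grid), "empty")
})

test_that("predict_map is a pure function of predictors with valid probabilities", {
  w <- generate_weather(8, 8, years = 2, seed = 41)
  r <- generate_region(8, 8, n_districts = 8, seed = 41)
  y <- generate_yields(w, r, truth_spec(noise_sd = 0), seed = 41)
  v <- assemble_variables(w, r)
  lab <- rasterize_labels(class_districts(y, "maize")$classes, r)
  samples <- build_samples(v, lab)
  m <- tune_and_fit(samples, data.frame(nrounds = 30L, max_depth = 2L, eta = 0.3),
                    nfolds = 2, seed = 41)
  map <- predict_map(m, v)
  expect_s3_class(map, "suitability_map")
  expect_true(all(map$rank[v$mask] %in% 1:4))
  psum <- Reduce(`+`, map$prob)
  expect_equal(psum[v$mask], rep(1, sum(v$mask)), tolerance = 1e-6)

  # purity: identical second call
  expect_identical(predict_map(m, v), map)

  # constant predictors -> spatially constant prediction
  vc <- v
  for (nm in names(vc$vars)) vc$vars[[nm]][] <- mean(v$vars[[nm]], na.rm = TRUE)
  mc <- predict_map(m, vc)
  expect_length(unique(mc$rank[vc$mask]), 1)

  # missing predictor band errors
  vbad <- v; vbad$vars$rain_cv <- NULL
  expect_error(predict_map(m, vbad), "rain_cv")
})

test_that("training labels are reproduced on a separable fit and models round-trip", {
  s <- generate_recovery_samples(400, noise_sd = 0, seed = 51)
  m <- tune_and_fit(s, data.frame(nrounds = 60L, max_depth = 3L, eta = 0.3),
                    nfolds = 2, seed = 51)
  pred <- predict(m, s)
  expect_gt(mean(as.character(pred) == as.character(s$class)), 0.98)

  p <- tempfile(fileext = ".rds")
  write_model(m, p)
  m2 <- read_model(p)
  expect_identical(m2$booster$trees, m$booster$trees)
  expect_identical(predict(m2, s), pred)
})

test_that("held-out accuracy approaches but does not beat the Bayes oracle", {
  s <- generate_recovery_samples(2000, seed = 61)
  cuts <- attr(s, "cuts"); sd0 <- attr(s, "noise_sd"); mu <- attr(s, "mu")
  parts <- split_samples(s, 0.7, seed = 61)
  m <- tune_and_fit(parts$fit,
                    data.frame(nrounds = 100L, max_depth = 4L, eta = 0.1),
                    nfolds = 3, seed = 61)
  ref <- factor(as.character(parts$test$class), levels = suitability_levels())
  pred <- predict(m, parts$test)
  oa <- mean(as.character(pred) == as.character(ref))
  expect_gte(oa, 0.70)
  cm <- confusion_matrix(ref, pred, suitability_levels())
  expect_gte(kappa_coefficient(cm), 0.55)

  # brute-force Bayes rule from the known generator: class posterior from
  # the latent normal noise around mu with the known cuts
  test_mu <- mu[as.integer(rownames(parts$test))]
  b <- cbind(-Inf, matrix(cuts, length(test_mu), 3, byrow = TRUE), Inf)
  post <- sapply(1:4, function(k)
    pnorm((b[, k + 1] - test_mu) / sd0) - pnorm((b[, k] - test_mu) / sd0))
  bayes_acc <- mean(max.col(post) == class_rank(ref))
  expect_gt(bayes_acc, 0.80)  # world calibrated near 0.85
  expect_lt(bayes_acc, 0.90)
  expect_lte(oa, bayes_acc + 0.03)  # cannot beat the oracle beyond noise

  # scrambling sample order and unscrambling yields identical predictions
  perm <- sample(nrow(parts$test))
  pred_perm <- predict(m, parts$test[perm, ])
  expect_identical(pred_perm[order(perm)], pred)
})
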