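# Splitting, in-fold preprocessing, grid-search CV and the final refit.

test_that("the stratified split preserves class proportions within one", {
  labels <- c(rep("substrate", 20), rep("non_substrate", 80))
  sp <- split_train_test(labels, 0.2, seed = 1)
  expect_equal(length(sp$test), 20)
  expect_equal(sum(labels[sp$test] == "substrate"), 4)
  expect_equal(sum(labels[sp$train] == "substrate"), 16)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_train_test(labels, 0.2, seed = 1))
  expect_false(identical(sp$test, split_train_test(labels, 0.2, seed = 2)$test))
  expect_error(split_train_test(rep("substrate", 10)), "both classes")
})

test_that("stratified folds are balanced and refuse tiny minorities", {
  labels <- c(rep("substrate", 23), rep("non_substrate", 77))
  folds <- stratified_folds(labels, k = 5, seed = 3)
  expect_setequal(unique(folds), 1:5)
  per_fold_sub <- table(folds[labels == "substrate"])
  expect_lte(diff(range(per_fold_sub)), 1)
  expect_error(stratified_folds(c(rep("substrate", 4), rep("non_substrate", 50))),
               "minority")
})

test_that("vectorized ANOVA F scores match the linear-model oracle", {
  set.seed(11)
  X <- matrix(rnorm(40 * 6), 40)
  colnames(X) <- paste0("f", 1:6)
  y <- rep(c("substrate", "non_substrate"), each = 20)
  f_fast <- anova_f_scores(X, y)
  f_oracle <- apply(X, 2, function(col) {
    stats::anova(stats::lm(col ~ factor(y)))[["F value"]][1]
  })
  expect_equal(unname(f_fast), unname(f_oracle))
})

test_that("the preprocessor drops constant columns and ranks by F", {
  y <- rep(c("substrate", "non_substrate"), each = 10)
  X <- cbind(
    signal = c(rep(1, 10), rep(0, 10)),   # perfectly separating
    noise = rep(c(0, 1), 10),             # orthogonal to the classes
    constant = rep(3, 20)
  )
  pp <- build_preprocessor(X, y, percentile = 100)
  expect_setequal(pp$columns, c("signal", "noise"))   # constant removed
  pp50 <- build_preprocessor(X, y, percentile = 50)
  expect_equal(pp50$columns, "signal")                # top F score wins
  expect_error(build_preprocessor(X[, "constant", drop = FALSE], y),
               "zero variance")
})

test_that("standardization uses training statistics and skips binary columns", {
  set.seed(4)
  X <- cbind(cont = rnorm(30, 5, 2), bin = rbinom(30, 1, 0.4))
  y <- rep(c("substrate", "non_substrate"), 15)
  pp <- build_preprocessor(X, y, percentile = 100, standardize = TRUE)
  Xt <- apply_preprocessor(pp, X)
  expect_equal(mean(Xt[, "cont"]), 0)
  expect_equal(stats::sd(Xt[, "cont"]), 1)
  expect_true(all(Xt[, "bin"] %in% c(0, 1)))
  # new data transformed with the *training* statistics
  Xnew <- apply_preprocessor(pp, X[1:5, , drop = FALSE])
  expect_equal(unname(Xnew[, "cont"]),
               unname((X[1:5, "cont"] - mean(X[, "cont"])) / stats::sd(X[, "cont"])))
})

test_that("the default grid has the published cardinality", {
  grid <- default_hyperparameter_grid()
  expect_equal(nrow(cypsubstrate:::grid_points(grid, "rf")), 7 * 6 * 4)
  expect_equal(nrow(cypsubstrate:::grid_points(grid, "svm")), 6 * 6 * 4)
})

test_that("grid search is deterministic and honors a one-point grid", {
  ds <- tiny_dataset()
  X <- tiny_features("maccs")
  y <- ds$label_3A4
  one_point <- list(rf = list(min_samples_split = 8, max_features = list(0.4)),
                    svm = list(C = 1, gamma = 0.01),
                    feature_percentile = 70)
  cv1 <- grid_search_cv(X, y, "rf", grid = one_point, seed = 42)
  expect_equal(cv1$best_params$min_samples_split, 8)
  expect_equal(cv1$best_params$percentile, 70)
  expect_equal(nrow(cv1$fold_metrics), 5)
  cv2 <- grid_search_cv(X, y, "rf", grid = one_point, seed = 42)
  expect_identical(cv1$fold_metrics, cv2$fold_metrics)
  expect_identical(cv1$best_params, cv2$best_params)
})

test_that("feature selection is refit inside each fold", {
  set.seed(9)
  X <- matrix(rnorm(150 * 40), 150)
  colnames(X) <- paste0("f", 1:40)
  y <- sample(rep(c("substrate", "non_substrate"), c(50, 100)))
  grid <- list(rf = list(min_samples_split = 2, max_features = list("sqrt")),
               svm = list(C = 1, gamma = 0.01), feature_percentile = 10)
  cv <- grid_search_cv(X, y, "rf", grid = grid, seed = 1)
  expect_length(cv$fold_selected, 5)
  # on pure noise the per-fold top-10% sets differ
  expect_gt(length(unique(cv$fold_selected)), 1)
})

test_that("a planted-rule fixture is recovered almost perfectly on its own training data", {
  ds <- tiny_dataset()           # noise-free labels
  X <- tiny_features("maccs")
  y <- ds$label_3A4
  fit <- fit_cyp_classifier(X, y, "rf", cyp = "3A4",
                            grid = small_hyperparameter_grid(), seed = 42,
                            feature_set = "maccs")
  pred <- predict(fit, X, type = "label")
  counts <- confusion_counts(y, pred)
  expect_gte(mcc_score(counts), 0.9)
})

test_that("balanced class weighting yields nonzero minority recall at 1:16", {
  ds <- generate_labeled_set(fixture_config(n_compounds = 340,
                                            imbalance_ratio = c(1, 16),
                                            label_noise = 0,
                                            missing_fraction = 0, seed = 21))
  y <- ds$label_3A4
  sp <- split_train_test(y, 0.2, seed = 42)
  X <- featurize(ds, "maccs")
  fit <- fit_cyp_classifier(X[sp$train, ], y[sp$train], "rf", cyp = "3A4",
                            grid = small_hyperparameter_grid(), seed = 42,
                            feature_set = "maccs")
  pred <- predict(fit, X[sp$test, ], type = "label")
  minority <- y[sp$test] == "substrate"
  expect_gt(sum(pred[minority] == "substrate"), 0)
})

test_that("the SVM path yields calibrated, deterministic probabilities", {
  ds <- tiny_dataset()
  X <- tiny_features("physchem2d")
  y <- ds$label_3A4
  sp <- split_train_test(y, 0.2, seed = 42)
  grid <- list(svm = list(C = 10, gamma = 0.01),
               rf = list(min_samples_split = 2, max_features = list("sqrt")),
               feature_percentile = 100)
  f1 <- fit_cyp_classifier(X[sp$train, ], y[sp$train], "svm", cyp = "3A4",
                           grid = grid, seed = 42, feature_set = "physchem2d")
  p1 <- predict(f1, X[sp$test, ], type = "prob")
  expect_true(all(p1 >= 0 & p1 <= 1))
  f2 <- fit_cyp_classifier(X[sp$train, ], y[sp$train], "svm", cyp = "3A4",
                           grid = grid, seed = 42, feature_set = "physchem2d")
  expect_equal(p1, predict(f2, X[sp$test, ], type = "prob"))
  # the calibrated probability ranks like the decision value: sensible AUC
  expect_gt(auc_score(p1, y[sp$test]), 0.8)
})

test_that("model selection maximizes median MCC with a fixed tie-break", {
  a <- fake_classifier(0.58, "svm", "morgan2")
  b <- fake_classifier(0.44, "rf", "maccs")
  expect_identical(select_best_model(list(a, b)), a)
  expect_identical(select_best_model(list(b)), b)
  # exact tie: rf before svm, then feature-set order
  t1 <- fake_classifier(0.5, "svm", "maccs")
  t2 <- fake_classifier(0.5, "rf", "physchem2d")
  t3 <- fake_classifier(0.5, "rf", "morgan2")
  expect_identical(select_best_model(list(t1, t2, t3)), t3)
  expect_error(select_best_model(list()), "no candidate")
})
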