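# Per-CYP single classifiers: stratified splitting, in-fold preprocessing
# (zero-variance removal, ANOVA-F percentile selection, optional
# standardization), grid-search hyperparameter optimization within stratified
# five-fold cross-validation, and the final refit. Random forests are fitted
# with ranger, support vector machines with e1071 (libsvm); both use balanced
# class weights. The substrate class is the positive class.

CLASS_LEVELS <- c("non_substrate", "substrate")

as_label_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- !labels %in% CLASS_LEVELS
  if (any(bad)) stop("labels must be 'substrate' or 'non_substrate'")
  factor(labels, levels = CLASS_LEVELS)
}

#' Default hyperparameter grid
#'
#' Random forest: `min_samples_split` in \{2, 4, 8, 16, 32, 64, 128\} and
#' `max_features` in \{0.05, 0.1, 0.2, 0.4, 0.8, sqrt\}. SVM (RBF kernel):
#' `C` in 10^(-2..3) and `gamma` in 10^(0..-5). Feature-selection
#' percentile in \{10, 40, 70, 100\} for both.
#'
#' @return Nested list with components `rf`, `svm`, `feature_percentile`.
#' @export
default_hyperparameter_grid <- function() {
  list(
    rf = list(
      min_samples_split = c(2, 4, 8, 16, 32, 64, 128),
      max_features = list(0.05, 0.1, 0.2, 0.4, 0.8, "sqrt")
    ),
    svm = list(
      C = 10^seq(-2, 3),
      gamma = 10^seq(0, -5)
    ),
    feature_percentile = c(10, 40, 70, 100)
  )
}

#' A reduced grid for quick runs
#'
#' A small, fixed subset of the default grid used for fast pipeline runs and
#' examples: RF `min_samples_split` \{2, 32\} x `max_features` \{0.2, sqrt\},
#' SVM `C` \{1, 10\} x `gamma` \{0.01, 0.001\}, percentile \{100\}.
#'
#' @return Nested list in the same layout as [default_hyperparameter_grid()].
#' @export
small_hyperparameter_grid <- function() {
  list(
    rf = list(min_samples_split = c(2, 32), max_features = list(0.2, "sqrt")),
    svm = list(C = c(1, 10), gamma = c(1e-2, 1e-3)),
    feature_percentile = 100
  )
}

grid_points <- function(grid, algorithm) {
  if (algorithm == "rf") {
    pts <- expand.grid(
      min_samples_split = grid$rf$min_samples_split,
      max_features = seq_along(grid$rf$max_features),
      percentile = grid$feature_percentile
    )
    pts$max_features <- grid$rf$max_features[pts$max_features]
  } else {
    pts <- expand.grid(
      C = grid$svm$C,
      gamma = grid$svm$gamma,
      percentile = grid$feature_percentile
    )
  }
  pts
}

#' Stratified train/test split
#'
#' Shuffled, stratified by class, deterministic per seed; class proportions
#' are preserved within one compound per class.
#'
#' @param labels class labels (`"substrate"` / `"non_substrate"`), no
#'   missing values.
#' @param test_fraction fraction held out (default 0.2).
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, test_fraction = 0.2, seed = 42) {
  y <- as_label_factor(labels)
  if (nlevels(droplevels(y)) < 2L) {
    stop("both classes must be present to split")
  }
  idx_test <- integer(0)
  for (cls in levels(y)) {
    cls_idx <- which(y == cls)
    n_test <- round(test_fraction * length(cls_idx))
    shuffled <- with_seed(seed + match(cls, levels(y)),
                          sample(cls_idx))
    idx_test <- c(idx_test, shuffled[seq_len(n_test)])
  }
  idx_test <- sort(idx_test)
  list(train = setdiff(seq_along(y), idx_test), test = idx_test)
}

#' Stratified k-fold assignment
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed (folds are shuffled).
#' @return Integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(labels, k = 5, seed = 42) {
  y <- as_label_factor(labels)
  if (min(table(y)) < k) {
    stop("fewer than ", k, " members of the minority class; cannot build ",
         k, " stratified folds")
  }
  folds <- integer(length(y))
  for (cls in levels(y)) {
    cls_idx <- which(y == cls)
    shuffled <- with_seed(seed + 97L * match(cls, levels(y)),
                          sample(cls_idx))
    folds[shuffled] <- rep_len(seq_len(k), length(shuffled))
  }
  folds
}

# run expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' One-way ANOVA F scores per feature
#'
#' Closed-form one-way F statistic between the two classes for every column,
#' vectorized (identical to the classic per-feature `aov` F value).
#'
#' @param X numeric feature matrix.
#' @param labels class labels.
#' @return Numeric vector of F scores (Inf where within-class variance is 0
#'   and between-class variance is positive).
#' @export
anova_f_scores <- function(X, labels) {
  y <- as_label_factor(labels)
  n <- nrow(X)
  k <- nlevels(y)
  overall <- colMeans(X)
  ssb <- 0
  ssw <- 0
  for (cls in levels(y)) {
    rows <- y == cls
    m <- colMeans(X[rows, , drop = FALSE])
    ssb <- ssb + sum(rows) * (m - overall)^2
    ssw <- ssw + colSums(sweep(X[rows, , drop = FALSE], 2, m)^2)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- msb / msw
  f[msw == 0 & msb > 0] <- Inf
  f[msw == 0 & msb == 0] <- 0
  f
}

#' Fit a feature preprocessor
#'
#' Drops zero-variance columns, keeps the top `percentile` percent of the
#' remaining columns by one-way ANOVA F score (stable tie-break by column
#' order), and -- when `standardize` is set, the SVM path -- z-scores
#' non-binary columns using training statistics only.
#'
#' @param X training feature matrix.
#' @param labels training class labels.
#' @param percentile percentage of (non-constant) features kept.
#' @param standardize z-score non-binary columns.
#' @return Object of class `cyp_preprocessor`.
#' @export
build_preprocessor <- function(X, labels, percentile = 100,
                               standardize = FALSE) {
  stopifnot(percentile > 0, percentile <= 100)
  variances <- apply(X, 2, stats::var)
  keep_var <- variances > 0
  if (!any(keep_var)) stop("all feature columns have zero variance")
  X1 <- X[, keep_var, drop = FALSE]
  f <- anova_f_scores(X1, labels)
  n_keep <- max(1L, ceiling(percentile / 100 * ncol(X1)))
  sel <- order(-f)[seq_len(n_keep)]
  sel <- sort(sel)  # preserve original column order
  cols <- colnames(X1)[sel]
  center <- scale_ <- NULL
  if (standardize) {
    Xs <- X1[, sel, drop = FALSE]
    is_binary <- apply(Xs, 2, function(col) all(col %in% c(0, 1)))
    center <- ifelse(is_binary, 0, colMeans(Xs))
    sdv <- apply(Xs, 2, stats::sd)
    scale_ <- ifelse(is_binary | sdv == 0, 1, sdv)
    names(center) <- names(scale_) <- cols
  }
  structure(list(columns = cols, f_scores = f[sel], percentile = percentile,
                 standardize = standardize, center = center, scale = scale_),
            class = "cyp_preprocessor")
}

#' Apply a fitted preprocessor to a feature matrix
#'
#' @param preproc a `cyp_preprocessor`.
#' @param X feature matrix with (at least) the training columns.
#' @return Transformed matrix restricted to the selected columns.
#' @export
apply_preprocessor <- function(preproc, X) {
  missing_cols <- setdiff(preproc$columns, colnames(X))
  if (length(missing_cols)) {
    stop("feature matrix lacks columns: ",
         paste(utils::head(missing_cols, 3), collapse = ", "))
  }
  out <- X[, preproc$columns, drop = FALSE]
  if (isTRUE(preproc$standardize)) {
    out <- sweep(out, 2, preproc$center)
    out <- sweep(out, 2, preproc$scale, `/`)
  }
  out
}

balanced_class_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * as.numeric(tab))
  names(w) <- names(tab)
  w
}

mtry_from_max_features <- function(max_features, p) {
  if (identical(max_features, "sqrt")) {
    max(1L, floor(sqrt(p)))
  } else {
    max(1L, round(as.numeric(max_features) * p))
  }
}

fit_learner <- function(X, y, algorithm, params, seed) {
  w <- balanced_class_weights(y)
  if (algorithm == "rf") {
    d <- data.frame(X, check.names = FALSE)
    d$.y <- y
    model <- ranger::ranger(
      dependent.variable.name = ".y", data = d,
      num.trees = 500, probability = TRUE,
      min.node.size = params$min_samples_split,
      mtry = mtry_from_max_features(params$max_features[[1]], ncol(X)),
      class.weights = as.numeric(w[levels(y)]),
      importance = "impurity",
      seed = seed, num.threads = 1
    )
    list(algorithm = "rf", model = model)
  } else {
    model <- e1071::svm(
      x = X, y = y, kernel = "radial",
      cost = params$C, gamma = params$gamma,
      class.weights = w, scale = FALSE
    )
    list(algorithm = "svm", model = model)
  }
}

# substrate-class score: calibrated probability for RF; decision value
# oriented toward the substrate class for uncalibrated SVM
learner_scores <- function(fit, X) {
  if (fit$algorithm == "rf") {
    pred <- stats::predict(fit$model, data.frame(X, check.names = FALSE),
                           num.threads = 1)
    return(list(score = pred$predictions[, "substrate"], is_probability = TRUE))
  }
  pred <- stats::predict(fit$model, X, decision.values = TRUE)
  dv <- as.numeric(attr(pred, "decision.values"))
  first <- strsplit(colnames(attr(pred, "decision.values")), "/")[[1]][1]
  if (first != "substrate") dv <- -dv
  list(score = dv, is_probability = FALSE, label = as.character(pred))
}

learner_labels <- function(scores_obj) {
  if (!is.null(scores_obj$label)) return(scores_obj$label)
  ifelse(scores_obj$score > 0.5, "substrate", "non_substrate")
}

# Platt scaling: cross-validated sigmoid fit on decision values,
# seed-deterministic.
platt_calibrate <- function(X, y, params, seed, k = 3) {
  folds <- stratified_folds(y, k = min(k, min(table(y))), seed = seed + 1009L)
  dv <- numeric(length(y))
  for (f in unique(folds)) {
    tr <- folds != f
    fit_f <- fit_learner(X[tr, , drop = FALSE], droplevels(y[tr]),
                         "svm", params, seed)
    dv[!tr] <- learner_scores(fit_f, X[!tr, , drop = FALSE])$score
  }
  target <- as.integer(y == "substrate")
  cal <- suppressWarnings(
    stats::glm(target ~ dv, family = stats::binomial())
  )
  as.numeric(stats::coef(cal))
}

apply_calibration <- function(coefs, dv) {
  stats::plogis(coefs[1] + coefs[2] * dv)
}

fold_metrics <- function(truth, labels, scores, has_prob) {
  counts <- confusion_counts(truth, labels)
  auc <- if (length(unique(truth)) == 2L) auc_score(scores, truth) else NA_real_
  c(mcc = mcc_score(counts), jaccard = jaccard_score(counts), auc = auc)
}

#' Grid-search hyperparameter optimization within stratified five-fold CV
#'
#' For every hyperparameter point (including the feature-selection
#' percentile) the preprocessor is re-fitted inside each fold on that fold's
#' training portion, the learner is trained and evaluated on the validation
#' fold, and the point with the best median fold MCC wins (deterministic
#' tie-break by grid order).
#'
#' @param X feature matrix (training split).
#' @param labels class labels for `X`.
#' @param algorithm `"rf"` or `"svm"`.
#' @param grid hyperparameter grid, see [default_hyperparameter_grid()].
#' @param seed integer seed driving fold shuffling and forest bootstraps.
#' @param nfolds number of CV folds.
#' @return List of class `cyp_cv_result`: `best_params`, `fold_metrics`
#'   (matrix folds x \{mcc, jaccard, auc\} for the winning point),
#'   `median_mcc`, `summary` (per-point medians), `fold_n_features`.
#' @export
grid_search_cv <- function(X, labels, algorithm = c("rf", "svm"),
                           grid = default_hyperparameter_grid(),
                           seed = 42, nfolds = 5) {
  algorithm <- match.arg(algorithm)
  y <- as_label_factor(labels)
  folds <- stratified_folds(y, k = nfolds, seed = seed)
  pts <- grid_points(grid, algorithm)
  standardize <- algorithm == "svm"
  results <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    params <- as.list(pts[i, , drop = FALSE])
    per_fold <- matrix(NA_real_, nfolds, 3,
                       dimnames = list(NULL, c("mcc", "jaccard", "auc")))
    nfeat <- integer(nfolds)
    for (f in seq_len(nfolds)) {
      tr <- folds != f
      pp <- build_preprocessor(X[tr, , drop = FALSE], y[tr],
                               percentile = params$percentile,
                               standardize = standardize)
      nfeat[f] <- length(pp$columns)
      Xtr <- apply_preprocessor(pp, X[tr, , drop = FALSE])
      Xva <- apply_preprocessor(pp, X[!tr, , drop = FALSE])
      fit <- fit_learner(Xtr, droplevels(y[tr]), algorithm, params, seed)
      sc <- learner_scores(fit, Xva)
      per_fold[f, ] <- fold_metrics(as.character(y[!tr]),
                                    learner_labels(sc), sc$score,
                                    sc$is_probability)
    }
    results[[i]] <- list(params = params, fold_metrics = per_fold,
                         median_mcc = stats::median(per_fold[, "mcc"]),
                         fold_n_features = nfeat)
  }
  medians <- vapply(results, `[[`, numeric(1), "median_mcc")
  best <- which.max(medians)  # first max wins: deterministic tie-break
  summary_df <- cbind(pts, median_mcc = medians)
  # per-fold selected feature names at the winning point: selection is
  # refitted inside each fold, so the sets may legitimately differ
  best_pct <- results[[best]]$params$percentile
  fold_selected <- lapply(seq_len(nfolds), function(f) {
    tr <- folds != f
    build_preprocessor(X[tr, , drop = FALSE], y[tr],
                       percentile = best_pct,
                       standardize = standardize)$columns
  })
  structure(list(
    algorithm = algorithm,
    best_params = results[[best]]$params,
    fold_metrics = results[[best]]$fold_metrics,
    median_mcc = medians[best],
    median_jaccard = stats::median(results[[best]]$fold_metrics[, "jaccard"]),
    median_auc = stats::median(results[[best]]$fold_metrics[, "auc"]),
    fold_n_features = results[[best]]$fold_n_features,
    fold_selected = fold_selected,
    summary = summary_df,
    nfolds = nfolds,
    seed = seed
  ), class = "cyp_cv_result")
}

#' Fit a single CYP substrate classifier
#'
#' The modelling entry point: runs [grid_search_cv()] on the supplied
#' training features, refits the preprocessor and learner on the full
#' training split with the winning hyperparameters, fits a seed-deterministic
#' cross-validated sigmoid (Platt) calibration for the SVM path, and stores
#' the training Morgan fingerprints for applicability-domain reporting when
#' supplied.
#'
#' @param X training feature matrix from [featurize()].
#' @param labels training class labels.
#' @param algorithm `"rf"` (random forest, 500 trees) or `"svm"` (RBF
#'   kernel); both use balanced class weights.
#' @param cyp isozyme identifier (metadata).
#' @param grid hyperparameter grid.
#' @param seed pipeline seed (default 42).
#' @param nfolds CV folds (default 5).
#' @param ad_fingerprints optional binary Morgan fingerprint matrix of the
#'   training compounds (row-aligned with `X`) enabling
#'   applicability-domain reporting at prediction time.
#' @param feature_set feature-set identifier recorded in the model spec
#'   (defaults to the matrix attribute set by [featurize()]; matrix
#'   subsetting drops attributes, so pass it explicitly in pipelines).
#' @return Object of class `cyp_classifier`.
#' @export
fit_cyp_classifier <- function(X, labels, algorithm = c("rf", "svm"),
                               cyp = NA_character_,
                               grid = default_hyperparameter_grid(),
                               seed = 42, nfolds = 5,
                               ad_fingerprints = NULL,
                               feature_set = attr(X, "feature_set")) {
  algorithm <- match.arg(algorithm)
  y <- as_label_factor(labels)
  if (is.null(feature_set)) feature_set <- NA_character_
  cv <- grid_search_cv(X, y, algorithm, grid = grid, seed = seed,
                       nfolds = nfolds)
  pp <- build_preprocessor(X, y, percentile = cv$best_params$percentile,
                           standardize = algorithm == "svm")
  Xp <- apply_preprocessor(pp, X)
  fit <- fit_learner(Xp, y, algorithm, cv$best_params, seed)
  calibration <- NULL
  if (algorithm == "svm") {
    calibration <- platt_calibrate(Xp, y, cv$best_params, seed)
  }
  if (!is.null(ad_fingerprints)) {
    stopifnot(nrow(ad_fingerprints) == nrow(X))
    ad_fingerprints <- ad_fingerprints > 0
  }
  structure(list(
    spec = list(cyp = cyp, algorithm = algorithm, feature_set = feature_set,
                seed = seed),
    preprocessor = pp,
    fit = fit,
    calibration = calibration,
    cv = cv,
    ad_fingerprints = ad_fingerprints,
    n_train = nrow(X),
    class_counts = as.list(table(y))
  ), class = "cyp_classifier")
}

#' Predict method for CYP substrate classifiers
#'
#' @param object a `cyp_classifier`.
#' @param newdata feature matrix in the classifier's feature set.
#' @param type `"prob"` for substrate-class probabilities, `"label"` for
#'   class labels, `"both"` for a data frame with both.
#' @param ... unused.
#' @return Numeric vector, character vector, or data frame according to
#'   `type`.
#' @export
predict.cyp_classifier <- function(object, newdata,
                                   type = c("prob", "label", "both"), ...) {
  type <- match.arg(type)
  Xp <- apply_preprocessor(object$preprocessor, newdata)
  sc <- learner_scores(object$fit, Xp)
  if (object$spec$algorithm == "svm") {
    prob <- apply_calibration(object$calibration, sc$score)
    label <- learner_labels(sc)  # libsvm's own (weighted) decision rule
  } else {
    prob <- sc$score
    label <- ifelse(prob > 0.5, "substrate", "non_substrate")
  }
  switch(type,
         prob = prob,
         label = label,
         both = data.frame(label = label, probability = prob))
}

#' @export
print.cyp_classifier <- function(x, ...) {
  cat(sprintf("<cyp_classifier> CYP%s %s on %s (n=%d, S:%s/NS:%s)\n",
              x$spec$cyp, toupper(x$spec$algorithm), x$spec$feature_set,
              x$n_train, x$class_counts$substrate,
              x$class_counts$non_substrate))
  cat(sprintf("  CV median MCC %.3f | Jaccard %.3f | AUC %.3f (5-fold)\n",
              x$cv$median_mcc, x$cv$median_jaccard, x$cv$median_auc))
  cat("  best hyperparameters:",
      paste(names(x$cv$best_params),
            vapply(x$cv$best_params, function(v) paste(format(v), collapse = ""),
                   character(1)),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cyp_classifier <- function(object, ...) {
  print(object)
  cat("  per-fold metrics (best hyperparameter point):\n")
  print(round(object$cv$fold_metrics, 3))
  cat(sprintf("  features selected per fold: %s\n",
              paste(object$cv$fold_n_features, collapse = ", ")))
  invisible(object)
}

#' Select the best model by median CV MCC
#'
#' Argmax of the median cross-validated MCC with a deterministic tie-break by
#' the fixed (algorithm, feature set) ordering: RF before SVM, feature sets
#' in [feature_sets()] order.
#'
#' @param candidates list of `cyp_classifier` objects (or `cyp_cv_result`
#'   objects carrying `spec`).
#' @return The winning element of `candidates`.
#' @export
select_best_model <- function(candidates) {
  if (length(candidates) == 0L) stop("no candidate models supplied")
  med <- vapply(candidates, function(m) m$cv$median_mcc, numeric(1))
  alg <- vapply(candidates, function(m) m$spec$algorithm, character(1))
  fs <- vapply(candidates, function(m) as.character(m$spec$feature_set),
               character(1))
  ord <- order(-med, match(alg, c("rf", "svm")),
               match(fs, feature_sets()))
  candidates[[ord[1]]]
}
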