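# End-to-end orchestration: per-isozyme training over (algorithm, feature
# set) combinations, consensus construction, prediction with
# applicability-domain annotation, and the planted-rule recovery benchmark.

#' Train single classifiers for one isozyme
#'
#' Extracts the isozyme-specific labeled subset (rows with a missing label
#' are dropped), performs the stratified 80/20 train/test split, featurizes
#' the subset once per feature set, and fits one classifier per
#' (algorithm, feature set) combination on the training split. Training
#' Morgan fingerprints are attached to every model for applicability-domain
#' reporting.
#'
#' @param dataset a `cyp_dataset`.
#' @param cyp isozyme identifier (one of [cyp_isozymes()]).
#' @param feature_set_ids feature sets to use.
#' @param algorithms algorithms to use.
#' @param grid hyperparameter grid.
#' @param seed pipeline seed (default 42) driving the split, fold shuffling,
#'   forest bootstraps and calibration.
#' @param test_fraction held-out fraction (default 0.2).
#' @param embedding embedding table for the `embed300` feature set (defaults
#'   to the deterministic hashed fallback).
#' @return List of class `cyp_isozyme_models` with `models` (named list of
#'   `cyp_classifier`), `features` (named list of matrices over the whole
#'   subset), `labels`, `split`, `cyp`, `record_ids`.
#' @export
train_isozyme_models <- function(dataset, cyp,
                                 feature_set_ids = feature_sets(),
                                 algorithms = c("rf", "svm"),
                                 grid = default_hyperparameter_grid(),
                                 seed = 42, test_fraction = 0.2,
                                 embedding = hashed_embedding()) {
  stopifnot(cyp %in% cyp_isozymes())
  col <- paste0("label_", cyp)
  df <- as.data.frame(dataset)
  keep <- !is.na(df[[col]])
  if (!any(keep)) stop("no labeled compounds for CYP", cyp)
  df <- df[keep, , drop = FALSE]
  labels <- df[[col]]
  split <- split_train_test(labels, test_fraction = test_fraction, seed = seed)
  features <- list()
  for (fs in feature_set_ids) {
    features[[fs]] <- featurize(df, fs, embedding = embedding)
  }
  ad_fps <- if ("morgan2" %in% names(features)) {
    features$morgan2
  } else {
    featurize(df, "morgan2")
  }
  models <- list()
  for (alg in algorithms) {
    for (fs in feature_set_ids) {
      key <- paste(alg, fs, sep = "_")
      models[[key]] <- fit_cyp_classifier(
        features[[fs]][split$train, , drop = FALSE],
        labels[split$train],
        algorithm = alg, cyp = cyp, grid = grid, seed = seed,
        ad_fingerprints = ad_fps[split$train, , drop = FALSE],
        feature_set = fs
      )
    }
  }
  structure(list(models = models, features = features, labels = labels,
                 split = split, cyp = cyp, record_ids = df$record_id,
                 seed = seed),
            class = "cyp_isozyme_models")
}

#' @export
print.cyp_isozyme_models <- function(x, ...) {
  cat(sprintf("<cyp_isozyme_models> CYP%s: %d models, %d train / %d test\n",
              x$cyp, length(x$models), length(x$split$train),
              length(x$split$test)))
  for (m in x$models) {
    cat(sprintf("  %-4s %-11s CV median MCC %.3f\n",
                toupper(m$spec$algorithm), m$spec$feature_set,
                m$cv$median_mcc))
  }
  invisible(x)
}

#' Planted-rule recovery benchmark
#'
#' Generates a synthetic labeled set whose labels follow a planted structural
#' rule with label noise, trains one random forest per feature set, and
#' compares the best single classifier with the unanimous (min consensus =
#' member count) hard-voting consensus on the held-out test split -- the
#' hard-voting MCC is computed on the covered compounds and the single-model
#' MCC on that same subset.
#'
#' @param n_compounds fixture size (default 1000).
#' @param label_noise label-flip probability (default 0.05).
#' @param seed pipeline seed.
#' @param grid hyperparameter grid (default [small_hyperparameter_grid()]).
#' @param feature_set_ids feature sets for the members.
#' @param cyp which fixture label column to model.
#' @return List with `cv_median_mcc` (per member), `best_single` (key),
#'   `best_single_cv_mcc`, test-set evaluations `single_eval` and
#'   `hard_eval`, and the covered-subset comparison `mcc_hard_covered`,
#'   `mcc_single_covered`, `coverage_substrates`, `coverage_non_substrates`.
#' @export
recovery_benchmark <- function(n_compounds = 1000, label_noise = 0.05,
                               seed = 42,
                               grid = small_hyperparameter_grid(),
                               feature_set_ids = feature_sets(),
                               cyp = "3A4") {
  config <- fixture_config(n_compounds = n_compounds,
                           label_noise = label_noise,
                           missing_fraction = 0, seed = seed)
  dataset <- generate_labeled_set(config)
  run <- train_isozyme_models(dataset, cyp,
                              feature_set_ids = feature_set_ids,
                              algorithms = "rf", grid = grid, seed = seed)
  cv_mcc <- vapply(run$models, function(m) m$cv$median_mcc, numeric(1))
  best <- select_best_model(run$models)
  best_key <- paste(best$spec$algorithm, best$spec$feature_set, sep = "_")
  test_idx <- run$split$test
  truth <- run$labels[test_idx]
  test_features <- lapply(run$features, function(f) {
    f[test_idx, , drop = FALSE]
  })
  single_pred <- stats::predict(best, test_features[[best$spec$feature_set]],
                                type = "both")
  single_eval <- evaluate_predictions(truth, single_pred$label,
                                      single_pred$probability)
  members <- run$models[paste("rf", feature_set_ids, sep = "_")]
  consensus <- cyp_consensus(members, strategy = "hard",
                             min_consensus = length(members))
  hard_pred <- stats::predict(consensus, test_features)
  hard_eval <- evaluate_predictions(truth, hard_pred$label)
  covered <- !hard_pred$abstained
  mcc_hard_covered <- mcc_score(
    confusion_counts(truth[covered], hard_pred$label[covered]))
  mcc_single_covered <- mcc_score(
    confusion_counts(truth[covered], single_pred$label[covered]))
  list(
    cv_median_mcc = cv_mcc,
    best_single = best_key,
    best_single_cv_mcc = best$cv$median_mcc,
    single_eval = single_eval,
    hard_eval = hard_eval,
    mcc_hard_covered = mcc_hard_covered,
    mcc_single_covered = mcc_single_covered,
    coverage_substrates = hard_eval$coverage_substrates,
    coverage_non_substrates = hard_eval$coverage_non_substrates,
    n_test = length(test_idx),
    n_covered = sum(covered),
    models = run$models,
    dataset = dataset
  )
}

#' Predict substrates for new molecules with reliability annotation
#'
#' Runs the best single model and the hard-voting consensus side by side for
#' a batch of molecules, reporting label, probability (single model only),
#' abstention, the nearest-training-neighbor Tanimoto similarity (Morgan2)
#' and the applicability-domain reliability flag (similarity >= threshold,
#' inclusive).
#'
#' @param single the selected `cyp_classifier`.
#' @param consensus a hard-voting `cyp_consensus` (or `NULL` to skip).
#' @param smiles character vector of standardized SMILES.
#' @param ids record identifiers.
#' @param embedding embedding table if any member uses `embed300`.
#' @param reliability_threshold Tanimoto threshold (default 0.7).
#' @return Data frame with one row per molecule and model type.
#' @export
predict_molecules <- function(single, consensus, smiles, ids = NULL,
                              embedding = hashed_embedding(),
                              reliability_threshold = 0.7) {
  if (is.null(ids)) ids <- sprintf("mol_%d", seq_along(smiles))
  needed <- unique(c(as.character(single$spec$feature_set),
                     if (!is.null(consensus)) consensus$feature_sets,
                     "morgan2"))
  feats <- list()
  for (fs in needed) {
    feats[[fs]] <- featurize(stats::setNames(smiles, ids), fs,
                             embedding = embedding)
  }
  if (is.null(single$ad_fingerprints)) {
    stop("the selected model carries no training fingerprints; ",
         "refit with `ad_fingerprints` to enable reliability reporting")
  }
  nn <- nearest_training_similarity(feats$morgan2, single$ad_fingerprints,
                                    threshold = reliability_threshold)
  single_pred <- stats::predict(
    single, feats[[as.character(single$spec$feature_set)]], type = "both")
  out <- data.frame(
    id = ids, cyp = single$spec$cyp, model_type = "single",
    label = single_pred$label, probability = single_pred$probability,
    nn_similarity = nn$similarity, reliable = nn$reliable,
    stringsAsFactors = FALSE
  )
  if (!is.null(consensus)) {
    hard_pred <- stats::predict(consensus, feats)
    out <- rbind(out, data.frame(
      id = ids, cyp = single$spec$cyp, model_type = "hard_voting",
      label = hard_pred$label, probability = NA_real_,
      nn_similarity = nn$similarity, reliable = nn$reliable,
      stringsAsFactors = FALSE
    ))
  }
  out
}

#' Enumerate and evaluate combined models for one isozyme
#'
#' Builds every combined-model specification over the best single model per
#' (algorithm, feature set) pair and evaluates each on the held-out test
#' split, reporting MCC, Jaccard, AUC (probability-based strategies only)
#' and per-class coverage (abstaining strategies only).
#'
#' @param run a `cyp_isozyme_models` object whose models cover each
#'   (algorithm, feature set) pair at most once.
#' @return Data frame, one row per combined model.
#' @export
evaluate_combined_models <- function(run) {
  stopifnot(inherits(run, "cyp_isozyme_models"))
  fsets <- unique(vapply(run$models, function(m) {
    as.character(m$spec$feature_set)
  }, character(1)))
  algs <- unique(vapply(run$models, function(m) m$spec$algorithm,
                        character(1)))
  specs <- enumerate_combined_specs(fsets, algs)
  test_idx <- run$split$test
  truth <- run$labels[test_idx]
  test_features <- lapply(run$features, function(f) f[test_idx, , drop = FALSE])
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    members_df <- specs$members[[i]]
    members <- lapply(seq_len(nrow(members_df)), function(j) {
      run$models[[paste(members_df$algorithm[j], members_df$feature_set[j],
                        sep = "_")]]
    })
    cm <- cyp_consensus(members, strategy = specs$strategy[i],
                        min_consensus = specs$min_consensus[i])
    pred <- stats::predict(cm, test_features)
    ev <- evaluate_predictions(truth, pred$label,
                               if (specs$strategy[i] == "hard") NULL
                               else pred$probability)
    data.frame(
      size = specs$size[i], strategy = specs$strategy[i],
      min_consensus = specs$min_consensus[i],
      setup = paste(toupper(members_df$algorithm), members_df$feature_set,
                    collapse = " + "),
      mcc = ev$mcc, jaccard = ev$jaccard, auc = ev$auc,
      coverage_substrates = ev$coverage_substrates,
      coverage_non_substrates = ev$coverage_non_substrates,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
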