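# Shared, memoized test objects. Everything is generated in code; the
# chemistry backend is called once per unique input thanks to the memoized
# standardization cache.

.test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  hit <- .test_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  .test_cache[[key]] <- val
  val
}

# a small noise-free labeled fixture used across test files
tiny_dataset <- function() {
  memo("tiny_dataset", generate_labeled_set(
    fixture_config(n_compounds = 200, label_noise = 0,
                   missing_fraction = 0, seed = 7)))
}

tiny_features <- function(fs) {
  memo(paste0("feat_", fs),
       featurize(tiny_dataset(), fs, embedding = hashed_embedding()))
}

# minimal stand-in classifier objects for selection-logic tests
fake_classifier <- function(median_mcc, algorithm, feature_set) {
  structure(list(spec = list(cyp = "3A4", algorithm = algorithm,
                             feature_set = feature_set, seed = 1),
                 cv = list(median_mcc = median_mcc)),
            class = "cyp_classifier")
}

# a trained maccs + morgan2 model pair on the tiny fixture (rf, small grid)
tiny_model_pair <- function() {
  memo("tiny_model_pair", {
    ds <- tiny_dataset()
    y <- ds$label_3A4
    sp <- split_train_test(y, 0.2, seed = 42)
    models <- lapply(c("maccs", "morgan2"), function(fs) {
      X <- tiny_features(fs)
      fit_cyp_classifier(X[sp$train, , drop = FALSE], y[sp$train],
                         algorithm = "rf", cyp = "3A4",
                         grid = small_hyperparameter_grid(), seed = 42,
                         feature_set = fs)
    })
    names(models) <- c("maccs", "morgan2")
    list(models = models, split = sp, labels = y,
         features = list(maccs = tiny_features("maccs"),
                         morgan2 = tiny_features("morgan2")))
  })
}

with_seed_local <- function(seed, expr) {
  set.seed(seed)
  expr
}

expect_same_dataset <- function(a, b) {
  a <- as.data.frame(a)[order(as.data.frame(a)$smiles), ]
  b <- as.data.frame(b)[order(as.data.frame(b)$smiles), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a[, c("smiles", label_columns())],
               b[, c("smiles", label_columns())])
}
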