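# Metrics, Tanimoto similarity, applicability domain, feature importance.

test_that("MCC and Jaccard hit their bounds and hand-computed values", {
  expect_equal(mcc_score(list(tp = 50, tn = 50, fp = 0, fn = 0)), 1)
  expect_equal(jaccard_score(list(tp = 50, tn = 50, fp = 0, fn = 0)), 1)
  expect_equal(mcc_score(list(tp = 0, tn = 0, fp = 50, fn = 50)), -1)
  expect_equal(mcc_score(list(tp = 25, tn = 25, fp = 25, fn = 25)), 0)
  expect_equal(jaccard_score(list(tp = 25, tn = 25, fp = 25, fn = 25)), 1 / 3)
  expect_equal(mcc_score(list(tp = 10, tn = 0, fp = 5, fn = 0)), 0)  # degenerate
  expect_true(is.na(mcc_score(list(tp = 10, tn = 0, fp = 5, fn = 0),
                              degenerate = "na")))
  expect_error(mcc_score(list(tp = 0, tn = 0, fp = 0, fn = 0)), "all-zero")
})

test_that("MCC is symmetric under a simultaneous class swap", {
  set.seed(2)
  for (i in 1:25) {
    cnt <- as.list(stats::setNames(sample(0:12, 4, replace = TRUE),
                                   c("tp", "tn", "fp", "fn")))
    if (sum(unlist(cnt)) == 0) next
    swapped <- list(tp = cnt$tn, tn = cnt$tp, fp = cnt$fn, fn = cnt$fp)
    expect_equal(mcc_score(cnt), mcc_score(swapped))
  }
})

test_that("MCC equals the correlation of the expanded binary vectors", {
  set.seed(5)
  for (i in 1:50) {
    cnt <- as.list(stats::setNames(sample(0:10, 4, replace = TRUE),
                                   c("tp", "tn", "fp", "fn")))
    truth <- c(rep(1, cnt$tp), rep(0, cnt$tn), rep(0, cnt$fp), rep(1, cnt$fn))
    pred <- c(rep(1, cnt$tp), rep(0, cnt$tn), rep(1, cnt$fp), rep(0, cnt$fn))
    if (length(truth) == 0) next
    oracle <- suppressWarnings(stats::cor(truth, pred))
    if (is.na(oracle)) oracle <- 0
    expect_equal(mcc_score(cnt), oracle)
  }
})

test_that("AUC matches brute-force pair counting", {
  scores <- c(0.9, 0.8, 0.7, 0.6)
  truth <- c("substrate", "substrate", "non_substrate", "non_substrate")
  expect_equal(auc_score(scores, truth), 1)
  expect_equal(auc_score(-scores, truth), 0)
  # a 6-item ranking with a tie, counted exhaustively
  scores <- c(0.9, 0.7, 0.7, 0.5, 0.4, 0.2)
  truth <- c("substrate", "non_substrate", "substrate",
             "substrate", "non_substrate", "non_substrate")
  pos <- scores[truth == "substrate"]
  neg <- scores[truth == "non_substrate"]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  expect_equal(auc_score(scores, truth), mean(pairs))
  expect_error(auc_score(scores, rep("substrate", 6)), "both classes")
})

test_that("Tanimoto handles identity, disjointness and the toy overlap", {
  a <- c(1, 1, 1, 0, 0)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0)  # both empty
  # bits {1,2,3} vs {2,3,4}: 2 shared / 4 union
  expect_equal(tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "mismatch")
})

test_that("nearest-training similarity is a max with an inclusive 0.7 flag", {
  train <- rbind(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
                 c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  nn <- nearest_training_similarity(train[1, ], train)
  expect_equal(nn$similarity, 1)
  expect_true(nn$reliable)
  # 7/10 = 0.70 exactly: reliable (inclusive threshold)
  q <- c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0)
  nn <- nearest_training_similarity(q, train[1, , drop = FALSE])
  expect_equal(nn$similarity, 0.7)
  expect_true(nn$reliable)
  # 69/100 < 0.7: unreliable
  train100 <- matrix(c(rep(1, 100)), nrow = 1)
  q100 <- c(rep(1, 69), rep(0, 31))
  nn <- nearest_training_similarity(q100, train100)
  expect_equal(nn$similarity, 0.69)
  expect_false(nn$reliable)
  expect_error(nearest_training_similarity(q, train[0, , drop = FALSE]),
               "empty")
})

test_that("similarity-binned MCC yields the expected rank correlations", {
  # accuracy increasing with similarity: perfect positive rank correlation
  sims <- rep(c(0.15, 0.45, 0.75), each = 40)
  truth <- rep(c("substrate", "non_substrate"), 60)
  correct <- c(rep(c(TRUE, FALSE), 20)[sample(40)],  # mixed
               rep(c(TRUE, TRUE, TRUE, FALSE), 10),
               rep(TRUE, 40))
  flip <- function(l) ifelse(l == "substrate", "non_substrate", "substrate")
  pred <- ifelse(correct, truth, flip(truth))
  prof <- similarity_binned_performance(pred, truth, sims)
  expect_equal(prof$spearman_rho, 1)
  # reversed construction
  prof_rev <- similarity_binned_performance(pred, truth, 1 - sims)
  expect_equal(prof_rev$spearman_rho, -1)
  # three-bin toy case: rho from the rank-correlation formula by hand
  mccs <- prof$table$mcc[!is.na(prof$table$mcc)]
  mids <- prof$table$midpoint[!is.na(prof$table$mcc)]
  expect_equal(prof$spearman_rho, stats::cor(rank(mids), rank(mccs)))
  # fewer than two defined bins: undefined correlation
  prof1 <- similarity_binned_performance(pred[1:40], truth[1:40], sims[1:40])
  expect_true(is.na(prof1$spearman_rho))
})

test_that("abstentions are excluded from binned confusion counts", {
  truth <- rep("substrate", 10)
  pred <- c(rep("abstain", 5), rep("substrate", 5))
  sims <- rep(0.95, 10)
  prof <- similarity_binned_performance(pred, truth, sims)
  last_bin <- prof$table[prof$table$n > 0, ]
  expect_equal(last_bin$n, 10)   # all queries fall in the top bin
})

test_that("evaluation reports coverage per true class for abstaining models", {
  truth <- c(rep("substrate", 4), rep("non_substrate", 6))
  pred <- c("substrate", "abstain", "substrate", "non_substrate",
            rep("non_substrate", 5), "abstain")
  ev <- evaluate_predictions(truth, pred)
  expect_equal(ev$coverage_substrates, 3 / 4)
  expect_equal(ev$coverage_non_substrates, 5 / 6)
  expect_equal(ev$n_covered, 8)
  # non-abstaining models report no coverage
  ev2 <- evaluate_predictions(truth, rep("substrate", 10))
  expect_true(is.na(ev2$coverage_substrates))
})

test_that("Gini importances are normalized and rank planted signal first", {
  ds <- tiny_dataset()
  X <- tiny_features("maccs")
  y <- ds$label_3A4
  fit <- fit_cyp_classifier(X, y, "rf", cyp = "3A4",
                            grid = small_hyperparameter_grid(), seed = 42,
                            feature_set = "maccs")
  imp <- feature_importance_report(fit)
  expect_equal(sum(imp$importance), 1)
  expect_true(all(imp$importance >= 0))
  # the aromaticity key drives the planted rule; it must outrank the median
  aromatic_rank <- which(imp$feature == "Aromatic")
  expect_lt(aromatic_rank, nrow(imp) / 2)
  # SVM models have no Gini importances
  svm_like <- fit
  svm_like$spec$algorithm <- "svm"
  expect_error(feature_importance_report(svm_like), "random forest")
})
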