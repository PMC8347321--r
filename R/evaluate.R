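# Classification metrics, coverage accounting, applicability-domain
# (similarity-binned) performance, and Gini feature-importance reports.
# The substrate class is the positive class throughout.

#' Confusion counts for binary substrate classification
#'
#' @param truth,predicted character vectors with values `"substrate"` /
#'   `"non_substrate"` (predictions equal to `"abstain"` are dropped together
#'   with their truth values).
#' @return List with fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  keep <- predicted != "abstain"
  truth <- truth[keep]
  predicted <- predicted[keep]
  list(
    tp = sum(truth == "substrate" & predicted == "substrate"),
    tn = sum(truth == "non_substrate" & predicted == "non_substrate"),
    fp = sum(truth == "non_substrate" & predicted == "substrate"),
    fn = sum(truth == "substrate" & predicted == "non_substrate")
  )
}

#' Matthews correlation coefficient from confusion counts
#'
#' MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)).
#'
#' @param counts list with `tp`, `tn`, `fp`, `fn`.
#' @param degenerate value convention when any denominator factor is zero:
#'   `"zero"` (default, the common convention) or `"na"` (used for
#'   similarity-binned reporting, where degenerate bins are undefined).
#' @return Numeric in \[-1, 1\] (or `NA` under `degenerate = "na"`).
#' @export
mcc_score <- function(counts, degenerate = c("zero", "na")) {
  degenerate <- match.arg(degenerate)
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (tp + tn + fp + fn == 0) stop("all-zero confusion counts")
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(if (degenerate == "zero") 0 else NA_real_)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' Jaccard score on the substrate class
#'
#' @param counts list with `tp`, `fp`, `fn`.
#' @return tp / (tp + fp + fn); 0 when that denominator is zero.
#' @export
jaccard_score <- function(counts) {
  denom <- counts$tp + counts$fp + counts$fn
  if (denom == 0) return(0)
  counts$tp / denom
}

#' Area under the ROC curve
#'
#' Equals the Mann-Whitney rank statistic (ties counted half).
#'
#' @param scores substrate-class probabilities or scores.
#' @param truth character vector `"substrate"` / `"non_substrate"`.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  if (length(unique(truth)) < 2L) stop("both classes must be present for AUC")
  r <- pROC::roc(response = truth, predictor = as.numeric(scores),
                 levels = c("non_substrate", "substrate"),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Tanimoto coefficient between two binary fingerprints
#'
#' @param a,b binary (0/1 or logical) vectors of equal length.
#' @return |intersection| / |union|; defined as 0 when both are empty.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Maximum Tanimoto similarity of queries to a training set
#'
#' The applicability-domain statistic: for each query fingerprint, the
#' highest Tanimoto coefficient to any training-set fingerprint, with a
#' reliability flag at the (inclusive) threshold.
#'
#' @param query binary matrix (queries x bits) or a single vector.
#' @param training binary matrix (training compounds x bits).
#' @param threshold reliability threshold (default 0.7, inclusive).
#' @return Data frame with columns `similarity` and `reliable`.
#' @export
nearest_training_similarity <- function(query, training, threshold = 0.7) {
  if (is.vector(query)) query <- matrix(query, nrow = 1)
  if (is.vector(training)) training <- matrix(training, nrow = 1)
  if (nrow(training) == 0L) stop("empty training set")
  if (ncol(query) != ncol(training)) stop("fingerprint length mismatch")
  q <- query > 0
  t_ <- training > 0
  inter <- q %*% t(t_)                       # |A n B|
  qa <- rowSums(q)
  tb <- rowSums(t_)
  uni <- outer(qa, tb, `+`) - inter          # |A u B|
  sim <- ifelse(uni == 0, 0, inter / uni)
  best <- apply(sim, 1, max)
  data.frame(similarity = best, reliable = best >= threshold)
}

#' Evaluation report for a set of predictions
#'
#' Computes MCC and Jaccard on the covered (non-abstained) predictions, AUC
#' when probabilities are available, and per-true-class coverage when the
#' model can abstain.
#'
#' @param truth true labels (`"substrate"` / `"non_substrate"`).
#' @param predicted predicted labels, possibly containing `"abstain"`.
#' @param probability substrate-class probabilities, or `NULL` for models
#'   that emit none (hard voting).
#' @return List of class `cyp_evaluation`: `mcc`, `jaccard`, `auc` (`NA` when
#'   unavailable), `coverage_substrates`, `coverage_non_substrates` (`NA` for
#'   non-abstaining models), `counts`, `n`, `n_covered`.
#' @export
evaluate_predictions <- function(truth, predicted, probability = NULL) {
  stopifnot(length(truth) == length(predicted))
  counts <- confusion_counts(truth, predicted)
  covered <- predicted != "abstain"
  abstaining <- any(!covered)
  cov_by_class <- function(cls) {
    n_cls <- sum(truth == cls)
    if (n_cls == 0) return(NA_real_)
    sum(covered & truth == cls) / n_cls
  }
  auc <- NA_real_
  if (!is.null(probability)) {
    keep <- covered & !is.na(probability)
    if (length(unique(truth[keep])) == 2L) {
      auc <- auc_score(probability[keep], truth[keep])
    }
  }
  structure(list(
    mcc = mcc_score(counts),
    jaccard = jaccard_score(counts),
    auc = auc,
    coverage_substrates = if (abstaining) cov_by_class("substrate") else NA_real_,
    coverage_non_substrates = if (abstaining) cov_by_class("non_substrate") else NA_real_,
    counts = counts,
    n = length(truth),
    n_covered = sum(covered)
  ), class = "cyp_evaluation")
}

#' @export
print.cyp_evaluation <- function(x, ...) {
  cat(sprintf("<cyp_evaluation> n=%d covered=%d MCC=%.3f Jaccard=%.3f",
              x$n, x$n_covered, x$mcc, x$jaccard))
  if (!is.na(x$auc)) cat(sprintf(" AUC=%.3f", x$auc))
  if (!is.na(x$coverage_substrates)) {
    cat(sprintf(" cov(S)=%.2f cov(NS)=%.2f",
                x$coverage_substrates, x$coverage_non_substrates))
  }
  cat("\n")
  invisible(x)
}

#' Similarity-binned performance profile
#'
#' Bins queries by their maximum Tanimoto similarity to the training set and
#' reports the MCC per bin (undefined for bins with a degenerate confusion
#' matrix), plus Spearman's rank correlation between bin midpoint and bin MCC
#' over the defined bins (average ranks on ties; `NA` when fewer than two
#' bins are defined).
#'
#' @param predicted,truth aligned label vectors.
#' @param similarities per-query maximum Tanimoto similarity.
#' @param bin_edges bin boundaries over \[0, 1\] (default width 0.1); the last
#'   bin is closed on the right.
#' @param reliability_threshold threshold reported alongside the profile.
#' @return List of class `cyp_similarity_profile` with `table` (bin, n, mcc)
#'   and `spearman_rho`.
#' @export
similarity_binned_performance <- function(predicted, truth, similarities,
                                          bin_edges = seq(0, 1, by = 0.1),
                                          reliability_threshold = 0.7) {
  stopifnot(length(predicted) == length(truth),
            length(truth) == length(similarities))
  bins <- cut(similarities, breaks = bin_edges, include.lowest = TRUE,
              right = FALSE)
  # right=FALSE leaves similarity exactly 1 unbinned; close the last bin
  bins[similarities == max(bin_edges)] <- levels(bins)[nlevels(bins)]
  mids <- (bin_edges[-length(bin_edges)] + bin_edges[-1]) / 2
  per_bin <- vapply(seq_along(levels(bins)), function(i) {
    idx <- which(as.integer(bins) == i & predicted != "abstain")
    if (length(idx) == 0L) return(NA_real_)
    counts <- confusion_counts(truth[idx], predicted[idx])
    mcc_score(counts, degenerate = "na")
  }, numeric(1))
  n_bin <- as.integer(table(bins))
  defined <- !is.na(per_bin)
  rho <- if (sum(defined) >= 2L) {
    stats::cor(mids[defined], per_bin[defined], method = "spearman")
  } else {
    NA_real_
  }
  structure(list(
    table = data.frame(bin = levels(bins), midpoint = mids,
                       n = n_bin, mcc = per_bin),
    spearman_rho = rho,
    reliability_threshold = reliability_threshold
  ), class = "cyp_similarity_profile")
}

#' Gini feature-importance report for a random forest classifier
#'
#' Mean-impurity-decrease importances of the features surviving
#' preprocessing, normalized to sum to 1.
#'
#' @param model a `cyp_classifier` fitted with `algorithm = "rf"`.
#' @param top_k optionally restrict the returned ranking.
#' @return Data frame with columns `feature`, `importance` (non-negative,
#'   summing to 1 before any `top_k` cut), sorted decreasing.
#' @export
feature_importance_report <- function(model, top_k = NULL) {
  stopifnot(inherits(model, "cyp_classifier"))
  if (model$spec$algorithm != "rf") {
    stop("feature importances are only defined for random forest models")
  }
  imp <- model$fit$model$variable.importance
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  out <- data.frame(feature = names(imp), importance = as.numeric(imp))
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}
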