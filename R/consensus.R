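# Combined (consensus) models over the best single classifiers: soft voting
# (averaged probabilities), hard voting (agreement of at least
# `min_consensus` members, abstaining otherwise, no probability output), and
# max voting (the single largest class probability across members and both
# classes). Decision threshold for probability-based votes is
# strictly-greater-than 0.5, with non_substrate on exact ties.

#' Enumerate all combined-model specifications
#'
#' All choices of 2, 3 or 4 distinct feature sets, an algorithm for each
#' chosen feature set, and a voting strategy: soft, max and hard
#' (min consensus = member count) for sizes 2-4, plus hard with
#' min consensus = 3 for size 4. With four feature sets and two algorithms
#' this yields 72 + 96 + 64 = 232 specifications.
#'
#' @param feature_set_ids feature sets to combine (default all four).
#' @param algorithms available algorithms per member.
#' @return Data frame with columns `size`, `strategy`, `min_consensus` and a
#'   list column `members` (each a data frame with `feature_set`,
#'   `algorithm`).
#' @export
enumerate_combined_specs <- function(feature_set_ids = feature_sets(),
                                     algorithms = c("rf", "svm")) {
  specs <- list()
  for (k in 2:4) {
    if (k > length(feature_set_ids)) next
    fs_choices <- utils::combn(feature_set_ids, k, simplify = FALSE)
    alg_grid <- expand.grid(rep(list(algorithms), k),
                            stringsAsFactors = FALSE)
    modes <- data.frame(strategy = c("soft", "max", "hard"),
                        min_consensus = c(NA, NA, k),
                        stringsAsFactors = FALSE)
    if (k == 4) {
      modes <- rbind(modes, data.frame(strategy = "hard", min_consensus = 3))
    }
    for (fs in fs_choices) {
      for (a in seq_len(nrow(alg_grid))) {
        members <- data.frame(feature_set = fs,
                              algorithm = unlist(alg_grid[a, ]),
                              stringsAsFactors = FALSE)
        for (m in seq_len(nrow(modes))) {
          specs[[length(specs) + 1L]] <- list(
            size = k,
            strategy = modes$strategy[m],
            min_consensus = modes$min_consensus[m],
            members = members
          )
        }
      }
    }
  }
  out <- data.frame(
    size = vapply(specs, `[[`, numeric(1), "size"),
    strategy = vapply(specs, `[[`, character(1), "strategy"),
    min_consensus = vapply(specs, `[[`, numeric(1), "min_consensus")
  )
  out$members <- lapply(specs, `[[`, "members")
  out
}

#' Soft vote: average the substrate-class probabilities
#'
#' @param member_probabilities numeric vector (one query) or matrix
#'   (queries x members) of substrate-class probabilities in \[0, 1\].
#' @return Data frame with `label` and `probability` (the mean); substrate
#'   iff the mean is strictly greater than 0.5.
#' @export
soft_vote <- function(member_probabilities) {
  p <- as_prob_matrix(member_probabilities)
  mean_p <- rowMeans(p)
  data.frame(label = ifelse(mean_p > 0.5, "substrate", "non_substrate"),
             probability = mean_p)
}

#' Hard vote with a minimum-consensus requirement
#'
#' @param member_labels character vector (one query) or matrix
#'   (queries x members) of member labels.
#' @param min_consensus minimum number of members that must agree; must not
#'   exceed the member count.
#' @return Data frame with `label` (`"substrate"`, `"non_substrate"` or
#'   `"abstain"`) and `probability` (always `NA`: hard voting emits no
#'   probability).
#' @export
hard_vote <- function(member_labels, min_consensus) {
  if (is.vector(member_labels)) {
    member_labels <- matrix(member_labels, nrow = 1)
  }
  m <- ncol(member_labels)
  if (length(member_labels) == 0L) stop("no member votes supplied")
  if (min_consensus > m) stop("min_consensus exceeds the member count")
  n_sub <- rowSums(member_labels == "substrate")
  n_non <- rowSums(member_labels == "non_substrate")
  label <- rep("abstain", nrow(member_labels))
  label[n_sub >= min_consensus] <- "substrate"
  label[n_non >= min_consensus] <- "non_substrate"
  data.frame(label = label, probability = NA_real_)
}

#' Max vote: the single largest class probability wins
#'
#' Considers both class probabilities (substrate p and non-substrate 1-p) of
#' every member; the class holding the overall maximum is predicted with that
#' maximum as the reported probability. Exact cross-member ties are resolved
#' by member order (first member wins); a member's own 0.5 tie counts as
#' non_substrate.
#'
#' @param member_probabilities substrate-class probabilities, vector (one
#'   query) or matrix (queries x members).
#' @return Data frame with `label` and `probability`.
#' @export
max_vote <- function(member_probabilities) {
  p <- as_prob_matrix(member_probabilities)
  best_prob <- pmax_matrix(p, 1 - p)          # each member's larger class prob
  member_label <- ifelse(p > 0.5, "substrate", "non_substrate")
  winner <- apply(best_prob, 1, which.max)    # first max: fixed member order
  idx <- cbind(seq_len(nrow(p)), winner)
  data.frame(label = member_label[idx], probability = best_prob[idx])
}

as_prob_matrix <- function(p) {
  if (is.vector(p)) p <- matrix(p, nrow = 1)
  if (length(p) == 0L) stop("no member probabilities supplied")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  p
}

pmax_matrix <- function(a, b) {
  out <- a
  swap <- b > a
  out[swap] <- b[swap]
  out
}

#' Construct a consensus model over fitted single classifiers
#'
#' @param members list of 2-4 `cyp_classifier` objects with pairwise distinct
#'   feature sets.
#' @param strategy `"soft"`, `"hard"` or `"max"`.
#' @param min_consensus required agreement for hard voting; defaults to the
#'   member count; `member count - 1` is allowed only for four members.
#' @return Object of class `cyp_consensus`.
#' @export
cyp_consensus <- function(members, strategy = c("soft", "hard", "max"),
                          min_consensus = NULL) {
  strategy <- match.arg(strategy)
  k <- length(members)
  if (k < 2 || k > 4) stop("a consensus model has 2-4 members")
  fsets <- vapply(members, function(m) as.character(m$spec$feature_set),
                  character(1))
  if (anyDuplicated(fsets)) stop("member feature sets must be pairwise distinct")
  if (strategy == "hard") {
    if (is.null(min_consensus)) min_consensus <- k
    ok <- min_consensus == k || (k == 4 && min_consensus == 3)
    if (!ok) {
      stop("hard voting with ", k, " members allows min_consensus = ", k,
           if (k == 4) " or 3" else "")
    }
  } else {
    min_consensus <- NA_integer_
  }
  structure(list(members = members, strategy = strategy,
                 min_consensus = min_consensus, feature_sets = fsets),
            class = "cyp_consensus")
}

#' Predict method for consensus models
#'
#' Dispatches on the voting strategy and records one vote per member for
#' audit purposes.
#'
#' @param object a `cyp_consensus`.
#' @param newdata named list of feature matrices, one per member feature set
#'   (names from [feature_sets()]), row-aligned across members.
#' @param ... unused.
#' @return Data frame with `label`, `probability` (`NA` under hard voting),
#'   `abstained`, and one `vote_<feature_set>` column per member.
#' @export
predict.cyp_consensus <- function(object, newdata, ...) {
  missing_fs <- setdiff(object$feature_sets, names(newdata))
  if (length(missing_fs)) {
    stop("newdata lacks feature matrices for: ",
         paste(missing_fs, collapse = ", "))
  }
  member_prob <- vapply(object$members, function(m) {
    stats::predict(m, newdata[[as.character(m$spec$feature_set)]],
                   type = "prob")
  }, numeric(nrow(newdata[[object$feature_sets[1]]])))
  if (is.vector(member_prob)) member_prob <- matrix(member_prob, nrow = 1)
  member_label <- vapply(object$members, function(m) {
    stats::predict(m, newdata[[as.character(m$spec$feature_set)]],
                   type = "label")
  }, character(nrow(member_prob)))
  if (is.vector(member_label)) member_label <- matrix(member_label, nrow = 1)
  out <- switch(object$strategy,
    soft = soft_vote(member_prob),
    max = max_vote(member_prob),
    hard = hard_vote(member_label, object$min_consensus)
  )
  out$abstained <- out$label == "abstain"
  for (j in seq_along(object$feature_sets)) {
    out[[paste0("vote_", object$feature_sets[j])]] <- member_label[, j]
  }
  rownames(out) <- rownames(newdata[[object$feature_sets[1]]])
  out
}

#' @export
print.cyp_consensus <- function(x, ...) {
  desc <- paste(vapply(x$members, function(m) {
    paste0(toupper(m$spec$algorithm), " ", m$spec$feature_set)
  }, character(1)), collapse = " + ")
  cat(sprintf("<cyp_consensus> %s voting%s: %s\n", x$strategy,
              if (!is.na(x$min_consensus)) {
                sprintf(" (min consensus %d)", x$min_consensus)
              } else "",
              desc))
  invisible(x)
}
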