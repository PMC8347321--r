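# Chemical-space characterization: PCA projection of descriptor space and
# maximum-similarity threshold curves of reference sets against a core
# compound collection.

#' Fixed 44-descriptor panel for chemical-space PCA
#'
#' An open, documented panel of 44 interpretable 2D physicochemical
#' descriptors (size, lipophilicity, polarity, topology, ring and
#' heteroatom content) drawn from the `physchem2d` feature set, standing in
#' for commercial descriptor panels used in comparable chemical-space
#' analyses.
#'
#' @return Character vector of 44 descriptor names.
#' @export
chemspace_descriptor_panel <- function() {
  c("MolWt", "HeavyAtomCount", "NumRotatableBonds", "RingCount",
    "NumAromaticRings", "NumAliphaticRings", "NumSaturatedRings",
    "NumAromaticCarbocycles", "NumAromaticHeterocycles",
    "FractionCSP3", "MolLogP", "MolMR", "TPSA", "LabuteASA",
    "NumHDonors", "NumHAcceptors", "NumHeteroatoms", "NOCount",
    "NHOHCount", "NumValenceElectrons", "BalabanJ", "BertzCT",
    "Chi0", "Chi1", "Chi0v", "Chi1v", "Chi2v", "Chi3v",
    "Kappa1", "Kappa2", "Kappa3", "HallKierAlpha",
    "PEOE_VSA1", "PEOE_VSA2", "SMR_VSA1", "SMR_VSA5",
    "SlogP_VSA2", "SlogP_VSA5", "EState_VSA1", "EState_VSA9",
    "VSA_EState1", "MaxEStateIndex", "MinEStateIndex", "qed")
}

#' PCA projection of a continuous descriptor matrix
#'
#' Columns are z-score normalized on the pooled data before the
#' decomposition; components are ordered by explained variance.
#'
#' @param X numeric descriptor matrix (compounds x descriptors).
#' @param k number of principal components to return.
#' @return List of class `cyp_projection` with `scores` (compounds x k),
#'   `explained_variance` (fractions, non-increasing) and `loadings`.
#' @export
pca_projection <- function(X, k = 2) {
  variances <- apply(X, 2, stats::var)
  X <- X[, variances > 0, drop = FALSE]
  if (ncol(X) < k) {
    stop("k = ", k, " exceeds the number of non-constant descriptors (",
         ncol(X), ")")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  if (k > length(pc$sdev)) stop("k exceeds the rank of the descriptor matrix")
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = pc$x[, seq_len(k), drop = FALSE],
    explained_variance = ev[seq_len(k)],
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    center = pc$center, scale = pc$scale
  ), class = "cyp_projection")
}

#' @export
print.cyp_projection <- function(x, ...) {
  cat(sprintf("<cyp_projection> %d compounds, %d components (%s%% variance)\n",
              nrow(x$scores), ncol(x$scores),
              paste(round(100 * x$explained_variance, 1), collapse = "/")))
  invisible(x)
}

#' Maximum-similarity threshold curve
#'
#' For each threshold t, the fraction of reference compounds whose nearest
#' neighbor in the core set has a Tanimoto coefficient of at least t. The
#' curve is non-increasing in t and equals 1 at t = 0.
#'
#' @param reference_fps binary fingerprint matrix of the reference set.
#' @param core_fps binary fingerprint matrix of the core set.
#' @param thresholds threshold grid over \[0, 1\].
#' @return Data frame with columns `threshold` and `proportion`.
#' @export
similarity_threshold_curve <- function(reference_fps, core_fps,
                                       thresholds = seq(0, 1, by = 0.05)) {
  if (NROW(reference_fps) == 0L || NROW(core_fps) == 0L) {
    stop("both compound sets must be non-empty")
  }
  nn <- nearest_training_similarity(reference_fps, core_fps)
  proportion <- vapply(thresholds,
                       function(t) mean(nn$similarity >= t), numeric(1))
  data.frame(threshold = thresholds, proportion = proportion)
}
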