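# The four molecular feature families used by the classifiers:
# MACCS structural keys, Morgan (circular) fingerprints, RDKit 2D
# physicochemical descriptors, and mol2vec-style substructure embeddings.
# All featurizers are pure functions of the canonical structure string.

#' The four feature-set identifiers
#'
#' @return `c("maccs", "morgan2", "physchem2d", "embed300")`.
#' @export
feature_sets <- function() c("maccs", "morgan2", "physchem2d", "embed300")

#' Descriptive aliases for selected MACCS keys
#'
#' Column names of the MACCS matrix are `MACCS_<key>` except for a handful of
#' keys with well-known public names that are referenced in importance
#' analyses. Key 162 ("Aromatic") encodes the presence of at least one
#' aromatic atom.
#'
#' @return Named character vector mapping key number to alias.
#' @export
maccs_key_aliases <- function() {
  c("125" = "AromaticRingGt1", "162" = "Aromatic",
    "164" = "O", "165" = "Ring")
}

maccs_column_names <- function() {
  nm <- sprintf("MACCS_%03d", 1:166)
  al <- maccs_key_aliases()
  nm[as.integer(names(al))] <- al
  nm
}

#' Compute a molecular feature matrix
#'
#' @param x a `cyp_dataset` or a character vector of standardized SMILES.
#' @param feature_set one of [feature_sets()]: `"maccs"` (166 binary
#'   structural keys), `"morgan2"` (hashed circular fingerprint, radius 2,
#'   2048 bits), `"physchem2d"` (all RDKit 2D descriptors, with the
#'   averaged-information-content variant of Ipc so values stay finite), or
#'   `"embed300"` (300-dimensional substructure embedding; requires
#'   `embedding`).
#' @param embedding an embedding table from [read_embedding_table()] or
#'   [hashed_embedding()]; only used for `"embed300"`.
#' @param radius,n_bits Morgan fingerprint parameters.
#' @return Numeric matrix, one row per input molecule (row names are record
#'   ids), with attributes `feature_set` and `binary`.
#' @export
featurize <- function(x, feature_set = feature_sets(), embedding = NULL,
                      radius = 2, n_bits = 2048) {
  feature_set <- match.arg(feature_set)
  if (inherits(x, "cyp_dataset") || is.data.frame(x)) {
    smiles <- x$smiles
    ids <- x$record_id
  } else {
    smiles <- as.character(x)
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("mol_%d", seq_along(smiles))
  }
  if (length(smiles) == 0L) stop("no molecules to featurize")
  backend_feature <- switch(feature_set,
    maccs = "maccs", morgan2 = "morgan2",
    physchem2d = "physchem2d", embed300 = "morgan_ids")
  res <- backend_featurize(smiles, backend_feature,
                           radius = radius, n_bits = n_bits)
  failed <- vapply(res, function(r) !identical(r$status, "ok"), logical(1))
  if (any(failed)) {
    stop("featurization failed for record(s): ",
         paste(ids[failed], collapse = ", "))
  }
  mat <- switch(feature_set,
    maccs = {
      m <- matrix(0, length(res), 166,
                  dimnames = list(ids, maccs_column_names()))
      for (i in seq_along(res)) {
        on <- unlist(res[[i]]$maccs_on)
        if (length(on)) m[i, on] <- 1
      }
      m
    },
    morgan2 = {
      m <- matrix(0, length(res), n_bits,
                  dimnames = list(ids, sprintf("MFP_%04d", seq_len(n_bits) - 1L)))
      for (i in seq_along(res)) {
        on <- unlist(res[[i]]$morgan_on)
        if (length(on)) m[i, on + 1L] <- 1
      }
      m
    },
    physchem2d = {
      cols <- names(res[[1]]$physchem)
      m <- matrix(NA_real_, length(res), length(cols),
                  dimnames = list(ids, cols))
      for (i in seq_along(res)) m[i, ] <- unlist(res[[i]]$physchem[cols])
      if (any(!is.finite(m))) stop("non-finite descriptor values")
      m
    },
    embed300 = {
      if (is.null(embedding)) {
        stop("feature set `embed300` requires an `embedding` table ",
             "(see read_embedding_table() or hashed_embedding())")
      }
      dims <- embedding_dims(embedding)
      m <- matrix(0, length(res), dims,
                  dimnames = list(ids, sprintf("EMB_%03d", seq_len(dims))))
      for (i in seq_along(res)) {
        counts <- res[[i]]$morgan_ids
        v <- numeric(dims)
        for (id in names(counts)) {
          v <- v + as.numeric(counts[[id]]) * embed_vector(embedding, id)
        }
        m[i, ] <- v
      }
      m
    })
  attr(mat, "feature_set") <- feature_set
  attr(mat, "binary") <- feature_set %in% c("maccs", "morgan2")
  mat
}

#' Unhashed Morgan substructure identifiers of a molecule
#'
#' The radius-0 and radius-1 atom-environment identifiers (with
#' multiplicities) that act as the substructure "words" of the embedding
#' feature set.
#'
#' @param smiles character vector of SMILES.
#' @return List (one element per molecule) of named numeric vectors:
#'   identifier -> count.
#' @export
morgan_substructure_ids <- function(smiles) {
  res <- backend_featurize(smiles, "morgan_ids")
  lapply(res, function(r) {
    if (!identical(r$status, "ok")) stop("featurization failed")
    vapply(r$morgan_ids, as.numeric, numeric(1))
  })
}

#' Write a feature matrix as CSV
#'
#' One-line header names the feature set; rows carry record ids.
#'
#' @param mat matrix from [featurize()].
#' @param path output file.
#' @export
write_feature_matrix <- function(mat, path) {
  df <- data.frame(record_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# feature_set: ", attr(mat, "feature_set")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV file path.
#' @return Numeric matrix with `feature_set` attribute.
#' @export
read_feature_matrix <- function(path) {
  header <- readLines(path, n = 1)
  fs <- sub("^# feature_set: *", "", header)
  df <- utils::read.csv(path, skip = 1, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$record_id
  attr(mat, "feature_set") <- fs
  attr(mat, "binary") <- all(mat %in% c(0, 1))
  mat
}
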