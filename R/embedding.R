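# Substructure embedding tables for the mol2vec-style feature set.
#
# A molecule's embedding is the multiplicity-weighted sum of the vectors of
# its radius-0/1 Morgan substructure identifiers (summation, not averaging,
# following the original mol2vec formulation). Identifiers absent from the
# table map to the unknown-token vector.

#' Load a substructure embedding table
#'
#' Plain-text format: one row per substructure identifier followed by its
#' vector components, whitespace-separated. A row with identifier `UNK`
#' provides the unknown-token vector (defaults to the zero vector). Gzipped
#' files are read transparently.
#'
#' @param path file path.
#' @return An object of class `cyp_embedding`.
#' @export
read_embedding_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  ids <- vapply(parts, `[[`, character(1), 1)
  vecs <- lapply(parts, function(p) as.numeric(p[-1]))
  dims <- unique(lengths(vecs))
  if (length(dims) != 1L) stop("embedding vectors have inconsistent dimensions")
  mat <- do.call(rbind, vecs)
  rownames(mat) <- ids
  unk <- if ("UNK" %in% ids) mat["UNK", ] else numeric(dims)
  mat <- mat[setdiff(ids, "UNK"), , drop = FALSE]
  structure(list(type = "table", vectors = mat, unknown = unk, dims = dims),
            class = "cyp_embedding")
}

#' Deterministic hashed pseudo-embedding
#'
#' A self-contained fallback when no pretrained embedding table is available:
#' each substructure identifier is hashed to a reproducible pseudo-random
#' vector (unit expected norm). This is not equivalent to an embedding
#' trained on a large compound corpus -- it preserves substructure identity
#' but carries no learned chemical similarity structure. Sufficient for
#' pipeline testing and as a generic continuous feature set.
#'
#' @param dims embedding dimensionality.
#' @return An object of class `cyp_embedding`.
#' @export
hashed_embedding <- function(dims = 300) {
  structure(list(type = "hashed", dims = dims,
                 cache = new.env(parent = emptyenv())),
            class = "cyp_embedding")
}

embedding_dims <- function(embedding) {
  stopifnot(inherits(embedding, "cyp_embedding"))
  embedding$dims
}

# vector for one identifier (character form of the numeric Morgan id)
embed_vector <- function(embedding, id) {
  stopifnot(inherits(embedding, "cyp_embedding"))
  if (embedding$type == "table") {
    if (id %in% rownames(embedding$vectors)) {
      return(embedding$vectors[id, ])
    }
    return(embedding$unknown)
  }
  hit <- embedding$cache[[id]]
  if (!is.null(hit)) return(hit)
  seed <- as.integer(as.numeric(id) %% 2147483563)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  v <- stats::rnorm(embedding$dims) / sqrt(embedding$dims)
  embedding$cache[[id]] <- v
  v
}

#' @export
print.cyp_embedding <- function(x, ...) {
  if (x$type == "table") {
    cat(sprintf("<cyp_embedding> table, %d identifiers, %d dims\n",
                nrow(x$vectors), x$dims))
  } else {
    cat(sprintf("<cyp_embedding> deterministic hashed fallback, %d dims\n",
                x$dims))
  }
  invisible(x)
}
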