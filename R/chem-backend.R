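# Interface to the RDKit chemistry backend.
#
# All structure handling (parsing, ChEMBL-rule standardization, tautomer
# canonicalization, fingerprints, 2D descriptors) is delegated to RDKit,
# invoked as a batched subprocess through the system `python` interpreter.
# One process call handles a whole vector of molecules; results travel as
# JSON through temporary files.

.backend_env <- new.env(parent = emptyenv())

backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "cypsubstrate")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is mapped directly
    path <- system.file("inst", "python", "chem_backend.py",
                        package = "cypsubstrate")
  }
  if (!nzchar(path)) stop("chem_backend.py not found in the installed package")
  path
}

python_binary <- function() {
  bin <- getOption("cypsubstrate.python", Sys.which("python"))
  if (!nzchar(bin)) stop("no `python` interpreter found on the PATH")
  bin
}

#' Check that the RDKit backend is functional
#'
#' @return `TRUE` invisibly if `python` with RDKit is available, otherwise
#'   an error is raised.
#' @export
chem_backend_available <- function() {
  status <- suppressWarnings(system2(
    python_binary(), c("-c", shQuote("import rdkit")),
    stdout = FALSE, stderr = FALSE
  ))
  if (status != 0L) stop("the `python` interpreter on the PATH cannot import rdkit")
  invisible(TRUE)
}

chem_backend_call <- function(payload) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  status <- suppressWarnings(system2(
    python_binary(), c(backend_script(), infile, outfile),
    stdout = FALSE, stderr = FALSE
  ))
  if (status != 0L || !file.exists(outfile)) {
    stop("chemistry backend call failed (task: ", payload$task, ")")
  }
  jsonlite::read_json(outfile, simplifyVector = FALSE)$results
}

# Batched standardization, memoized per molecule within the session: repeated
# curation of overlapping molecule sets (fixture pools, merge scenarios) only
# pays the subprocess round-trip for structures not seen before.
backend_standardize <- function(smiles, canonical_tautomer = TRUE) {
  smiles <- ifelse(is.na(smiles), "", smiles)
  prefix <- if (canonical_tautomer) "t1:" else "t0:"
  keys <- paste0(prefix, smiles)
  todo <- vapply(keys, function(k) is.null(.backend_env[[k]]), logical(1))
  if (any(todo)) {
    fresh <- unique(smiles[todo])
    res <- chem_backend_call(list(
      task = "standardize",
      smiles = as.list(fresh),
      canonical_tautomer = canonical_tautomer
    ))
    for (i in seq_along(fresh)) {
      .backend_env[[paste0(prefix, fresh[i])]] <- res[[i]]
    }
  }
  lapply(keys, function(k) .backend_env[[k]])
}

backend_featurize <- function(smiles, features, radius = 2, n_bits = 2048) {
  chem_backend_call(list(
    task = "featurize",
    smiles = as.list(smiles),
    features = as.list(features),
    radius = radius,
    n_bits = n_bits
  ))
}

backend_parse_sdf <- function(path) {
  chem_backend_call(list(task = "parse_sdf", path = normalizePath(path)))
}
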