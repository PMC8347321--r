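# Curation of molecule records: standardization, element filtering,
# label-conflict-aware deduplication, and compilation of multi-source
# labeled data sets.

#' The nine human CYP isozymes covered by the models
#'
#' @return Character vector of isozyme identifiers in the fixed reporting
#'   order.
#' @export
cyp_isozymes <- function() {
  c("1A2", "2A6", "2B6", "2C8", "2C9", "2C19", "2D6", "2E1", "3A4")
}

label_columns <- function() paste0("label_", cyp_isozymes())

#' Elements permitted in curated molecule records
#'
#' Molecules containing any other element are discarded during curation.
#'
#' @return Character vector of element symbols.
#' @export
allowed_elements <- function() {
  c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Se", "Br", "I")
}

#' Parse and standardize molecular structures
#'
#' Applies ChEMBL-rule structure standardization via the RDKit backend:
#' normalization of frequent drawing variants, kekulization, salt/solvent
#' stripping to the parent component, removal of duplicate fragments and of
#' all isotope annotations, neutralization, and (by default) tautomer
#' canonicalization, which also removes all stereochemical information.
#' Unparsable inputs are never dropped silently; they are returned with a
#' reason code so rejection counts can be reported.
#'
#' @param smiles character vector of structure strings (SMILES).
#' @param ids optional record identifiers (defaults to `mol_<i>`).
#' @param source optional provenance tag(s), recycled.
#' @param canonical_tautomer canonicalize tautomers (the full curation path);
#'   set `FALSE` to stop after parent/neutralization standardization.
#' @return A data frame with one row per input: `record_id`, `smiles_input`,
#'   `smiles` (canonical, stereo-free; `NA` on rejection), `status` (one of
#'   `ok`, `missing_structure`, `parse_error`, `standardization_error`),
#'   `n_atoms`, `n_aromatic_atoms`, and a list column `elements`.
#' @export
standardize_molecules <- function(smiles, ids = NULL, source = NA_character_,
                                  canonical_tautomer = TRUE) {
  stopifnot(is.character(smiles) || all(is.na(smiles)))
  n <- length(smiles)
  if (n == 0L) stop("no structures supplied")
  if (is.null(ids)) ids <- sprintf("mol_%d", seq_len(n))
  res <- backend_standardize(as.character(smiles), canonical_tautomer)
  pick <- function(field, default) {
    vapply(res, function(r) {
      v <- r[[field]]
      if (is.null(v)) default else v
    }, default)
  }
  out <- data.frame(
    record_id = as.character(ids),
    smiles_input = as.character(smiles),
    smiles = pick("smiles", NA_character_),
    status = pick("status", "standardization_error"),
    n_atoms = as.integer(pick("n_atoms", NA_integer_)),
    n_aromatic_atoms = as.integer(pick("n_aromatic_atoms", NA_integer_)),
    source = rep_len(as.character(source), n),
    stringsAsFactors = FALSE
  )
  out$elements <- lapply(res, function(r) {
    if (is.null(r$elements)) character(0) else unlist(r$elements)
  })
  out
}

#' Canonicalize tautomers of already-standardized structures
#'
#' Two tautomeric spellings of the same compound map to the same output
#' string; any stereo descriptors are removed in the process.
#'
#' @param smiles character vector of standardized SMILES.
#' @return Character vector of canonical-tautomer SMILES (`NA` where
#'   canonicalization failed).
#' @export
canonicalize_tautomer <- function(smiles) {
  standardize_molecules(smiles, canonical_tautomer = TRUE)$smiles
}

#' Element-filter predicate
#'
#' Keep a record iff every atom's element belongs to [allowed_elements()].
#'
#' @param elements a character vector of element symbols, or a list of such
#'   vectors (one per record).
#' @return Logical vector of keep decisions.
#' @export
filter_elements <- function(elements) {
  if (!is.list(elements)) elements <- list(elements)
  vapply(elements, function(e) all(e %in% allowed_elements()), logical(1))
}

#' Construct a labeled molecule data set
#'
#' @param records data frame with columns `record_id`, `smiles`, `source`
#'   and one `label_<CYP>` column per isozyme with values `"substrate"`,
#'   `"non_substrate"` or `NA` (missing).
#' @return An object of class `cyp_dataset` (a data frame).
#' @export
cyp_dataset <- function(records) {
  stopifnot(is.data.frame(records))
  for (col in c("record_id", "smiles")) {
    if (!col %in% names(records)) stop("missing column: ", col)
  }
  if (!"source" %in% names(records)) records$source <- NA_character_
  for (col in label_columns()) {
    if (!col %in% names(records)) records[[col]] <- NA_character_
    bad <- !is.na(records[[col]]) &
      !records[[col]] %in% c("substrate", "non_substrate")
    if (any(bad)) stop("invalid label values in ", col)
  }
  records <- records[, c("record_id", "smiles", "source", label_columns())]
  if (anyDuplicated(records$smiles)) {
    stop("duplicate structures present; run merge_duplicates() first")
  }
  class(records) <- c("cyp_dataset", "data.frame")
  records
}

#' @export
print.cyp_dataset <- function(x, ...) {
  cat(sprintf("<cyp_dataset> %d records, completeness %.3f\n",
              nrow(x), dataset_completeness(x)))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Fraction of non-missing cells in the records-by-isozymes label matrix
#'
#' @param dataset a `cyp_dataset`.
#' @return Numeric in \[0, 1\].
#' @export
dataset_completeness <- function(dataset) {
  m <- as.matrix(as.data.frame(dataset)[, label_columns()])
  1 - sum(is.na(m)) / length(m)
}

#' Merge duplicate molecule records
#'
#' Records sharing the same canonical structure string are merged into one.
#' Per CYP: consistent labels are kept; conflicting labels ("substrate" vs
#' "non-substrate") are resolved by removing the label for that CYP only;
#' a defined label beats a missing one. Provenance tags of merged records are
#' concatenated.
#'
#' @param records data frame in the `cyp_dataset` column layout (duplicates
#'   allowed in `smiles`).
#' @return A `cyp_dataset` with attribute `merge_log`: a list with
#'   `n_input`, `n_unique`, `n_removed` (duplicate rows merged away) and
#'   `n_conflict_cells`.
#' @export
merge_duplicates <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  lab_cols <- label_columns()
  for (col in lab_cols) if (!col %in% names(records)) records[[col]] <- NA_character_
  if (!"source" %in% names(records)) records$source <- NA_character_
  groups <- split(seq_len(nrow(records)), records$smiles)
  # keep first-appearance order of unique structures
  first <- vapply(groups, min, integer(1))
  groups <- groups[order(first)]
  n_conflicts <- 0L
  merged <- lapply(groups, function(idx) {
    block <- records[idx, , drop = FALSE]
    row <- block[1, c("record_id", "smiles", "source"), drop = FALSE]
    src <- unique(stats::na.omit(block$source))
    row$source <- if (length(src)) paste(src, collapse = ";") else NA_character_
    for (col in lab_cols) {
      vals <- unique(stats::na.omit(block[[col]]))
      if (length(vals) == 1L) {
        row[[col]] <- vals
      } else {
        if (length(vals) > 1L) n_conflicts <<- n_conflicts + 1L
        row[[col]] <- NA_character_
      }
    }
    row
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out <- cyp_dataset(out)
  attr(out, "merge_log") <- list(
    n_input = nrow(records),
    n_unique = nrow(out),
    n_removed = nrow(records) - nrow(out),
    n_conflict_cells = n_conflicts
  )
  out
}

curate_source <- function(raw, source = NA_character_) {
  # raw: data.frame(id, smiles, label_* ...) possibly unstandardized
  std <- standardize_molecules(raw$smiles, ids = raw$id, source = source)
  keep_elements <- filter_elements(std$elements)
  status <- std$status
  status[status == "ok" & !keep_elements] <- "element_filter"
  log <- list(
    n_input = nrow(raw),
    removed_missing_structure = sum(status == "missing_structure"),
    removed_unparsable = sum(status == "parse_error" |
                               status == "standardization_error"),
    removed_element_filter = sum(status == "element_filter")
  )
  ok <- status == "ok"
  recs <- data.frame(
    record_id = std$record_id[ok],
    smiles = std$smiles[ok],
    source = std$source[ok],
    stringsAsFactors = FALSE
  )
  for (col in label_columns()) {
    recs[[col]] <- if (col %in% names(raw)) raw[[col]][ok] else NA_character_
  }
  list(records = recs, log = log, status = status)
}

#' Compile a core data set from two preprocessed sources
#'
#' Each source is standardized and element-filtered independently, the union
#' is deduplicated under the label-conflict rules, and a processing log
#' reports the number of molecules removed at each step (missing structure,
#' unparsable, element filter, duplicates).
#'
#' @param source_a,source_b data frames with columns `id`, `smiles` and
#'   optional `label_<CYP>` columns. `source_b` may be `NULL` or empty.
#' @param tag_a,tag_b provenance tags.
#' @return A list with elements `dataset` (a `cyp_dataset`) and `log`.
#' @export
compile_dataset <- function(source_a, source_b = NULL,
                            tag_a = "source_a", tag_b = "source_b") {
  cur_a <- curate_source(source_a, tag_a)
  cur_b <- if (!is.null(source_b) && nrow(source_b) > 0) {
    curate_source(source_b, tag_b)
  } else {
    list(records = NULL,
         log = list(n_input = 0L, removed_missing_structure = 0L,
                    removed_unparsable = 0L, removed_element_filter = 0L))
  }
  union <- rbind(cur_a$records, cur_b$records)
  if (is.null(union) || nrow(union) == 0L) {
    stop("no molecules survived curation; cannot compile an empty data set")
  }
  dataset <- merge_duplicates(union)
  mlog <- attr(dataset, "merge_log")
  log <- list(
    n_input = cur_a$log$n_input + cur_b$log$n_input,
    removed_missing_structure = cur_a$log$removed_missing_structure +
      cur_b$log$removed_missing_structure,
    removed_unparsable = cur_a$log$removed_unparsable +
      cur_b$log$removed_unparsable,
    removed_element_filter = cur_a$log$removed_element_filter +
      cur_b$log$removed_element_filter,
    removed_duplicates = mlog$n_removed,
    label_conflict_cells = mlog$n_conflict_cells,
    n_final = nrow(dataset)
  )
  list(dataset = dataset, log = log)
}

#' Read a labeled molecule table from CSV
#'
#' Expected columns: `id`, `smiles`, and one label column per CYP (named
#' `label_<CYP>`, `CYP<CYP>` or just the isozyme identifier) with values
#' `substrate`, `non_substrate`, or empty for missing.
#'
#' @param path CSV file path.
#' @return Data frame with normalized column names (`id`, `smiles`,
#'   `label_<CYP>`).
#' @export
read_molecule_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  names(raw)[tolower(names(raw)) %in% c("id", "record_id")] <- "id"
  if (!"smiles" %in% tolower(names(raw))) stop("no `smiles` column in ", path)
  names(raw)[tolower(names(raw)) == "smiles"] <- "smiles"
  if (!"id" %in% names(raw)) raw$id <- sprintf("mol_%d", seq_len(nrow(raw)))
  for (cyp in cyp_isozymes()) {
    hit <- which(names(raw) %in% c(paste0("label_", cyp), paste0("CYP", cyp), cyp))
    if (length(hit)) {
      vals <- raw[[hit[1]]]
      vals[!is.na(vals) & !nzchar(trimws(vals))] <- NA_character_
      bad <- !is.na(vals) & !vals %in% c("substrate", "non_substrate")
      if (any(bad)) stop("invalid label values for CYP", cyp, " in ", path)
      raw[[paste0("label_", cyp)]] <- vals
    }
  }
  raw
}

#' Write a labeled data set in the standard CSV dialect
#'
#' @param dataset a `cyp_dataset` (or data frame in the same layout).
#' @param path output file.
#' @export
write_molecule_table <- function(dataset, path) {
  df <- as.data.frame(dataset)
  names(df)[names(df) == "record_id"] <- "id"
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read molecules from an SDF file
#'
#' Labels are taken from SD tags named `label_<CYP>`, `CYP<CYP>` or the bare
#' isozyme identifier.
#'
#' @param path SDF file path.
#' @return Data frame with columns `id`, `smiles` and any `label_<CYP>`
#'   columns found, plus a `parse_failures` attribute with rejected indices.
#' @export
read_sdf_molecules <- function(path) {
  res <- backend_parse_sdf(path)
  ok <- vapply(res, function(r) identical(r$status, "ok"), logical(1))
  rows <- lapply(res[ok], function(r) {
    row <- data.frame(
      id = if (nzchar(r$name)) r$name else sprintf("sdf_%d", r$index + 1L),
      smiles = r$smiles, stringsAsFactors = FALSE
    )
    for (cyp in cyp_isozymes()) {
      for (tag in c(paste0("label_", cyp), paste0("CYP", cyp), cyp)) {
        if (!is.null(r$properties[[tag]])) {
          row[[paste0("label_", cyp)]] <- r$properties[[tag]]
          break
        }
      }
    }
    row
  })
  out <- do.call(rbind_fill, list(rows))
  attr(out, "parse_failures") <- which(!ok)
  out
}

# rbind for data frames with non-identical column sets (NULLs dropped)
rbind_fill <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(NULL)
  cols <- unique(unlist(lapply(rows, names)))
  filled <- lapply(rows, function(r) {
    for (col in setdiff(cols, names(r))) r[[col]] <- NA_character_
    r[, cols, drop = FALSE]
  })
  do.call(rbind, filled)
}

#' Write a processing log as JSON
#'
#' @param log a named list (e.g. from [compile_dataset()]).
#' @param path output file.
#' @export
write_processing_log <- function(log, path) {
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Published class-label counts for the curated core data collection
#'
#' Per-isozyme numbers of substrates and non-substrates in the curated
#' 1831-compound core collection compiled from the Tian and Hunt source sets,
#' together with the counts obtained when the substrate-only Hunt source is
#' left out. Shipped as plain text under `inst/extdata`; used to recompute
#' the label-matrix completeness and the average substrate gain contributed
#' by the Hunt source.
#'
#' @return Data frame with columns `cyp`, `substrates_without_hunt`,
#'   `substrates`, `nonsubstrates_without_hunt`, `nonsubstrates`.
#' @export
core_label_counts <- function() {
  path <- system.file("extdata", "core_label_counts.csv",
                      package = "cypsubstrate")
  if (!nzchar(path)) {
    path <- system.file("inst", "extdata", "core_label_counts.csv",
                        package = "cypsubstrate")
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Label-matrix completeness implied by per-isozyme class counts
#'
#' @param counts data frame as returned by [core_label_counts()].
#' @param n_compounds total number of compounds in the collection.
#' @return Completeness as a percentage (0-100).
#' @export
completeness_from_counts <- function(counts = core_label_counts(),
                                     n_compounds = 1831) {
  labeled <- sum(counts$substrates) + sum(counts$nonsubstrates)
  100 * labeled / (n_compounds * nrow(counts))
}

#' Mean per-isozyme substrate gain from integrating the Hunt source set
#'
#' @param counts data frame as returned by [core_label_counts()].
#' @return Mean over isozymes of the substrate-count difference.
#' @export
mean_substrate_gain <- function(counts = core_label_counts()) {
  mean(counts$substrates - counts$substrates_without_hunt)
}
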