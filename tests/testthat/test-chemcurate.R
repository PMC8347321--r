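# Structure standardization, element filtering, and label-conflict-aware
# deduplication.

test_that("standardization strips salts, isotopes and stereo, rejects bad input", {
  std <- standardize_molecules(c(
    aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    acetate_salt = "CC(=O)[O-].[Na+]",
    heavy_methane = "[13CH4]",
    broken = "C1CC",
    alanine = "C[C@H](N)C(=O)O"
  ))
  expect_equal(std$smiles[1], "CC(=O)Oc1ccccc1C(=O)O")
  expect_equal(std$n_atoms[1], 13)          # heavy-atom count unchanged
  expect_equal(std$smiles[2], "CC(=O)O")    # parent acid, neutralized
  expect_equal(std$smiles[3], "C")          # isotope label removed
  expect_equal(std$status[4], "parse_error")
  expect_true(is.na(std$smiles[4]))
  expect_false(grepl("@", std$smiles[5], fixed = TRUE))
  expect_equal(std$status[c(1:3, 5)], rep("ok", 4))
})

test_that("standardization and tautomer canonicalization are idempotent", {
  inputs <- c("CC(=O)[O-].[Na+]", "C=C(C)O", "c1ccc(O)cc1", "CCN")
  once <- standardize_molecules(inputs)$smiles
  twice <- standardize_molecules(once)$smiles
  expect_equal(twice, once)
  expect_equal(canonicalize_tautomer(once), once)
})

test_that("tautomeric spellings map to one canonical structure", {
  out <- canonicalize_tautomer(c("C=C(C)O", "CC(C)=O"))
  expect_equal(out[1], out[2])
  expect_equal(canonicalize_tautomer("c1ccccc1"), "c1ccccc1")
})

test_that("element filter keeps the allowed set and nothing else", {
  expect_true(filter_elements(c("C", "H", "N", "O")))
  expect_false(filter_elements(c("C", "Fe")))
  expect_true(filter_elements(c("C", "Se")))   # Se explicitly allowed
  std <- standardize_molecules(c("Cl[Fe](Cl)Cl", "c1cc[se]c1", "c1ccccc1"))
  expect_equal(filter_elements(std$elements), c(FALSE, TRUE, TRUE))
})

make_records <- function(smiles, labels_1a2) {
  recs <- data.frame(record_id = sprintf("r%d", seq_along(smiles)),
                     smiles = smiles, source = "t",
                     stringsAsFactors = FALSE)
  recs$label_1A2 <- labels_1a2
  recs
}

test_that("merge resolves conflicts to missing and keeps one-sided labels", {
  recs <- make_records(c("CCO", "CCO"), c("substrate", "non_substrate"))
  merged <- merge_duplicates(recs)
  expect_equal(nrow(merged), 1)
  expect_true(is.na(merged$label_1A2))
  expect_equal(attr(merged, "merge_log")$n_conflict_cells, 1L)

  recs <- make_records(c("CCO", "CCO"), c("substrate", NA))
  merged <- merge_duplicates(recs)
  expect_equal(merged$label_1A2, "substrate")

  single <- make_records("CCO", "substrate")
  merged <- merge_duplicates(single)
  expect_equal(nrow(merged), 1)
  expect_equal(attr(merged, "merge_log")$n_removed, 0L)
  expect_equal(merged$label_1A2, "substrate")
})

test_that("merge is order-independent and never invents labels", {
  set.seed(3)
  smiles <- sample(c("CCO", "CCN", "CCC", "c1ccccc1"), 30, replace = TRUE)
  labs <- sample(c("substrate", "non_substrate", NA), 30, replace = TRUE)
  recs <- make_records(smiles, labs)
  merged <- merge_duplicates(recs)
  for (perm in 1:5) {
    shuffled <- recs[sample(nrow(recs)), ]
    expect_same_dataset(merge_duplicates(shuffled), merged)
  }
  for (i in seq_len(nrow(merged))) {
    inputs <- recs$label_1A2[recs$smiles == merged$smiles[i]]
    out <- merged$label_1A2[i]
    expect_true(is.na(out) || out %in% inputs)
  }
})

test_that("completeness equals one minus the missing-cell fraction", {
  ds <- tiny_dataset()
  m <- as.matrix(as.data.frame(ds)[, label_columns()])
  expect_equal(dataset_completeness(ds), 1 - sum(is.na(m)) / length(m))
  ds2 <- generate_labeled_set(fixture_config(n_compounds = 100,
                                             missing_fraction = 0.3,
                                             seed = 5))
  m2 <- as.matrix(as.data.frame(ds2)[, label_columns()])
  expect_equal(dataset_completeness(ds2), 1 - sum(is.na(m2)) / length(m2))
})

test_that("compiling two sources merges shared structures and logs counts", {
  a <- data.frame(id = c("a1", "a2", "a3"),
                  smiles = c("CCO", "CCN", "CCC"),
                  label_1A2 = c("substrate", "non_substrate", "substrate"),
                  stringsAsFactors = FALSE)
  b <- data.frame(id = c("b1", "b2"),
                  smiles = c("OCC", "c1ccccc1"),  # OCC == CCO after curation
                  label_1A2 = c("substrate", NA),
                  stringsAsFactors = FALSE)
  res <- compile_dataset(a, b)
  expect_equal(nrow(res$dataset), 4)
  expect_equal(res$log$n_input, 5L)
  expect_equal(res$log$removed_duplicates, 1L)
  expect_equal(res$log$n_final, 4L)
  # the shared structure had consistent labels
  ethanol <- res$dataset[res$dataset$smiles == "CCO", ]
  expect_equal(ethanol$label_1A2, "substrate")

  res_a <- compile_dataset(a, NULL)
  expect_equal(nrow(res_a$dataset), 3)
  expect_equal(res_a$log$removed_duplicates, 0L)
})

test_that("curation log accounts for every rejection reason", {
  a <- data.frame(
    id = sprintf("x%d", 1:5),
    smiles = c("CCO", "", "C1CC", "Cl[Fe](Cl)Cl", "CCN"),
    stringsAsFactors = FALSE
  )
  res <- compile_dataset(a)
  expect_equal(res$log$removed_missing_structure, 1L)
  expect_equal(res$log$removed_unparsable, 1L)
  expect_equal(res$log$removed_element_filter, 1L)
  expect_equal(res$log$n_final, 2L)
  expect_equal(res$log$n_input, 5L)
})

test_that("the CSV dialect round-trips a labeled data set", {
  ds <- tiny_dataset()[1:20, ]
  path <- tempfile(fileext = ".csv")
  write_molecule_table(ds, path)
  back <- read_molecule_table(path)
  expect_equal(back$smiles, ds$smiles)
  expect_equal(back$label_3A4, ds$label_3A4)
  expect_equal(back$id, ds$record_id)
})

test_that("SDF molecules and their SD-tag labels are read", {
  sdf <- paste(
    "ethanol", "  test", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.0000    0.0000    0.0000 O   0  0",
    "  1  2  1  0", "  2  3  1  0",
    "M  END",
    ">  <label_3A4>", "substrate", "",
    "$$$$", sep = "\n")
  path <- tempfile(fileext = ".sdf")
  writeLines(sdf, path)
  mols <- read_sdf_molecules(path)
  expect_equal(nrow(mols), 1)
  expect_equal(mols$smiles, "CCO")
  expect_equal(mols$label_3A4, "substrate")
})
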