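# Synthetic labeled molecule sets with controllable class structure, so the
# whole pipeline is testable offline. Structures are assembled by template
# substitution (fixed scaffold list x substituent list), which guarantees
# chemical validity without a validity-checking loop; labels follow a planted
# structural rule ("aromatic ring AND at least one oxygen atom"). The
# fixtures test machinery, not CYP structure-activity relationships.

fixture_substituents <- function() {
  list(
    oxygen = c("O", "OC", "OCC", "C(=O)O", "C(=O)C", "C(=O)N", "COC",
               "C(=O)OC"),
    plain = c("C", "CC", "CCC", "CCCC", "C(C)C", "C(C)(C)C", "N", "NC",
              "CN", "N(C)C", "CCN", "Cl", "F", "Br", "C#N", "CCl")
  )
}

fixture_templates <- function() {
  # pattern placeholders {R}, {R1}, {R2}; `sites`: number of placeholders
  list(
    list(pattern = "c1ccc({R})cc1", sites = 1),
    list(pattern = "c1cc({R1})ccc1{R2}", sites = 2),
    list(pattern = "c1cc({R1})cc({R2})c1", sites = 2),
    list(pattern = "c1ccnc({R})c1", sites = 1),
    list(pattern = "c1cc({R1})nc({R2})c1", sites = 2),
    list(pattern = "c1cc({R})oc1", sites = 1),
    list(pattern = "c1cc({R})sc1", sites = 1),
    list(pattern = "c1ccc2cc({R})ccc2c1", sites = 1),
    list(pattern = "C1CCC({R})CC1", sites = 1),
    list(pattern = "C1CC({R1})CCC1{R2}", sites = 2),
    list(pattern = "CCCC{R}", sites = 1),
    list(pattern = "CC(C){R}", sites = 1),
    list(pattern = "C1CCNC({R})C1", sites = 1),
    list(pattern = "C1CCC({R1})CC1{R2}", sites = 2)
  )
}

assemble_fixture_smiles <- function() {
  subs <- unlist(fixture_substituents(), use.names = FALSE)
  out <- character(0)
  for (tpl in fixture_templates()) {
    if (tpl$sites == 1) {
      out <- c(out, vapply(subs, function(r) {
        gsub("{R}", r, tpl$pattern, fixed = TRUE)
      }, character(1)))
    } else {
      grid <- expand.grid(r1 = subs, r2 = subs, stringsAsFactors = FALSE)
      # unordered pairs only: symmetric scaffolds make (a,b) and (b,a) collide
      grid <- grid[grid$r1 <= grid$r2, ]
      out <- c(out, apply(grid, 1, function(g) {
        s <- gsub("{R1}", g[["r1"]], tpl$pattern, fixed = TRUE)
        gsub("{R2}", g[["r2"]], s, fixed = TRUE)
      }))
    }
  }
  unique(out)
}

.fixture_env <- new.env(parent = emptyenv())

# Standardized, deduplicated template pool with structure-derived truth
# flags; built once per session (tautomer canonicalization of ~2000
# structures), then memoized.
fixture_pool <- function() {
  pool <- .fixture_env$pool
  if (!is.null(pool)) return(pool)
  raw <- assemble_fixture_smiles()
  std <- standardize_molecules(raw, ids = sprintf("tpl_%d", seq_along(raw)))
  ok <- std$status == "ok" & filter_elements(std$elements)
  std <- std[ok, , drop = FALSE]
  std <- std[!duplicated(std$smiles), , drop = FALSE]
  pool <- data.frame(
    smiles = std$smiles,
    aromatic = std$n_aromatic_atoms > 0,
    has_oxygen = vapply(std$elements, function(e) "O" %in% e, logical(1)),
    stringsAsFactors = FALSE
  )
  pool$rule_substrate <- pool$aromatic & pool$has_oxygen
  .fixture_env$pool <- pool
  pool
}

#' Configuration for the synthetic fixture generator
#'
#' @param n_compounds total number of compounds.
#' @param imbalance_ratio substrates : non-substrates, as a length-2 numeric
#'   (default 1:4, emulating the class imbalance of curated CYP data).
#' @param label_noise probability of flipping each label (default 0.05).
#' @param missing_fraction probability of masking each label as missing
#'   (default 0.05).
#' @param seed integer seed; the generated set is byte-identical per seed.
#' @return List of class `fixture_config`.
#' @export
fixture_config <- function(n_compounds = 1000, imbalance_ratio = c(1, 4),
                           label_noise = 0.05, missing_fraction = 0.05,
                           seed = 42) {
  stopifnot(length(imbalance_ratio) == 2, all(imbalance_ratio > 0),
            label_noise >= 0, label_noise < 1,
            missing_fraction >= 0, missing_fraction < 1)
  structure(list(n_compounds = n_compounds,
                 imbalance_ratio = imbalance_ratio,
                 label_noise = label_noise,
                 missing_fraction = missing_fraction,
                 seed = seed),
            class = "fixture_config")
}

#' Generate a synthetic labeled data set
#'
#' Draws rule-positive and rule-negative structures from the template pool in
#' the exact configured class ratio (construction, not sampling), assigns the
#' planted-rule label to all nine CYPs, flips each label with probability
#' `label_noise`, and masks each label as missing with probability
#' `missing_fraction`. Deterministic per seed.
#'
#' @param config a [fixture_config()].
#' @return A `cyp_dataset` with attribute `truth`: a data frame with the
#'   noise-free rule labels (`rule_substrate`) and structure flags.
#' @export
generate_labeled_set <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  ratio <- config$imbalance_ratio
  n <- config$n_compounds
  n_sub <- n * ratio[1] / sum(ratio)
  if (n_sub != round(n_sub)) {
    stop("imbalance ratio ", ratio[1], ":", ratio[2],
         " is unsatisfiable for n = ", n)
  }
  n_sub <- as.integer(n_sub)
  n_non <- n - n_sub
  pool <- fixture_pool()
  pos <- pool[pool$rule_substrate, ]
  neg <- pool[!pool$rule_substrate, ]
  if (n_sub > nrow(pos) || n_non > nrow(neg)) {
    stop("template pool too small for the requested configuration (",
         nrow(pos), " rule-positive / ", nrow(neg), " rule-negative ",
         "structures available)")
  }
  records <- with_seed(config$seed, {
    chosen <- rbind(pos[sample(nrow(pos), n_sub), ],
                    neg[sample(nrow(neg), n_non), ])
    chosen <- chosen[sample(nrow(chosen)), ]
    rule_label <- ifelse(chosen$rule_substrate, "substrate", "non_substrate")
    recs <- data.frame(
      record_id = sprintf("fx_%04d", seq_len(n)),
      smiles = chosen$smiles,
      source = "fixture",
      stringsAsFactors = FALSE
    )
    for (col in label_columns()) {
      lab <- rule_label
      flip <- stats::runif(n) < config$label_noise
      lab[flip] <- ifelse(lab[flip] == "substrate",
                          "non_substrate", "substrate")
      lab[stats::runif(n) < config$missing_fraction] <- NA_character_
      recs[[col]] <- lab
    }
    attr(recs, "truth") <- data.frame(
      record_id = recs$record_id,
      rule_substrate = chosen$rule_substrate,
      aromatic = chosen$aromatic,
      has_oxygen = chosen$has_oxygen,
      stringsAsFactors = FALSE
    )
    recs
  })
  truth <- attr(records, "truth")
  out <- cyp_dataset(records)
  attr(out, "truth") <- truth
  attr(out, "config") <- config
  out
}

# base molecules with alternative input spellings that standardize to the
# same canonical structure (salt form, isotope label, tautomer, stereo,
# kekulized aromatic ring)
duplicate_scenario_bases <- function() {
  list(
    list(spellings = c("CC(=O)O", "CC(=O)[O-].[Na+]", "[13CH3]C(=O)O")),
    list(spellings = c("CC(C)=O", "C=C(C)O")),
    list(spellings = c("c1ccccc1", "C1=CC=CC=C1")),
    list(spellings = c("CC(N)C(=O)O", "C[C@H](N)C(=O)O")),
    list(spellings = c("CCO", "OCC"))
  )
}

#' Generate duplicate/conflict merge scenarios
#'
#' Produces a collection of raw molecule records containing planted duplicate
#' pairs -- at least one with consistent labels, one with conflicting labels,
#' and one with a one-sided missing label -- together with a machine-readable
#' expected outcome computed directly from the merge rules (consistent
#' labels kept; conflicts resolved to missing; a defined label beats a
#' missing one).
#'
#' @param seed integer seed controlling label assignment.
#' @return List with `records` (raw data frame: `id`, `smiles`, labels) and
#'   `expected` (data frame keyed by canonical structure with the merged
#'   labels), plus counts `n_consistent`, `n_conflict`, `n_one_sided`.
#' @export
generate_duplicate_scenarios <- function(seed = 42) {
  bases <- duplicate_scenario_bases()
  canon <- canonicalize_tautomer(
    vapply(bases, function(b) b$spellings[1], character(1))
  )
  kinds <- c("consistent", "conflict", "one_sided")
  with_seed(seed, {
    kind_of <- c(kinds, sample(kinds, length(bases) - 3, replace = TRUE))
    kind_of <- sample(kind_of)
    records <- NULL
    expected <- NULL
    n_kind <- c(consistent = 0L, conflict = 0L, one_sided = 0L)
    for (i in seq_along(bases)) {
      spell <- sample(bases[[i]]$spellings, 2)
      cyp_col <- sample(label_columns(), 1)
      base_label <- sample(c("substrate", "non_substrate"), 1)
      other <- setdiff(c("substrate", "non_substrate"), base_label)
      kind <- kind_of[i]
      n_kind[kind] <- n_kind[kind] + 1L
      lab <- switch(kind,
        consistent = c(base_label, base_label),
        conflict = c(base_label, other),
        one_sided = c(base_label, NA_character_)
      )
      exp_label <- switch(kind,
        consistent = base_label,
        conflict = NA_character_,
        one_sided = base_label
      )
      rec <- data.frame(id = sprintf("dup_%d_%d", i, 1:2),
                        smiles = spell, stringsAsFactors = FALSE)
      rec[[cyp_col]] <- lab
      records <- rbind_fill(list(records, rec))
      exp <- data.frame(smiles = canon[i], stringsAsFactors = FALSE)
      exp[[cyp_col]] <- exp_label
      expected <- rbind_fill(list(expected, exp))
    }
    for (col in setdiff(label_columns(), names(expected))) {
      expected[[col]] <- NA_character_
    }
    expected <- expected[, c("smiles", label_columns())]
    list(records = records, expected = expected,
         n_consistent = n_kind[["consistent"]],
         n_conflict = n_kind[["conflict"]],
         n_one_sided = n_kind[["one_sided"]])
  })
}
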