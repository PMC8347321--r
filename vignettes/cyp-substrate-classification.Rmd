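---
title: "Classifying CYP substrates: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying CYP substrates: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cypsubstrate` builds binary substrate / non-substrate classifiers for nine
human cytochrome P450 isozymes (1A2, 2A6, 2B6, 2C8, 2C9, 2C19, 2D6, 2E1,
3A4). This vignette explains the modelling procedure, its assumptions, the
tunable parameters and their defaults, the numerical conventions, and what
the synthetic test bed does and does not demonstrate.

## The data model

A labeled data set (`cyp_dataset`) is a table of standardized molecules with
one three-state label per isozyme: `substrate`, `non_substrate`, or missing
(`NA`). Missing is deliberately distinct from both classes: it encodes
absent or conflicting evidence and such rows are dropped per isozyme at
training time, never imputed. Real curated CYP collections are incomplete
(a published 1831-compound core collection has a 94%-complete label matrix)
and strongly imbalanced — ratios of substrates to non-substrates reach 1:16
for CYP2A6 — which drives two design features: balanced class weighting in
every learner, and stratification in every split.

### Curation

Structures are standardized with the ChEMBL standardization rules as
implemented in RDKit's `rdMolStandardize` (invoked through the system
`python`): normalization of frequent drawing variants, kekulization,
stripping of known salts/solvents to the parent component, removal of
duplicate fragments and isotope annotations, neutralization, tautomer
canonicalization, and removal of all stereochemistry. Stereo-free modelling
is an explicit assumption: the fingerprints used downstream are
2D-topological, so enantiomers are treated as the same compound and their
labels are merged under the conflict rules.

The duplicate identity key is the stereo-free canonical SMILES *after*
tautomer canonicalization; canonicalization therefore precedes
deduplication. Merging follows three rules, per isozyme: consistent labels
merge as-is; a `substrate` / `non_substrate` conflict removes the label for
that isozyme only; a defined label beats a missing one. Rejected inputs
(missing structure, unparsable, disallowed element) are counted per reason
code, never silently dropped, so processing logs are reproducible. Molecules
containing elements outside {H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I} are
discarded. Records whose labels end up missing for all nine isozymes are
retained in the compiled set — they may still inform other isozymes'
subsets later, and per-isozyme training drops missing rows anyway.

Multi-source provenance after merging is kept as a concatenated source tag;
this is a pragmatic convention, not a registration-grade provenance model.

## Feature sets

Four families, all pure functions of the canonical structure string:

* `maccs` — the public 166-key MACCS dictionary. Columns are `MACCS_<k>`
  except a few keys with well-known names; key 162 (`Aromatic`, "at least
  one aromatic atom") matters because aromaticity is consistently the most
  discriminative structural property for CYP substrate recognition.
* `morgan2` — hashed circular fingerprints, radius 2, 2048 bits. Also the
  similarity currency of the applicability domain.
* `physchem2d` — every RDKit 2D descriptor (about 210, depending on the
  RDKit release; column count is taken from the backend, not hard-coded).
  The `Ipc` descriptor uses the averaged-information-content form
  (`avg = 1`): the raw form grows combinatorially with molecule size and
  overflows single-precision range, while the averaged form stays finite.
  Any non-finite descriptor value rejects the molecule rather than
  propagating `NaN`.
* `embed300` — a mol2vec-style embedding: each molecule is the
  multiplicity-weighted *sum* (not average, following the original mol2vec
  formulation) of the vectors of its radius-0/1 Morgan substructure
  identifiers. The package loads an external plain-text embedding table
  when one is available; otherwise a deterministic hashed fallback assigns
  each identifier a reproducible pseudo-random vector of unit expected
  norm. The fallback preserves substructure identity but no learned
  chemical similarity — adequate for pipeline testing and as a generic
  continuous representation, not a reproduction of an embedding trained on
  a large corpus.

## Single classifiers

For one isozyme, the labeled subset is split 80/20 by stratified shuffled
sampling (default seed 42). On the training split, hyperparameters are
optimized by exhaustive grid search inside a stratified, shuffled,
seed-deterministic five-fold CV:

| component | grid |
|---|---|
| RF `min_samples_split` | 2, 4, 8, 16, 32, 64, 128 |
| RF `max_features` | 0.05, 0.1, 0.2, 0.4, 0.8, sqrt |
| SVM `C` | 10^-2 ... 10^3 |
| SVM `gamma` | 10^0 ... 10^-5 |
| selection percentile | 10, 40, 70, 100 |

Random forests use 500 trees and balanced class weights (`ranger`;
`min.node.size` is the minimum-samples-to-split control, fractions map to
`mtry = round(f * p)`). SVMs use an RBF kernel with balanced class weights
(`e1071`/libsvm) on features standardized by the preprocessor
(`scale = FALSE` in the learner).

The preprocessor — zero-variance removal, then ANOVA-F percentile selection
(top `ceiling(p% · n)` columns by the closed-form one-way F statistic,
stable tie-break by column order), then z-scoring of non-binary columns on
the SVM path — is refit *inside every fold* on that fold's training
portion. Whether selection should be global or fold-wise was genuinely
open; fold-wise refitting was chosen because global selection leaks
validation information into the fold metrics. The per-fold selected feature
sets are recorded, and a test asserts they can differ.

The winning hyperparameter point maximizes the **median fold MCC** (the
median is also the reported CV summary; using the mean inside the search
was the plausible alternative, and on the synthetic benchmark the choice is
immaterial). Ties break deterministically by grid order. The final model is
refit on the whole training split. SVM probabilities come from Platt
scaling implemented in the package: a stratified cross-validated sigmoid
(binomial GLM on held-out decision values), seed-deterministic — libsvm's
built-in probability machinery is not seed-controllable from R, and the
refit-based sigmoid matches the standard formulation. Note that the SVM
*label* remains libsvm's class-weighted decision; the calibrated
probability is reported alongside and used by the probability-based voting
strategies. Determinism contracts are per-seed within this implementation;
bit-identical splits across other implementations of the same procedure are
not promised.

Model selection across the eight (algorithm, feature set) candidates is the
argmax of median CV MCC with a fixed tie-break ordering (RF before SVM,
feature sets in `feature_sets()` order).

## Consensus models

Over the best model per (algorithm, feature set) pair, all combinations of
2–4 distinct feature sets, per-member algorithm assignments, and voting
strategies are enumerated: soft and max voting plus hard voting with
`min_consensus` equal to the member count, and additionally `min_consensus
= 3` for four members — 72, 96 and 64 specifications for sizes 2, 3 and 4;
232 in total.

* **Soft**: the substrate probability is the arithmetic mean of the member
  probabilities.
* **Hard**: predict the class reached by at least `min_consensus` members,
  otherwise abstain; no probability (and hence no AUC) is defined. Members
  contribute their binary label, not raw margins.
* **Max**: the single largest class probability across members *and both
  classes* wins and is reported as the consensus probability.

Two conventions the voting rules need but the procedure leaves open were
fixed as: the decision threshold is strictly-greater-than 0.5 with
`non_substrate` on exact ties (a conservative default for a positive class
one usually wants high confidence in), and max-vote cross-member ties
resolve by declared member order, recorded in the audit columns (one vote
per member in every prediction).

Coverage — covered / (covered + abstained), reported separately per true
class — is the price of hard voting's accuracy and is always reported with
it.

## Applicability domain

Prediction reliability correlates with similarity to the training data. For
each query the package reports the maximum Tanimoto coefficient (Morgan2,
2048 bits) to the training compounds and flags the prediction *reliable*
when that similarity is at least 0.7 — the threshold is inclusive.
`similarity_binned_performance` profiles MCC across similarity bins
(default width 0.1 over [0, 1]; the binning granularity is a reporting
choice) and summarizes the trend with Spearman's rho over defined bins
(average ranks on ties); bins with a degenerate confusion matrix are
reported as undefined rather than zero, unlike the global MCC where the
zero-denominator convention is the conventional MCC = 0. The fingerprint
underlying the domain is configurable; Morgan2 is the default because it is
the similarity measure used for the 0.7 rule, although MACCS-based
similarity profiles are sometimes shown in comparable analyses.

## Chemical-space reports

`pca_projection` z-scores a descriptor panel on the pooled data and reports
component scores with explained-variance fractions. The default panel is a
fixed, documented list of 44 interpretable 2D descriptors
(`chemspace_descriptor_panel()`); published analyses of this kind often use
a commercial 44-descriptor panel, so projections are comparable in spirit,
not bit-exact. `similarity_threshold_curve` reports, for each threshold t,
the fraction of reference compounds whose nearest core-set neighbor has
Tanimoto ≥ t — non-increasing by construction, 1 at t = 0.

## The synthetic test bed

`generate_labeled_set` assembles valid structures by template substitution
(aromatic and aliphatic scaffolds × a fixed substituent list, one or two
sites), standardizes them through the real curation path, and labels them
by a planted structural rule — *aromatic ring AND at least one oxygen
atom* — evaluated on the standardized structure (aromatic atom count and
element inventory from the chemistry backend, so tautomer shifts cannot
desynchronize labels from structures). Class ratios are met exactly by
construction; label noise and missingness are applied per label cell;
generation is byte-identical per seed. Defaults (n = 1000, ratio 1:4, 5%
noise, 5% missing) emulate the moderate imbalance and noise of curated CYP
data sets; the 1:16 CYP2A6-like extreme is exercised separately in the
tests.

What passing on fixtures shows: the machinery — curation, featurization,
selection, CV, voting, abstention accounting — is correct, leak-free and
deterministic, and the pipeline recovers a planted structure–activity rule
under label noise (best single classifier reaches CV median MCC ≥ 0.8 on
the default benchmark; unanimous hard voting is at least as accurate as the
best single model on the compounds it covers). What it does not show:
performance on real CYP data. The planted rule is a two-feature predicate,
vastly simpler than CYP structure–activity relationships; fixture chemistry
spans a narrow scaffold space; and the hashed embedding carries no learned
similarity. Published-scale numbers require the original curated
collections and a pretrained embedding model, which are inputs, not part of
the package.

Benchmark problem sizes were chosen to make the full suite comfortably
reproducible on a laptop: the recovery benchmark uses 1000 compounds with
the reduced grid (`small_hyperparameter_grid()`, exposed through the same
grid-override mechanism the CLI offers), exhaustive metric oracles cover
all confusion matrices with totals ≤ 40 and all label patterns up to n = 12,
and voting oracles sweep a 0.05 probability grid for 2–4 members.

## Numerical conventions and edge cases

* MCC with any zero marginal: 0 globally (common convention), undefined in
  similarity bins.
* Jaccard with an empty substrate union: 0.
* AUC: Mann–Whitney statistic with half-credit ties; requires both classes.
* Tanimoto of two empty fingerprints: 0.
* ANOVA F with zero within-class variance: +Inf (selected first) unless the
  between-class variance is also zero.
* All-zero-variance feature matrices, single-class splits, empty candidate
  lists, fewer than five minority-class members for five folds: errors, not
  silent degradation.
* Hard-voting `min_consensus` greater than the member count: an error; the
  k − 1 relaxation exists only for four members.

## Known limitations

Stereochemistry is discarded by design, so stereospecific metabolism cannot
be represented. The curation pipeline targets modelling-grade, not
registration-grade, normalization. The embedding fallback is not a trained
mol2vec model. Hard-voting consensus models provide no probability, so no
ranking applications. And every performance claim in this document is about
the synthetic benchmark the tests compute, not about real-world CYP
prediction accuracy.
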