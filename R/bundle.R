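# Model bundles: a directory with a JSON manifest (spec, hyperparameters,
# selected feature names, scaler statistics, CV metrics) plus the serialized
# learner state, loadable for prediction without retraining.

#' Save a fitted classifier as a bundle directory
#'
#' @param model a `cyp_classifier`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
save_classifier_bundle <- function(model, dir) {
  stopifnot(inherits(model, "cyp_classifier"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    spec = model$spec,
    hyperparameters = model$cv$best_params,
    selected_features = model$preprocessor$columns,
    scaler = if (isTRUE(model$preprocessor$standardize)) {
      list(center = as.numeric(model$preprocessor$center),
           scale = as.numeric(model$preprocessor$scale))
    },
    cv = list(median_mcc = model$cv$median_mcc,
              median_jaccard = model$cv$median_jaccard,
              median_auc = model$cv$median_auc,
              fold_metrics = as.data.frame(model$cv$fold_metrics)),
    n_train = model$n_train,
    class_counts = model$class_counts,
    package_version = as.character(utils::packageVersion("cypsubstrate"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  saveRDS(model, file.path(dir, "learner.rds"))
  invisible(dir)
}

#' Load a classifier bundle
#'
#' @param dir bundle directory written by [save_classifier_bundle()].
#' @return The `cyp_classifier`.
#' @export
load_classifier_bundle <- function(dir) {
  path <- file.path(dir, "learner.rds")
  if (!file.exists(path)) stop("no learner.rds in ", dir)
  model <- readRDS(path)
  stopifnot(inherits(model, "cyp_classifier"))
  model
}

# short stable hash of a configuration list (for run manifests)
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  v <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(v * (seq_along(v) %% 997)) %% .Machine$integer.max)
}

write_run_manifest <- function(dir, command, config) {
  manifest <- list(
    command = command,
    config = config,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("cypsubstrate")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(manifest)
}
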