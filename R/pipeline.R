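#' Pipeline configuration
#'
#' Bundles every tunable of the classification pipeline. Serializable to
#' YAML or JSON ([save_pipeline_config()] / [load_pipeline_config()]);
#' unknown keys in a config file are rejected.
#'
#' @param filter a [filter_spec()].
#' @param bands band list for the knowledge extractor.
#' @param feature_mode `"knowledge"` or `"conventional"`.
#' @param classifier classifier kind (`"rvm"`, `"lda"`, `"knn"`, `"svm"`).
#' @param kernel `"linear"` or `"rbf"`.
#' @param rbf_gamma RBF width (default 0.5).
#' @param k k-NN neighbor count (default 13).
#' @param cost SVM penalty parameter (default 50).
#' @param seed integer seed for every stochastic step.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_spec(), bands = default_bands(),
                            feature_mode = c("knowledge", "conventional"),
                            classifier = c("rvm", "lda", "knn", "svm"),
                            kernel = c("linear", "rbf"), rbf_gamma = 0.5,
                            k = 13L, cost = 50, seed = 1L) {
  structure(list(filter = filter, bands = bands,
                 feature_mode = match.arg(feature_mode),
                 classifier = match.arg(classifier),
                 kernel = match.arg(kernel), rbf_gamma = rbf_gamma,
                 k = as.integer(k), cost = cost, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Turn a pipeline config into a classifier spec
#' @param config a [pipeline_config()].
#' @return A [classifier_spec()].
#' @export
config_classifier_spec <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  classifier_spec(config$classifier,
                  kernel = kernel_spec(config$kernel,
                                       rbf_gamma = config$rbf_gamma),
                  k = config$k, cost = config$cost)
}

config_keys <- c("filter", "bands", "feature_mode", "classifier", "kernel",
                 "rbf_gamma", "k", "cost", "seed")

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @export
save_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$filter <- unclass(x$filter)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path))
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(x), config_keys)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  filt <- if (is.null(x$filter)) filter_spec()
  else do.call(filter_spec, x$filter[c("low_cut_hz", "high_cut_hz", "order",
                                       "zero_phase")])
  bands <- if (is.null(x$bands)) default_bands()
  else lapply(x$bands, as.numeric)
  pipeline_config(
    filter = filt, bands = bands,
    feature_mode = x$feature_mode %||% "knowledge",
    classifier = x$classifier %||% "rvm",
    kernel = x$kernel %||% "linear",
    rbf_gamma = x$rbf_gamma %||% 0.5,
    k = x$k %||% 13L, cost = x$cost %||% 50, seed = x$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- pipeline commands (thin shell entry points call these) ----------------

#' Simulate a cohort to disk
#'
#' @param out_dir output directory (EDF + hypnogram per subject and a
#'   `manifest.json`).
#' @param config a [pipeline_config()] (supplies the seed).
#' @param n_subjects,epochs_per_subject cohort size.
#' @return The manifest path, invisibly.
#' @export
cmd_simulate <- function(out_dir, config = pipeline_config(),
                         n_subjects = 10L, epochs_per_subject = 300L) {
  sc <- simulation_config(n_subjects = n_subjects,
                          epochs_per_subject = epochs_per_subject,
                          seed = config$seed)
  cohort <- simulate_cohort(sc, dir = out_dir)
  message(sprintf("simulated %d subject(s) x %d epochs into %s",
                  n_subjects, epochs_per_subject, out_dir))
  invisible(attr(cohort, "manifest"))
}

#' Extract a feature table from an EDF recording and its hypnogram
#'
#' @param edf_path EDF file.
#' @param hypnogram_path side-car hypnogram (optional).
#' @param out_csv output CSV path; when `NULL` the data frame is returned
#'   instead of written.
#' @param config a [pipeline_config()].
#' @param channels channels to load.
#' @return The feature data frame (invisibly when written).
#' @export
cmd_extract <- function(edf_path, hypnogram_path = NULL, out_csv = NULL,
                        config = pipeline_config(),
                        channels = c("FP1", "FP2")) {
  rec <- read_edf(edf_path, channels)
  hyp <- if (!is.null(hypnogram_path)) read_hypnogram(hypnogram_path)
  pairs <- segment_epochs(rec, hyp)
  feat <- feature_table(pairs, subject_id = rec$subject_id,
                        mode = config$feature_mode, filter = config$filter,
                        bands = config$bands)
  if (is.null(out_csv)) return(feat)
  write.csv(feat, out_csv, row.names = FALSE)
  invisible(feat)
}

#' Train a stage classifier on a feature table
#'
#' Epochs labeled `"UNKNOWN"` are dropped before fitting.
#'
#' @param features feature CSV path or data frame.
#' @param model_path output model file (RDS).
#' @param config a [pipeline_config()].
#' @return The fitted model, invisibly.
#' @export
cmd_train <- function(features, model_path, config = pipeline_config()) {
  if (is.character(features))
    features <- read.csv(features, check.names = FALSE,
                         stringsAsFactors = FALSE)
  features <- features[features$stage != "UNKNOWN", , drop = FALSE]
  set.seed(config$seed)
  model <- fit_stage_classifier(
    as.matrix(features[, feature_columns(features), drop = FALSE]),
    features$stage, config_classifier_spec(config))
  saveRDS(list(model = model, feature_mode = config$feature_mode,
               feature_names = feature_columns(features)), model_path)
  invisible(model)
}

#' Score a recording with a trained model
#'
#' Emits one stage label per full 30-s epoch, written in the same side-car
#' hypnogram format the package reads.
#'
#' @param model_path model file from [cmd_train()].
#' @param edf_path recording to score.
#' @param out_hypnogram output hypnogram path; `NULL` returns the
#'   [hypnogram()] instead.
#' @param config a [pipeline_config()].
#' @param channels channels to load.
#' @return The predicted [hypnogram()] (invisibly when written).
#' @export
cmd_predict <- function(model_path, edf_path, out_hypnogram = NULL,
                        config = pipeline_config(),
                        channels = c("FP1", "FP2")) {
  stored <- readRDS(model_path)
  config$feature_mode <- stored$feature_mode
  feat <- cmd_extract(edf_path, NULL, NULL, config, channels)
  pred <- predict_stages(stored$model,
                         as.matrix(feat[, stored$feature_names,
                                        drop = FALSE]))
  hyp <- hypnogram(pred)
  if (is.null(out_hypnogram)) return(hyp)
  write_hypnogram(hyp, out_hypnogram)
  invisible(hyp)
}

#' Leave-one-subject-out evaluation of a simulated or recorded cohort
#'
#' Reads a cohort `manifest.json` (as written by [cmd_simulate()]), extracts
#' features for every subject, and runs [loso_evaluate()].
#'
#' @param manifest_path cohort manifest.
#' @param out_json optional report path.
#' @param config a [pipeline_config()].
#' @return The `evaluation_report`.
#' @export
cmd_evaluate_loso <- function(manifest_path, out_json = NULL,
                              config = pipeline_config()) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  tables <- lapply(seq_len(nrow(man$subjects)), function(i) {
    cmd_extract(file.path(dir, man$subjects$edf[i]),
                file.path(dir, man$subjects$hypnogram[i]),
                NULL, config)
  })
  features <- do.call(rbind, tables)
  report <- loso_evaluate(features, config_classifier_spec(config))
  for (s in names(report$per_subject)) {
    cm <- report$per_subject[[s]]$confusion
    message(sprintf("fold %s: n=%d, class balance %s", s, sum(cm),
                    paste(rowSums(cm), collapse = "/")))
  }
  if (!is.null(out_json)) write_evaluation_report(report, out_json)
  report
}
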