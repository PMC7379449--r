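#' Run the staged lateralization pipeline
#'
#' Wires the package stages — simulate (or load) a cohort, extract
#' asymmetry-index features, train a classifier (or use a published rule),
#' predict the held-out test set, and evaluate — from a single declarative
#' configuration. Every artifact is written under `out_dir` together with
#' a `manifest.json` recording the configuration, seeds and package
#' version, so a rerun with an identical configuration reproduces the
#' outputs byte for byte (volumes compare equal voxelwise).
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognized fields:
#'   \describe{
#'     \item{out_dir}{Output directory (required).}
#'     \item{seed}{Master integer seed (default 1).}
#'     \item{algorithm}{`"c45"`, `"lmt"`, `"published_j48"` or
#'       `"published_lmt"` (default `"lmt"`).}
#'     \item{cohort}{List of [cohort_config()] overrides for simulation.}
#'     \item{features_only}{Simulate the feature table directly, skipping
#'       the volume layer (default `TRUE`).}
#'     \item{write_volumes}{Also write NIfTI volumes when simulating the
#'       volume layer (default `FALSE`).}
#'     \item{features_csv}{Use an existing feature CSV instead of
#'       simulating.}
#'     \item{atlas_nii, regions_csv, volumes_dir}{Extract features from
#'       existing NIfTI inputs (labels in `manifest_csv` if available).}
#'     \item{manifest_csv}{CSV with `subject_id,label` for existing
#'       volumes.}
#'     \item{train_fraction}{Train/test proportion (default 31/49).}
#'     \item{k}{If set, additionally run k-fold cross-validation on the
#'       whole cohort.}
#'     \item{params}{Extra trainer arguments.}
#'   }
#' @return The run manifest (named list), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("Configuration error: config file not found: ", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML path.")
  need <- function(field) {
    if (is.null(config[[field]])) {
      abort(paste0("Configuration error: required field `", field,
                   "` is missing."))
    }
    config[[field]]
  }
  out_dir <- need("out_dir")
  seed <- as.integer(config$seed %||% 1L)
  algorithm <- config$algorithm %||% "lmt"
  if (!algorithm %in% c("c45", "lmt", "published_j48", "published_lmt")) {
    abort("Configuration error: `algorithm` must be one of c45, lmt, published_j48, published_lmt.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  # --- stage: obtain the feature table -------------------------------
  if (!is.null(config$features_csv)) {
    if (!file.exists(config$features_csv)) {
      abort(paste0("Configuration error: `features_csv` not found: ",
                   config$features_csv))
    }
    features <- read_features(config$features_csv)
    source_desc <- list(kind = "csv", path = config$features_csv)
  } else if (!is.null(config$atlas_nii) || !is.null(config$volumes_dir)) {
    for (field in c("atlas_nii", "regions_csv", "volumes_dir")) {
      p <- need(field)
      if (!file.exists(p)) {
        abort(paste0("Configuration error: `", field, "` not found: ", p))
      }
    }
    atlas <- read_atlas(config$atlas_nii, config$regions_csv)
    paths <- sort(list.files(config$volumes_dir,
                             pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
    if (length(paths) == 0) {
      abort("Configuration error: `volumes_dir` contains no NIfTI volumes.")
    }
    vols <- setNames(
      purrr::map(paths, RNifti::readNifti),
      sub("\\.nii(\\.gz)?$", "", basename(paths))
    )
    labels <- NULL
    if (!is.null(config$manifest_csv)) {
      man <- read.csv(config$manifest_csv)
      labels <- man$label[match(names(vols), man$subject_id)]
    }
    features <- extract_features(vols, atlas, labels = labels)
    source_desc <- list(kind = "volumes", n = length(vols))
  } else {
    cc <- do.call(cohort_config, c(list(seed = seed), config$cohort))
    if (isFALSE(config$features_only %||% TRUE)) {
      atlas <- generate_atlas(seed = seed)
      cohort <- generate_cohort(atlas, cc)
      if (isTRUE(config$write_volumes)) {
        write_cohort(cohort, atlas, file.path(out_dir, "cohort"), cc)
        files <- c(files, "cohort/")
      }
      features <- extract_features(cohort, atlas)
    } else {
      features <- generate_feature_table(cc)
    }
    source_desc <- list(kind = "simulated", n = nrow(features),
                        seed = seed)
  }
  features_path <- file.path(out_dir, "features.csv")
  write_features(features, features_path)
  files <- c(files, "features.csv")

  # --- stage: train / load model, predict, evaluate -------------------
  params <- config$params %||% list()
  has_labels <- "label" %in% names(features)
  if (startsWith(algorithm, "published_")) {
    rules <- published_rules()
    model <- if (algorithm == "published_j48") rules$j48_test_model else rules$lmt_test_model
    test_tab <- features
  } else {
    if (!has_labels) {
      abort("Configuration error: training requires a labeled feature table.")
    }
    split <- make_split(features, config$train_fraction %||% (31 / 49),
                        seed = seed)
    train_tab <- features[split$set == "train", , drop = FALSE]
    test_tab <- features[split$set == "test", , drop = FALSE]
    trainer <- switch(algorithm, c45 = train_c45, lmt = train_lmt)
    args <- c(list(train_tab), params)
    if (algorithm == "lmt" && is.null(params$seed)) args$seed <- seed
    model <- do.call(trainer, args)
    write.csv(split, file.path(out_dir, "split.csv"), row.names = FALSE,
              quote = FALSE)
    files <- c(files, "split.csv")
  }
  serialize_model(model, file.path(out_dir, "model.json"))
  predictions <- tibble::tibble(
    subject_id = test_tab$subject_id %||%
      sprintf("S%03d", seq_len(nrow(test_tab))),
    prediction = predict(model, test_tab)
  )
  if (has_labels) predictions$truth <- as.character(test_tab$label)
  write.csv(predictions, file.path(out_dir, "predictions.csv"),
            row.names = FALSE, quote = FALSE)
  files <- c(files, "model.json", "predictions.csv")

  metrics <- NULL
  if (has_labels) {
    metrics <- as.list(evaluate_predictions(predictions$prediction,
                                            predictions$truth))
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "metrics.json")
  }

  # --- stage: optional cross-validation -------------------------------
  cv_summary <- NULL
  if (!is.null(config$k) && has_labels &&
      !startsWith(algorithm, "published_")) {
    cv <- cross_validate(features, k = as.integer(config$k),
                         algo = algorithm, params = params, seed = seed)
    cv_summary <- list(
      algo = cv$algo, k = cv$k, mean_ratio = cv$mean_ratio,
      folds = dplyr::select(cv$folds, -"model")
    )
    jsonlite::write_json(cv_summary, file.path(out_dir, "crossval.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    files <- c(files, "crossval.json")
  }

  manifest <- list(
    package = "petlat",
    version = as.character(utils::packageVersion("petlat")),
    seed = seed, algorithm = algorithm, source = source_desc,
    files = files,
    metrics = metrics,
    cv_mean_ratio = cv_summary$mean_ratio
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
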